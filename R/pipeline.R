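# End-to-end orchestration: simulate (or load) volumes, denoise, segment,
# QC, map the ETDRS grid, measure layer intensities, and run the cohort
# statistics.  Deterministic given the config seeds; volumes failing QC are
# excluded from cohort outputs and logged with their reason.

#' Default pipeline configuration
#'
#' A single nested list mirroring the pipeline stages.  `simulate`
#' describes the phantom cohort (number of volumes, phantom overrides,
#' per-subject intensity scaling SD, optional operator re-scan pairs and
#' the statistical cohort); alternatively `inputs` may point to a directory
#' of `.tif`/`.nii` volumes with JSON sidecars.  `segment`, `qc` and
#' `stats` hold stage parameters.
#'
#' @return nested configuration list with all defaults filled in.
#' @export
pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "oct-results",
    simulate = list(
      n_volumes = 20L,
      phantom = list(),          # overrides for phantom_spec()
      subject_gain_sd = 0.03,    # between-subject reflectivity scaling
      rescan_pairs = 0L,         # operator re-scan pairs for ICC
      rescan = list(gain_sd = 0.03, shift_cols = 0L, shift_bscans = 0L),
      cohort_n = 231L,
      cohort = list()            # overrides for cohort_model()
    ),
    inputs = NULL,               # directory of volumes (disables simulate)
    segment = list(),            # overrides for segment_config()
    qc = list(min_thickness = 1, max_thickness = 80, max_jump = 15),
    stats = list(run = TRUE, decline_from = 50)
  )
}

.merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    parsed <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
    config <- parsed
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  .merge_config(pipeline_config(), config)
}

# one volume through denoise -> segment -> QC -> fovea -> ETDRS -> intensity
.process_volume <- function(vol, seg_cfg, qc_thresholds) {
  surfaces <- segment_retina(vol, seg_cfg)
  qc <- qc_surfaces(surfaces, qc_thresholds)
  if (!qc$pass) {
    return(list(ok = FALSE, qc = qc,
                reason = paste(unique(qc$flags$reason), collapse = "; ")))
  }
  center <- locate_fovea(surfaces)
  grid <- suppressWarnings(
    build_etdrs_masks(center, vol$laterality, dim(vol$voxels)[1:2], vol$spacing))
  tab <- suppressWarnings(layer_sector_intensity(vol, surfaces, grid))
  list(ok = TRUE, surfaces = surfaces, qc = qc, center = center,
       grid = grid, table = tab)
}

#' Run the full analysis pipeline from a configuration
#'
#' Simulates (or loads) macular volumes, processes each through denoising,
#' 11-surface segmentation, QC, fovea-centred ETDRS mapping and intensity
#' measurement, then runs the cohort statistics battery.  All outputs are
#' written as CSV under `out_dir`; QC-excluded volumes are logged with the
#' failing B-scans' reasons and excluded from cohort tables.  Runs are
#' deterministic for a fixed config.
#'
#' @param config configuration list or path to a YAML/JSON file; see
#'   [pipeline_config()] for the schema and defaults.
#' @return invisibly, a list with the written file paths and in-memory
#'   results (`volumes`, `intensity`, `cohort_imaging`, `stats`, `qc_log`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  seg_cfg <- do.call(segment_config, cfg$segment)
  vols <- list()
  if (!is.null(cfg$inputs)) {
    files <- list.files(cfg$inputs, pattern = "\\.(tiff?|nii)$",
                        full.names = TRUE)
    if (!length(files)) stop("no volumes found under ", cfg$inputs)
    for (f in files) {
      id <- sub("\\.(tiff?|nii)$", "", basename(f))
      vols[[id]] <- read_volume(f)
    }
  } else {
    sim <- cfg$simulate
    base_spec <- do.call(phantom_spec, sim$phantom)
    for (i in seq_len(sim$n_volumes)) {
      id <- sprintf("P%03d", i)
      spec_i <- base_spec
      gain <- .run_seeded(cfg$seed * 10000L + i,
                          rnorm(1, 1, sim$subject_gain_sd))
      spec_i$band_au <- pmin(pmax(spec_i$band_au * gain, 0), 65535)
      spec_i$vitreous_au <- min(spec_i$vitreous_au * gain, 65535)
      spec_i$choroid_au <- min(spec_i$choroid_au * gain, 65535)
      ph <- generate_phantom(spec_i, seed = cfg$seed * 10000L + 500L + i)
      ph$volume$subject_id <- id
      vols[[id]] <- ph$volume
    }
    say("simulated %d phantom volume(s)", length(vols))
  }

  qc_log <- data.frame(volume = character(), status = character(),
                       reason = character(), stringsAsFactors = FALSE)
  tables <- list()
  centers <- list()
  for (id in names(vols)) {
    res <- tryCatch(.process_volume(vols[[id]], seg_cfg, cfg$qc),
                    error = function(e) list(ok = FALSE, reason = conditionMessage(e)))
    if (!res$ok) {
      say("volume %s EXCLUDED by QC: %s", id, res$reason)
      qc_log <- rbind(qc_log, data.frame(volume = id, status = "excluded",
                                         reason = res$reason))
      next
    }
    qc_log <- rbind(qc_log, data.frame(volume = id, status = "included",
                                       reason = ""))
    tables[[id]] <- res$table
    centers[[id]] <- res$center
    p <- file.path(cfg$out_dir, sprintf("intensity_%s.csv", id))
    tbl <- res$table
    rownames(tbl) <- NULL
    tab_out <- data.frame(subject_id = id, tbl,
                          fovea_x = unname(res$center[1]),
                          fovea_y = unname(res$center[2]),
                          check.names = FALSE)
    write_table_csv(tab_out, p)
    paths <- c(paths, p)
  }
  p <- file.path(cfg$out_dir, "qc_log.csv")
  write_table_csv(qc_log, p); paths <- c(paths, p)

  cohort_img <- NULL
  if (length(tables)) {
    cohort_img <- cohort_intensity(tables)
    p <- file.path(cfg$out_dir, "cohort_imaging.csv")
    write_table_csv(cohort_img, p); paths <- c(paths, p)
  }

  stats_out <- list()
  if (isTRUE(cfg$stats$run)) {
    # imaging cohort: nasal vs temporal paired contrast per layer
    if (length(tables) >= 3) {
      pooled_side <- function(tab, layer, sides) {
        s <- tab[tab$layer == layer & tab$sector %in% sides, ]
        sum(s$mean_au * s$n_voxels) / sum(s$n_voxels)
      }
      rows <- lapply(.layers, function(l) {
        nas <- vapply(tables, pooled_side, 0, layer = l, sides = c("Nin", "Nout"))
        tem <- vapply(tables, pooled_side, 0, layer = l, sides = c("Tin", "Tout"))
        ct <- compare_groups(nas, tem, mode = "paired")
        data.frame(layer = l, nasal_mean = mean(nas), temporal_mean = mean(tem),
                   t = ct$t, p = ct$p, stringsAsFactors = FALSE)
      })
      stats_out$sector_paired <- do.call(rbind, rows)
      p <- file.path(cfg$out_dir, "sector_paired_ttest.csv")
      write_table_csv(stats_out$sector_paired, p); paths <- c(paths, p)
    }

    # operator re-scan reproducibility on simulated pairs
    if (is.null(cfg$inputs) && cfg$simulate$rescan_pairs > 0) {
      sim <- cfg$simulate
      base_spec <- do.call(phantom_spec, sim$phantom)
      ja <- do.call(rescan_jitter, sim$rescan)
      ma <- mb <- matrix(NA_real_, sim$rescan_pairs, 8,
                         dimnames = list(NULL, .layers))
      for (i in seq_len(sim$rescan_pairs)) {
        spec_i <- base_spec
        gain <- .run_seeded(cfg$seed * 20000L + i,
                            rnorm(1, 1, sim$subject_gain_sd))
        spec_i$band_au <- pmin(pmax(spec_i$band_au * gain, 0), 65535)
        pr <- generate_rescan_pair(spec_i, ja, seed = cfg$seed * 20000L + 999L + i)
        for (v in c("a", "b")) {
          res <- .process_volume(pr[[v]], seg_cfg, cfg$qc)
          if (!res$ok) next
          ci <- cohort_intensity(list(x = res$table))
          if (v == "a") ma[i, ] <- as.numeric(ci[1, .layers])
          else mb[i, ] <- as.numeric(ci[1, .layers])
        }
      }
      rows <- lapply(.layers, function(l) {
        keep <- is.finite(ma[, l]) & is.finite(mb[, l])
        ic <- icc_two_operator(ma[keep, l], mb[keep, l])
        data.frame(layer = l, operator_a = mean(ma[keep, l]),
                   operator_b = mean(mb[keep, l]),
                   icc2 = ic$icc2, icc3 = ic$icc3, p = ic$p,
                   stringsAsFactors = FALSE)
      })
      stats_out$icc <- do.call(rbind, rows)
      p <- file.path(cfg$out_dir, "icc.csv")
      write_table_csv(stats_out$icc, p); paths <- c(paths, p)
    }

    # statistical cohort: correlation screen, stepwise, age groups, sex test
    if (is.null(cfg$inputs) && cfg$simulate$cohort_n >= 10) {
      model <- do.call(cohort_model, cfg$simulate$cohort)
      coh <- generate_cohort(model, cfg$simulate$cohort_n,
                             seed = cfg$seed * 30000L + 7L)
      p <- file.path(cfg$out_dir, "cohort_subjects.csv")
      write_table_csv(coh, p); paths <- c(paths, p)

      for (meth in c("pearson", "spearman")) {
        sc <- correlation_screen(coh, method = meth)
        rmat <- sc$r
        rownames(rmat) <- NULL
        tab <- data.frame(covariate = rownames(sc$r), rmat, check.names = FALSE)
        p <- file.path(cfg$out_dir, sprintf("correlations_%s.csv", meth))
        write_table_csv(tab, p); paths <- c(paths, p)
        stats_out[[paste0("correlations_", meth)]] <- sc
      }

      covs <- c("age", "height_cm", "weight_kg", "se_d", "axial_length_mm",
                "imageQ", "disc_area_mm2", "rd_area_ratio")
      sw <- lapply(.layers, function(l) stepwise_ols(coh, l, covs))
      names(sw) <- .layers
      rows <- do.call(rbind, lapply(.layers, function(l) {
        f <- sw[[l]]
        if (!length(f$selected)) {
          return(data.frame(layer = l, predictor = NA_character_,
                            beta = NA_real_, p = NA_real_,
                            r_squared = f$r_squared))
        }
        data.frame(layer = l, predictor = f$selected,
                   beta = unname(f$beta), p = unname(f$p),
                   r_squared = f$r_squared, stringsAsFactors = FALSE)
      }))
      stats_out$stepwise <- rows
      p <- file.path(cfg$out_dir, "stepwise.csv")
      write_table_csv(rows, p); paths <- c(paths, p)

      ag <- age_group_summary(coh, decline_from = cfg$stats$decline_from)
      stats_out$age_groups <- ag
      p <- file.path(cfg$out_dir, "age_groups.csv")
      write_table_csv(ag$table, p); paths <- c(paths, p)
      p <- file.path(cfg$out_dir, "age_trend.csv")
      write_table_csv(ag$trend, p); paths <- c(paths, p)

      sex_rows <- do.call(rbind, lapply(.layers, function(l) {
        ct <- compare_groups(coh[[l]], coh$sex, mode = "independent")
        data.frame(layer = l, t = ct$t, p = ct$p, stringsAsFactors = FALSE)
      }))
      stats_out$sex_ttest <- sex_rows
      p <- file.path(cfg$out_dir, "sex_ttest.csv")
      write_table_csv(sex_rows, p); paths <- c(paths, p)
    }
  }

  writeLines(log_lines, file.path(cfg$out_dir, "pipeline_log.txt"))
  paths <- c(paths, file.path(cfg$out_dir, "pipeline_log.txt"))
  invisible(list(paths = paths, intensity = tables,
                 cohort_imaging = cohort_img, stats = stats_out,
                 qc_log = qc_log, centers = centers, config = cfg))
}
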