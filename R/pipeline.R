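# End-to-end pipeline: simulate each requested condition, push the
# synthetic data through the measurement stages, compare conditions, and
# write per-stage CSV/JSON outputs plus a run manifest.

PIPELINE_STAGES <- c("transport", "morphology", "staging", "cohort", "wd")

validate_pipeline_config <- function(cfg) {
  known <- c("version", "seed", "conditions", "stages", "sizes", "profiles_path")
  unknown <- setdiff(names(cfg), known)
  stop_field(length(unknown) == 0,
             paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  stop_field(identical(cfg$version %||% 1L, 1L) || identical(cfg$version, 1),
             "unsupported config version")
  stages <- cfg$stages %||% character(0)
  bad <- setdiff(stages, PIPELINE_STAGES)
  stop_field(length(bad) == 0,
             paste0("unknown stages: ", paste(bad, collapse = ", ")))
  sizes <- cfg$sizes %||% list()
  known_sizes <- c("n_movies", "n_mito", "n_axons", "n_cells", "n_wd_reps",
                   "axon_length_um")
  bad <- setdiff(names(sizes), known_sizes)
  stop_field(length(bad) == 0,
             paste0("unknown size keys: ", paste(bad, collapse = ", ")))
  cfg
}

pipeline_defaults <- function(sizes) {
  list(n_movies = sizes$n_movies %||% 3L,
       n_mito = sizes$n_mito %||% 8L,
       n_axons = sizes$n_axons %||% 12L,
       n_cells = sizes$n_cells %||% 6L,
       n_wd_reps = sizes$n_wd_reps %||% 11L,
       axon_length_um = sizes$axon_length_um %||% 100)
}

run_condition_stage <- function(stage, prof, sz, seed, out_dir, log) {
  tag <- paste0(prof$name, "_", stage)
  t0 <- Sys.time()
  res <- switch(stage,
    transport = {
      sums <- lapply(seq_len(sz$n_movies), function(m) {
        mv <- simulate_transport_movie(prof$transport, sim_config(),
                                       n_mito = sz$n_mito,
                                       seed = seed + 1000L * m)
        ky <- build_kymograph(mv$stack, mv$trace)
        tk <- extract_tracks(ky)
        if (nrow(tk) == 0) return(NULL)
        summarize_transport(tk)
      })
      sums <- sums[!vapply(sums, is.null, TRUE)]
      list(pct_motile = mean(vapply(sums, `[[`, 0, "pct_motile")),
           mean_anterograde_speed =
             mean(vapply(sums, `[[`, 0, "mean_anterograde_speed"), na.rm = TRUE),
           pct_time_paused =
             mean(vapply(sums, `[[`, 0, "pct_time_paused"), na.rm = TRUE))
    },
    morphology = {
      img <- simulate_morphology_image(prof$morphology, morph_sim_config(),
                                       axon_length_um = sz$axon_length_um,
                                       seed = seed + 11L)
      shp <- segment_mitochondria(img$image, img$pixel_size_um)
      s <- summarize_morphology(shp, sz$axon_length_um)
      utils::write.csv(shp, file.path(out_dir, paste0(tag, "_shapes.csv")),
                       row.names = FALSE)
      list(n_mito = s$n_mito, density_per_100um = s$density_per_100um,
           ratio_mean = s$ratio_mean)
    },
    staging = {
      co <- simulate_cohort(prof, n_cells = sz$n_axons, seed = seed + 21L)
      co <- co[co$present_at_t1, , drop = FALSE]
      rec <- stage_records(co$cell_id, 2, co$stage_t1)
      dist <- summarize_stages(rec)
      write_stage_records(rec, file.path(out_dir, paste0(tag, "_records.csv")))
      list(mean_stage = dist$mean_stage, sem_stage = dist$sem_stage,
           n = dist$n)
    },
    cohort = {
      co <- simulate_cohort(prof, n_cells = sz$n_cells, seed = seed + 31L)
      utils::write.csv(as.data.frame(co),
                       file.path(out_dir, paste0(tag, "_cohort.csv")),
                       row.names = FALSE)
      sv <- survival_percent(co)
      list(pct_survival = sv$pct_survival, n_t1 = sv$n_t1)
    },
    wd = {
      lags <- vapply(seq_len(sz$n_wd_reps), function(r) {
        s <- simulate_wd_timecourse(prof$timing, seed = seed + 41L + r)
        k <- measure_wd(s)
        if (k$censored) NA_real_ else k$lag_min
      }, 0)
      list(mean_lag_min = mean(lags, na.rm = TRUE),
           lags = lags[!is.na(lags)])
    })
  log(sprintf("[%s] %s finished in %.2f s", prof$name, stage,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full synthetic pipeline for one or more conditions
#'
#' Simulates each requested stage for each condition, runs the matching
#' measurement modules, writes per-stage outputs and a JSON report to
#' `out_dir`, and returns the report. When at least two conditions are
#' requested, the report includes cross-condition comparisons (transport
#' t-tests on lags, staging contrast). A manifest (config hash, seed,
#' output files) makes deterministic re-runs checkable.
#'
#' @param config a YAML file path or a config list with keys `seed`,
#'   `conditions` (character), `stages` (subset of transport, morphology,
#'   staging, cohort, wd), optional `sizes`, optional `profiles_path`.
#'   Unknown keys are errors.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress logging to stderr.
#' @return the report, invisibly (list with `conditions`, `comparisons`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("axodyne_run_"),
                         quiet = FALSE) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible(NULL) else
    function(msg) message(msg)
  seed <- as.integer(cfg$seed %||% 1L)
  profiles <- load_condition_profiles(cfg$profiles_path)
  conds <- cfg$conditions %||% character(0)
  missing <- setdiff(conds, names(profiles))
  stop_field(length(missing) == 0,
             paste0("unknown conditions: ", paste(missing, collapse = ", ")))
  stages <- cfg$stages %||% character(0)
  results <- list()
  for (ci in seq_along(conds)) {
    prof <- profiles[[conds[ci]]]
    res <- list()
    for (stage in stages) {
      res[[stage]] <- run_condition_stage(stage, prof,
                                          pipeline_defaults(cfg$sizes %||% list()),
                                          seed + 100000L * ci, out_dir, log)
    }
    results[[conds[ci]]] <- res
  }
  comparisons <- list()
  if (length(conds) >= 2 && "wd" %in% stages) {
    a <- results[[conds[1]]]$wd$lags; b <- results[[conds[2]]]$wd$lags
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- ttest_unpaired(a, b)
      comparisons$wd_lag <- list(conditions = conds[1:2],
                                 t = tt$statistic, p = tt$p_value)
    }
  }
  # strip bulky vectors from the report
  for (cn in names(results)) results[[cn]]$wd$lags <- NULL
  cfg_canon <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_canon, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_canon)),
    config_path = config_path,
    seed = seed,
    package_version = as.character(utils::packageVersion("axodyne")),
    outputs = list.files(out_dir)
  )
  report <- list(conditions = results, comparisons = comparisons,
                 manifest = manifest)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest$outputs <- sort(unique(c(manifest$outputs, "report.json", "manifest.json")))
  report$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
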