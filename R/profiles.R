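#' Transport kinetics profile
#'
#' Parameter set for the run/pause renewal model of axonal mitochondrial
#' movement. Dwell times in the run and pause states are exponential
#' (memoryless); each new run chooses the retrograde direction with
#' probability `prob_next_run_retrograde` and a speed from a normal
#' distribution truncated below at 0.12 um/s (just above the 0.1 um/s
#' pause threshold, so every generated run is detectable as movement).
#'
#' Under the stationary renewal process the expected fraction of time a
#' motile mitochondrion spends paused is
#' `mean_pause_duration / (mean_run_duration + mean_pause_duration)`;
#' `target_time_fraction_paused` records that target explicitly and the
#' constructor checks the two are consistent.
#'
#' @param motile_fraction probability that a mitochondrion is motile.
#' @param anterograde_run_speed_mean,anterograde_run_speed_sd um/s.
#' @param retrograde_run_speed_mean,retrograde_run_speed_sd um/s.
#' @param mean_run_duration,mean_pause_duration seconds.
#' @param prob_next_run_retrograde probability a run is retrograde.
#' @param target_time_fraction_paused expected paused time fraction of
#'   motile mitochondria.
#' @return object of class `transport_profile`.
#' @export
transport_profile <- function(motile_fraction,
                              anterograde_run_speed_mean, anterograde_run_speed_sd,
                              retrograde_run_speed_mean, retrograde_run_speed_sd,
                              mean_run_duration, mean_pause_duration,
                              prob_next_run_retrograde,
                              target_time_fraction_paused) {
  stop_field(is_prob(motile_fraction), "motile_fraction must be in [0,1]")
  stop_field(is_prob(prob_next_run_retrograde), "prob_next_run_retrograde must be in [0,1]")
  stop_field(is_prob(target_time_fraction_paused), "target_time_fraction_paused must be in [0,1]")
  stop_field(anterograde_run_speed_mean > 0 && retrograde_run_speed_mean > 0,
             "run speeds must be > 0")
  stop_field(anterograde_run_speed_sd >= 0 && retrograde_run_speed_sd >= 0,
             "speed sds must be >= 0")
  stop_field(mean_run_duration > 0 && mean_pause_duration > 0, "durations must be > 0")
  implied <- mean_pause_duration / (mean_run_duration + mean_pause_duration)
  if (abs(implied - target_time_fraction_paused) > 0.02)
    warning("mean dwell times imply a paused time fraction of ",
            round(implied, 3), " but target_time_fraction_paused is ",
            target_time_fraction_paused)
  structure(list(
    motile_fraction = motile_fraction,
    anterograde_run_speed_mean = anterograde_run_speed_mean,
    anterograde_run_speed_sd = anterograde_run_speed_sd,
    retrograde_run_speed_mean = retrograde_run_speed_mean,
    retrograde_run_speed_sd = retrograde_run_speed_sd,
    mean_run_duration = mean_run_duration,
    mean_pause_duration = mean_pause_duration,
    prob_next_run_retrograde = prob_next_run_retrograde,
    target_time_fraction_paused = target_time_fraction_paused
  ), class = "transport_profile")
}

#' Mitochondrial morphology profile
#'
#' @param density_per_100um expected mitochondria per 100 um of axon.
#' @param aspect_ratio_mean,aspect_ratio_sd length:width ratio moments
#'   (dimensionless, mean >= 1).
#' @param mito_minor_axis_um mitochondrial width (um).
#' @param swollen_fraction probability a mitochondrion is spherical
#'   (ratio ~ 1), modelling pathological swelling.
#' @return object of class `morphology_profile`.
#' @export
morphology_profile <- function(density_per_100um, aspect_ratio_mean,
                               aspect_ratio_sd, mito_minor_axis_um = 0.7,
                               swollen_fraction = 0) {
  stop_field(density_per_100um >= 0, "density must be >= 0")
  stop_field(aspect_ratio_mean >= 1, "aspect_ratio_mean must be >= 1")
  stop_field(aspect_ratio_sd >= 0, "aspect_ratio_sd must be >= 0")
  stop_field(mito_minor_axis_um > 0, "mito_minor_axis_um must be > 0")
  stop_field(is_prob(swollen_fraction), "swollen_fraction must be in [0,1]")
  structure(list(density_per_100um = density_per_100um,
                 aspect_ratio_mean = aspect_ratio_mean,
                 aspect_ratio_sd = aspect_ratio_sd,
                 mito_minor_axis_um = mito_minor_axis_um,
                 swollen_fraction = swollen_fraction),
            class = "morphology_profile")
}

#' Axonopathy progression profile
#'
#' Initial 5-point stage distribution at 2 dpf and a per-day transition
#' matrix. Degeneration is monotone: no mass may move to a lower stage.
#'
#' @param stage_probabilities_at_2dpf probability 5-vector.
#' @param stage_transition_matrix_per_day 5x5 row-stochastic matrix,
#'   upper-triangular (including diagonal).
#' @param death_given_stage5 probability that a stage-5 axon corresponds to
#'   a dead soma.
#' @return object of class `axonopathy_profile`.
#' @export
axonopathy_profile <- function(stage_probabilities_at_2dpf,
                               stage_transition_matrix_per_day,
                               death_given_stage5 = 1) {
  p <- as.numeric(stage_probabilities_at_2dpf)
  stop_field(length(p) == 5 && all(p >= 0) && abs(sum(p) - 1) < 1e-6,
             "stage_probabilities_at_2dpf must be a 5-vector summing to 1")
  m <- as.matrix(stage_transition_matrix_per_day)
  stop_field(all(dim(m) == c(5, 5)), "transition matrix must be 5x5")
  stop_field(all(m >= 0) && all(abs(rowSums(m) - 1) < 1e-6),
             "transition matrix rows must sum to 1")
  stop_field(all(m[lower.tri(m)] == 0),
             "degeneration is monotone: no transitions to lower stages")
  stop_field(is_prob(death_given_stage5), "death_given_stage5 must be in [0,1]")
  structure(list(stage_probabilities_at_2dpf = p,
                 stage_transition_matrix_per_day = m,
                 death_given_stage5 = death_given_stage5),
            class = "axonopathy_profile")
}

#' Degeneration timing profile
#'
#' Truncated-normal (at zero) parameters for the Wallerian lag
#' (transection to fragmentation) and clearance (fragmentation to loss of
#' all debris) intervals, the lead time of axonopathy onset before soma
#' death, and the imaging cadence.
#'
#' @param lag_mean,lag_sd minutes.
#' @param clearance_mean,clearance_sd minutes.
#' @param axonopathy_onset_lead_hours hours by which stage >= 2 precedes
#'   soma death.
#' @param sampling_interval minutes between frames.
#' @return object of class `timing_profile`.
#' @export
timing_profile <- function(lag_mean, lag_sd, clearance_mean, clearance_sd,
                           axonopathy_onset_lead_hours, sampling_interval = 30) {
  stop_field(lag_mean > 0 && clearance_mean > 0, "means must be > 0")
  stop_field(lag_sd >= 0 && clearance_sd >= 0, "sds must be >= 0")
  stop_field(axonopathy_onset_lead_hours > 0, "onset lead must be > 0")
  stop_field(sampling_interval > 0, "sampling_interval must be > 0")
  structure(list(lag_mean = lag_mean, lag_sd = lag_sd,
                 clearance_mean = clearance_mean, clearance_sd = clearance_sd,
                 axonopathy_onset_lead_hours = axonopathy_onset_lead_hours,
                 sampling_interval = sampling_interval),
            class = "timing_profile")
}

#' Full experimental-condition profile
#'
#' Bundles the transport, morphology, axonopathy and timing parameter sets
#' for one condition (WT, aSyn, aSyn+WldS, aSyn+PGC1a) together with the
#' 2-to-3 dpf per-cell survival probability and the rate at which new cells
#' begin expressing the reporter during the observation window (which is
#' why survival percentages may exceed 100).
#'
#' @param name condition label.
#' @param transport a [transport_profile()].
#' @param morphology a [morphology_profile()].
#' @param axonopathy an [axonopathy_profile()].
#' @param timing a [timing_profile()].
#' @param survival_2to3dpf per-cell survival probability.
#' @param new_expression_rate per-cell probability of a new reporter-positive
#'   cell appearing by the second timepoint.
#' @return object of class `condition_profile`.
#' @export
condition_profile <- function(name, transport, morphology, axonopathy, timing,
                              survival_2to3dpf, new_expression_rate = 0) {
  stop_field(is.character(name) && length(name) == 1L, "name must be a string")
  stopifnot(inherits(transport, "transport_profile"),
            inherits(morphology, "morphology_profile"),
            inherits(axonopathy, "axonopathy_profile"),
            inherits(timing, "timing_profile"))
  stop_field(is_prob(survival_2to3dpf), "survival_2to3dpf must be in [0,1]")
  stop_field(is_prob(new_expression_rate), "new_expression_rate must be in [0,1]")
  structure(list(name = name, transport = transport, morphology = morphology,
                 axonopathy = axonopathy, timing = timing,
                 survival_2to3dpf = survival_2to3dpf,
                 new_expression_rate = new_expression_rate),
            class = "condition_profile")
}

#' Imaging simulation configuration
#'
#' Optics and acquisition settings of the synthetic microscope. Defaults
#' match the acquisition used for transport movies: 1 frame per second for
#' 6 minutes over a 50-um axon segment at confocal 40x / 3x-zoom scale.
#'
#' @param pixel_size_um um per pixel.
#' @param frame_interval_s seconds between frames.
#' @param movie_duration_s total movie duration (s).
#' @param segment_length_um imaged axon segment length (um).
#' @param noise_sigma additive Gaussian noise SD (8-bit intensity units).
#' @param psf_sigma_um point-spread-function sigma (um).
#' @param rng_seed optional default seed carried with the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(pixel_size_um = 0.2, frame_interval_s = 1,
                       movie_duration_s = 360, segment_length_um = 50,
                       noise_sigma = 4, psf_sigma_um = 0.3, rng_seed = NULL) {
  stop_field(pixel_size_um > 0, "pixel_size_um must be > 0")
  stop_field(frame_interval_s > 0, "frame_interval_s must be > 0")
  n_frames <- floor(movie_duration_s / frame_interval_s)
  stop_field(n_frames >= 2, "movie_duration_s / frame_interval_s must give >= 2 frames")
  stop_field(segment_length_um > 0, "segment_length_um must be > 0")
  stop_field(noise_sigma >= 0, "noise_sigma must be >= 0")
  stop_field(psf_sigma_um > 0, "psf_sigma_um must be > 0")
  structure(list(pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
                 movie_duration_s = movie_duration_s,
                 segment_length_um = segment_length_um, noise_sigma = noise_sigma,
                 psf_sigma_um = psf_sigma_um, rng_seed = rng_seed),
            class = "sim_config")
}

profile_from_list <- function(x) {
  condition_profile(
    name = x$name,
    transport = do.call(transport_profile, x$transport),
    morphology = do.call(morphology_profile, x$morphology),
    axonopathy = axonopathy_profile(
      stage_probabilities_at_2dpf = as.numeric(x$axonopathy$stage_probabilities_at_2dpf),
      stage_transition_matrix_per_day =
        matrix(unlist(x$axonopathy$stage_transition_matrix_per_day),
               nrow = 5, byrow = TRUE),
      death_given_stage5 = x$axonopathy$death_given_stage5 %||% 1
    ),
    timing = do.call(timing_profile, x$timing),
    survival_2to3dpf = x$survival_2to3dpf,
    new_expression_rate = x$new_expression_rate %||% 0
  )
}

#' Load the shipped (or a user) condition-profile configuration
#'
#' Reads a YAML file describing one [condition_profile()] per experimental
#' condition. The configuration shipped with the package encodes the
#' published WT, aSyn, aSyn+WldS and aSyn+PGC1a summary statistics as
#' generator targets.
#'
#' @param path YAML file; defaults to the shipped configuration.
#' @return named list of `condition_profile` objects.
#' @export
load_condition_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "condition_profiles.yaml",
                                package = "axodyne", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  stop_field(!is.null(raw$conditions), "profile YAML must have a 'conditions' list")
  out <- lapply(raw$conditions, profile_from_list)
  names(out) <- vapply(out, `[[`, "", "name")
  stop_field(!anyDuplicated(names(out)), "condition names must be unique")
  out
}
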