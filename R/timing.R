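#' Measure Wallerian-degeneration kinetics from a sampled event series
#'
#' Lag is the time of the first frame in which axonal continuity is broken
#' (at least 2 fragments); clearance is the additional time until the
#' first frame with a debris fraction below `debris_cleared`.
#' Fragmentation is synchronous if the fragment count jumps from one
#' (continuous) to its maximum within a single sampling interval. Both
#' intervals are therefore non-negative multiples of the sampling
#' interval; over many replicates the measured lag carries an average
#' quantization bias of half an interval, which
#' `wd_lag_bias_correction()` returns for bias-corrected means.
#'
#' @param series an event series data.frame (`time_min`,
#'   `debris_fraction`, `n_fragments`) beginning at transection (t = 0),
#'   uniformly sampled, >= 3 frames.
#' @param debris_cleared debris fraction counted as fully cleared
#'   (default 0.05).
#' @return object of class `wd_kinetics`: `lag_min`, `clearance_min`,
#'   `synchronous`, `censored` (no fragmentation observed ->
#'   right-censored, lag and clearance `NA`).
#' @export
measure_wd <- function(series, debris_cleared = 0.05) {
  stop_field(nrow(series) >= 3, "need >= 3 frames")
  tms <- series$time_min
  dts <- diff(tms)
  stop_field(all(dts > 0) && diff(range(dts)) < 1e-9,
             "times must be strictly increasing and uniformly spaced")
  stop_field(abs(tms[1]) < 1e-9, "series must begin at transection (t = 0)")
  stop_field(all(series$debris_fraction >= 0 & series$debris_fraction <= 1),
             "debris_fraction must lie in [0,1]")
  i_frag <- which(series$n_fragments >= 2L)[1]
  if (is.na(i_frag)) {
    return(structure(list(lag_min = NA_real_, clearance_min = NA_real_,
                          synchronous = NA, censored = TRUE),
                     class = "wd_kinetics"))
  }
  lag <- tms[i_frag]
  nf <- series$n_fragments
  synchronous <- (i_frag == 1L || nf[i_frag - 1L] <= 1L) &&
    nf[i_frag] == max(nf)
  i_clear <- which(series$debris_fraction < debris_cleared & tms >= lag)[1]
  clearance <- if (is.na(i_clear)) NA_real_ else tms[i_clear] - lag
  structure(list(lag_min = lag, clearance_min = clearance,
                 synchronous = synchronous, censored = FALSE),
            class = "wd_kinetics")
}

#' @export
print.wd_kinetics <- function(x, ...) {
  if (x$censored) {
    cat("<wd_kinetics> right-censored: no fragmentation observed\n")
  } else {
    cat(sprintf("<wd_kinetics> lag %.4g min | clearance %s min | %s fragmentation\n",
                x$lag_min,
                if (is.na(x$clearance_min)) "censored" else sprintf("%.4g", x$clearance_min),
                if (isTRUE(x$synchronous)) "synchronous" else "asynchronous"))
  }
  invisible(x)
}

#' Mean quantization bias of the measured lag
#'
#' Sampling every `sampling_interval` minutes rounds each event time up to
#' the next frame; for event times smooth on the interval scale the mean
#' measured lag exceeds the true mean by half an interval.
#'
#' @param sampling_interval minutes between frames.
#' @return minutes to subtract from a mean of measured lags.
#' @export
wd_lag_bias_correction <- function(sampling_interval) sampling_interval / 2

#' Order axonopathy onset, fragmentation and soma death in time
#'
#' Given per-frame axonopathy stages and soma status on a shared timebase,
#' reports the first time at stage >= 2 (swelling/beading onset), the
#' first time at stage >= 4 (fragmentation), the time of soma death, and
#' whether each axonal event preceded death. Events never observed are
#' reported as `NA` and flagged censored.
#'
#' @param stage_series integer stages per frame.
#' @param soma_series logical soma-alive per frame.
#' @param times frame times (e.g. minutes); defaults to frame index.
#' @return object of class `onset_ordering`.
#' @export
onset_ordering <- function(stage_series, soma_series, times = NULL) {
  stop_field(length(stage_series) == length(soma_series),
             "stage and soma series must share a timebase")
  times <- times %||% seq_along(stage_series)
  t_swell <- times[which(stage_series >= 2L)[1]][1]
  t_frag <- times[which(stage_series >= 4L)[1]][1]
  t_death <- times[which(!soma_series)[1]][1]
  death_censored <- is.na(t_death)
  structure(list(
    t_first_stage2 = t_swell,
    t_first_stage4 = t_frag,
    t_soma_death = t_death,
    death_censored = death_censored,
    swelling_before_death = if (death_censored) NA else
      (!is.na(t_swell) && t_swell < t_death),
    fragmentation_before_death = if (death_censored) NA else
      (!is.na(t_frag) && t_frag < t_death)
  ), class = "onset_ordering")
}

#' @export
print.onset_ordering <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "censored" else sprintf("%.4g", v)
  cat(sprintf("<onset_ordering> stage>=2 at %s | stage>=4 at %s | death at %s\n",
              fmt(x$t_first_stage2), fmt(x$t_first_stage4), fmt(x$t_soma_death)))
  if (!x$death_censored)
    cat(sprintf("  swelling before death: %s | fragmentation before death: %s\n",
                x$swelling_before_death, x$fragmentation_before_death))
  invisible(x)
}
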