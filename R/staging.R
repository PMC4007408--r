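#' Numeric thresholds for the 5-point axonopathy staging rubric
#'
#' Operational thresholds for scoring a 1D axon intensity profile:
#' stage 1 smooth and continuous, stage 2 mild beading, stage 3 severe
#' beading and/or large varicosities, stage 4 partial fragmentation,
#' stage 5 complete degeneration (or soma death). All thresholds are
#' configurable; the defaults reconstruct the rubric from its qualitative
#' descriptors.
#'
#' @param smoothness_cv_max maximum coefficient of variation for a smooth
#'   (stage-1) profile.
#' @param bead_density_mild_max beads per 100 um separating mild (stage 2)
#'   from severe (stage 3) beading.
#' @param varicosity_width_min um; a bead at least this wide is a large
#'   varicosity (stage 3).
#' @param gap_fraction_partial minimum fraction of length in gaps for
#'   partial fragmentation (stage 4).
#' @param loss_fraction_complete minimum fraction of length lost for
#'   complete degeneration (stage 5), default 0.9.
#' @return object of class `staging_thresholds`.
#' @export
staging_thresholds <- function(smoothness_cv_max = 0.3,
                               bead_density_mild_max = 10,
                               varicosity_width_min = 3,
                               gap_fraction_partial = 0.1,
                               loss_fraction_complete = 0.9) {
  stop_field(gap_fraction_partial > 0 && gap_fraction_partial < loss_fraction_complete &&
               loss_fraction_complete <= 1,
             "need 0 < gap_fraction_partial < loss_fraction_complete <= 1")
  stop_field(smoothness_cv_max > 0 && bead_density_mild_max > 0 &&
               varicosity_width_min > 0, "thresholds must be > 0")
  structure(list(smoothness_cv_max = smoothness_cv_max,
                 bead_density_mild_max = bead_density_mild_max,
                 varicosity_width_min = varicosity_width_min,
                 gap_fraction_partial = gap_fraction_partial,
                 loss_fraction_complete = loss_fraction_complete),
            class = "staging_thresholds")
}

# Bead detection: local maxima at least 2x the local (rolling-median)
# intensity; width measured at half-prominence above the local median.
# The local reference is capped at the global median so that a wide
# varicosity filling most of an (edge-truncated) window cannot raise the
# reference enough to mask genuine beads beside it.
find_beads <- function(p, step_um, window_um = 30) {
  n <- length(p)
  win <- max(3L, 2L * floor(window_um / step_um / 2) + 1L)
  win <- min(win, if (n %% 2L == 1L) n else n - 1L)
  med <- pmin(as.numeric(stats::runmed(p, win, endrule = "median")),
              stats::median(p))
  left <- c(-Inf, p[-n]); right <- c(p[-1], -Inf)
  peak <- which(p >= 2 * pmax(med, 1e-12) & p > left & p >= right)
  if (!length(peak)) return(data.frame(pos_um = numeric(0), width_um = numeric(0)))
  # merge peaks closer than 1 um (plateau/shoulder duplicates)
  keep <- peak[c(TRUE, diff(peak) * step_um >= 1)]
  widths <- vapply(keep, function(i) {
    half <- (p[i] + med[i]) / 2
    l <- i; while (l > 1 && p[l - 1] > half) l <- l - 1
    r <- i; while (r < n && p[r + 1] > half) r <- r + 1
    (r - l + 1) * step_um
  }, 0)
  data.frame(pos_um = (keep - 0.5) * step_um, width_um = widths)
}

#' Assign the 5-point axonopathy stage to an axon intensity profile
#'
#' Decision cascade (highest stage wins): soma death or loss of more than
#' `loss_fraction_complete` of the length is stage 5; a below-signal gap
#' fraction of at least `gap_fraction_partial` is stage 4; bead density
#' above `bead_density_mild_max` per 100 um or any varicosity at least
#' `varicosity_width_min` wide is stage 3; any beads at all is stage 2;
#' a smooth profile (CV at most `smoothness_cv_max`) is stage 1. The
#' signal/gap cut is relative (30% of the 98th intensity percentile), so
#' staging is invariant to rescaling the profile by a positive constant.
#'
#' @param profile numeric intensity vs arc length, as produced by
#'   [simulate_axon_profile()] (attributes `step_um` used if present).
#' @param thresholds a [staging_thresholds()].
#' @param soma_alive is the cell body alive? Dead somata score stage 5.
#' @param step_um arc-length step of the profile (um), if not an attribute.
#' @return integer stage 1-5.
#' @export
stage_axon <- function(profile, thresholds = staging_thresholds(),
                       soma_alive = TRUE, step_um = NULL) {
  step <- step_um %||% attr(profile, "step_um")
  stop_field(!is.null(step) && step > 0, "supply step_um for the profile")
  p <- as.numeric(profile)
  stop_field(length(p) * step >= 10, "profile must cover >= 10 um")
  if (!soma_alive) return(5L)
  mx <- max(p)
  if (mx <= 0) {
    warning("all-zero profile with a live soma; scoring stage 5")
    return(5L)
  }
  thr_sig <- 0.3 * as.numeric(stats::quantile(p, 0.98))
  above <- p > thr_sig
  frac_above <- mean(above)
  if (frac_above < 1 - thresholds$loss_fraction_complete) return(5L)
  gap_frac <- 1 - frac_above
  if (gap_frac >= thresholds$gap_fraction_partial) return(4L)
  beads <- find_beads(p, step)
  L_um <- length(p) * step
  bead_density <- 100 * nrow(beads) / L_um
  if (bead_density > thresholds$bead_density_mild_max ||
      any(beads$width_um >= thresholds$varicosity_width_min)) return(3L)
  if (nrow(beads) > 0) return(2L)
  cv <- stats::sd(p) / mean(p)
  if (cv <= thresholds$smoothness_cv_max) 1L else 2L
}

#' Per-cell stage record table
#'
#' @param cell_id labels.
#' @param timepoint numeric dpf, one per record.
#' @param stage integer 1-5.
#' @param soma_alive logical; records with a dead soma must be stage 5.
#' @return data.frame of class `stage_records`.
#' @export
stage_records <- function(cell_id, timepoint, stage, soma_alive = TRUE) {
  d <- data.frame(cell_id = as.character(cell_id), timepoint = timepoint,
                  stage = as.integer(stage),
                  soma_alive = rep_len(soma_alive, length(cell_id)))
  stop_field(all(d$stage %in% 1:5), "stages must be in 1..5")
  stop_field(all(d$stage[!d$soma_alive] == 5L),
             "records with a dead soma must be stage 5")
  class(d) <- c("stage_records", "data.frame")
  d
}

#' Summarize a stage distribution at one timepoint
#'
#' Counts, fractions, mean stage and s.e.m. (sample SD / sqrt(n)).
#'
#' @param records a [stage_records()] data.frame (single timepoint).
#' @return object of class `stage_distribution`.
#' @export
summarize_stages <- function(records) {
  stop_field(nrow(records) >= 1, "need >= 1 record")
  stop_field(length(unique(records$timepoint)) == 1L,
             "records span several timepoints; summarize one at a time")
  counts <- tabulate(records$stage, 5L)
  n <- sum(counts)
  stages <- records$stage
  structure(list(
    counts = counts, n = n,
    fractions = 100 * counts / n,
    mean_stage = mean(stages),
    sem_stage = if (n > 1) stats::sd(stages) / sqrt(n) else 0,
    timepoint = records$timepoint[1]
  ), class = "stage_distribution")
}

#' @export
print.stage_distribution <- function(x, ...) {
  cat(sprintf("<stage_distribution> n = %d at %.3g dpf | mean stage %.2f +/- %.2f\n",
              x$n, x$timepoint, x$mean_stage, x$sem_stage))
  cat("  counts (stage 1..5):", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' Fraction of records at or above a stage
#'
#' @param dist a [summarize_stages()] result.
#' @param stage_min lower stage bound (inclusive).
#' @return percentage in `[0, 100]`.
#' @export
stage_fraction_at_or_above <- function(dist, stage_min) {
  stop_field(stage_min %in% 1:5, "stage_min must be in 1..5")
  100 * sum(dist$counts[stage_min:5]) / dist$n
}

#' Read / write stage records as CSV
#' @param path CSV path.
#' @export
read_stage_records <- function(path) {
  d <- utils::read.csv(path)
  stage_records(d$cell_id, d$timepoint, d$stage, d$soma_alive)
}

#' @rdname read_stage_records
#' @param records a [stage_records()] table.
#' @export
write_stage_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
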