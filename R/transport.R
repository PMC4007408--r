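#' Motility criterion
#'
#' A mitochondrion counts as moving only if it travels at least
#' `min_travel_um` in a single run at a run speed of at least
#' `min_speed_um_s`. The speed threshold doubles as the pause cutoff in
#' run segmentation.
#'
#' @param min_travel_um minimum single-run excursion (um), default 2.
#' @param min_speed_um_s minimum run speed (um/s), default 0.1.
#' @return object of class `motility_criterion`.
#' @export
motility_criterion <- function(min_travel_um = 2, min_speed_um_s = 0.1) {
  stop_field(min_travel_um > 0 && min_speed_um_s > 0,
             "criterion thresholds must be > 0")
  structure(list(min_travel_um = min_travel_um,
                 min_speed_um_s = min_speed_um_s),
            class = "motility_criterion")
}

#' Extract mitochondrial tracks from a kymograph
#'
#' Decomposes the kymograph into a static and a moving component before
#' tracking. The per-column temporal median isolates ridges that are
#' vertical for most of the movie (stationary mitochondria); each static
#' ridge becomes one full-length track followed frame-by-frame within a
#' small window. Moving objects are then detected as per-row local maxima
#' of the static-subtracted residual above a threshold, so a moving ridge
#' never competes with the stationary ridge it crosses. Residual
#' detections are linked by greedy nearest-neighbour assignment against a
#' constant-velocity prediction (maximum jump `max_jump_um` per frame,
#' ties by smallest distance then lowest track id); detection gaps up to
#' `max_gap_frames` are bridged by linear interpolation, fragments
#' separated by a longer occlusion (a mover pausing on top of another
#' mitochondrion) are stitched back together when the implied drift is
#' below the pause threshold, and tracks spanning fewer than `min_frames`
#' frames are discarded.
#'
#' @param kymo a [build_kymograph()] result.
#' @param threshold intensity threshold; default Otsu on the smoothed
#'   kymograph.
#' @param max_jump_um maximum per-frame displacement when linking.
#' @param max_gap_frames maximum bridged detection gap (frames); the
#'   default accommodates the few-frame occlusion of two crossing movers.
#' @param min_frames minimum track length (frames).
#' @param min_sep_um non-maximum-suppression radius: a detection weaker
#'   than another within this distance is discarded (PSF flank noise).
#' @return data.frame of class `track_table`: mito_id, frame, time_s,
#'   position_um, interpolated.
#' @export
extract_tracks <- function(kymo, threshold = NULL, max_jump_um = 1.5,
                           max_gap_frames = 12L, min_frames = 10L,
                           min_sep_um = 0.5) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$matrix
  stop_field(nrow(m) >= 2, "kymograph must have >= 2 rows")
  nr <- nrow(m); nc <- ncol(m)
  bs <- kymo$bin_size_um
  # light smoothing along the spatial axis
  ms <- m
  if (nc >= 3)
    ms[, 2:(nc - 1)] <- (m[, 1:(nc - 2)] + m[, 2:(nc - 1)] + m[, 3:nc]) / 3
  thr <- threshold %||% otsu_threshold(ms)
  min_sep_bins <- max(1L, round(min_sep_um / bs))

  ## --- static component: ridges vertical for most of the movie -------
  static_prof <- apply(ms, 2, stats::median)
  sp <- local_maxima(static_prof, thr, min_sep_bins * 2L)
  tracks <- list()
  win <- 2L   # tight follow window: a passing mover may not drag the
              # static position by more than ~2 bins
  for (b0 in sp) {
    cols <- max(1L, b0 - win):min(nc, b0 + win)
    pos <- cols[max.col(ms[, cols, drop = FALSE], ties.method = "first")]
    pos <- pos + subbin_offset(ms, seq_len(nr), pos)
    tracks[[length(tracks) + 1L]] <-
      list(frames = seq_len(nr), bins = as.numeric(pos))
  }

  ## --- moving component: track the static-subtracted residual --------
  resid <- ms - matrix(static_prof, nr, nc, byrow = TRUE)
  thr_res <- 0.5 * thr
  open_ids <- integer(0)      # indices into `tracks` still linkable
  last_bin <- numeric(0); last_frame <- integer(0); vel <- numeric(0)
  n_static <- length(tracks)
  for (f in seq_len(nr)) {
    ipk <- local_maxima(resid[f, ], thr_res, min_sep_bins)
    peaks <- ipk + subbin_offset(resid, rep(f, length(ipk)), ipk)
    # expire stale tracks
    if (length(open_ids)) {
      stale <- (f - last_frame) > (max_gap_frames + 1L)
      open_ids <- open_ids[!stale]
      last_bin <- last_bin[!stale]; last_frame <- last_frame[!stale]
      vel <- vel[!stale]
    }
    assigned_peak <- rep(FALSE, length(peaks))
    if (length(open_ids) && length(peaks)) {
      gap <- f - last_frame                       # >= 1
      pred <- last_bin + vel * gap
      d_um <- abs(outer(pred, peaks, `-`)) * bs
      # rank candidates by distance to the constant-velocity prediction,
      # but gate on the better of prediction and last position so a
      # sharp run reversal (prediction overshoots) still links
      d_last <- abs(outer(last_bin, peaks, `-`)) * bs
      allow <- pmin(d_um, d_last) <= max_jump_um * pmin(gap, 4)
      ord <- order(d_um)
      used_tr <- rep(FALSE, length(open_ids))
      for (k in ord) {
        if (!allow[k]) next
        i <- (k - 1L) %% length(open_ids) + 1L
        j <- (k - 1L) %/% length(open_ids) + 1L
        if (used_tr[i] || assigned_peak[j]) next
        used_tr[i] <- TRUE; assigned_peak[j] <- TRUE
        id <- open_ids[i]
        tr <- tracks[[id]]
        tr$frames <- c(tr$frames, f); tr$bins <- c(tr$bins, peaks[j])
        tracks[[id]] <- tr
        n <- length(tr$bins)
        k3 <- min(3L, n - 1L)
        vel[i] <- if (k3 >= 1)
          (tr$bins[n] - tr$bins[n - k3]) / (tr$frames[n] - tr$frames[n - k3])
        else 0
        last_bin[i] <- peaks[j]; last_frame[i] <- f
      }
    }
    # unmatched peaks start new tracks
    for (j in which(!assigned_peak)) {
      tracks[[length(tracks) + 1L]] <- list(frames = f, bins = peaks[j])
      open_ids <- c(open_ids, length(tracks))
      last_bin <- c(last_bin, peaks[j])
      last_frame <- c(last_frame, f)
      vel <- c(vel, 0)
    }
  }
  if (!length(tracks)) return(empty_track_table())
  mobile <- if (length(tracks) > n_static)
    stitch_fragments(tracks[(n_static + 1L):length(tracks)], bs,
                     kymo$frame_interval_s)
  else list()
  tracks <- c(tracks[seq_len(n_static)], mobile)
  is_static <- seq_along(tracks) <= n_static
  # bridge gaps, convert, filter
  out <- list(); id_out <- 0L
  kept_static <- logical(0); kept_span <- list()
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    if (length(tr$frames) < 2L) next
    full <- tr$frames[1]:tr$frames[length(tr$frames)]
    if (length(full) < min_frames) next
    interp <- stats::approx(tr$frames, tr$bins, xout = full)$y
    id_out <- id_out + 1L
    kept_static[id_out] <- is_static[ti]
    kept_span[[id_out]] <- range(full)
    out[[id_out]] <- data.frame(
      mito_id = id_out, frame = full,
      time_s = (full - 1) * kymo$frame_interval_s,
      position_um = (interp - 0.5) * bs,
      interpolated = !(full %in% tr$frames)
    )
  }
  if (!length(out)) return(empty_track_table())
  # identity-insensitive organelle grouping: residual fragments that are
  # disjoint in time may be (and usually are) the same mitochondrion, so
  # the minimal consistent organelle count assigns them to groups by
  # interval partitioning; crossings may still swap identities within a
  # group, which summary statistics do not depend on
  group <- integer(id_out)
  group[kept_static] <- seq_len(sum(kept_static))
  mob_idx <- which(!kept_static)
  if (length(mob_idx)) {
    ordm <- mob_idx[order(vapply(kept_span[mob_idx], `[`, 0, 1))]
    L_um <- nc * bs
    g_end <- numeric(0)
    g_base <- sum(kept_static)
    for (ti in ordm) {
      sp_t <- kept_span[[ti]]
      open <- which(g_end < sp_t[1])
      if (length(open)) {
        g <- open[which.max(g_end[open])]
      } else {
        g_end <- c(g_end, -Inf); g <- length(g_end)
      }
      d <- out[[ti]]
      exit_pos <- d$position_um[nrow(d)]
      # a fragment that runs off the end of the segment is gone for good:
      # nothing later may continue its group
      g_end[g] <- if (min(exit_pos, L_um - exit_pos) < 1.2) Inf else sp_t[2]
      group[ti] <- g_base + g
    }
  }
  for (i in seq_len(id_out)) out[[i]]$group_id <- group[i]
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("track_table", "data.frame")
  attr(res, "frame_interval_s") <- kymo$frame_interval_s
  res
}

# Three-point parabolic sub-bin localization around integer maxima:
# offset = (l - r) / (2 (l - 2 c + r)), clamped to half a bin.
subbin_offset <- function(mat, rows, cols) {
  if (!length(cols)) return(numeric(0))
  nc <- ncol(mat)
  ok <- cols > 1L & cols < nc
  off <- numeric(length(cols))
  if (any(ok)) {
    l <- mat[cbind(rows[ok], cols[ok] - 1L)]
    c0 <- mat[cbind(rows[ok], cols[ok])]
    r <- mat[cbind(rows[ok], cols[ok] + 1L)]
    den <- l - 2 * c0 + r
    o <- ifelse(abs(den) < 1e-9, 0, (l - r) / (2 * den))
    off[ok] <- clamp(o, -0.5, 0.5)
  }
  off
}

# Local maxima of a vector above a threshold with non-maximum
# suppression at `min_sep` elements (strongest kept).
local_maxima <- function(v, thr, min_sep = 1L) {
  n <- length(v)
  if (n < 2) return(integer(0))
  left <- c(-Inf, v[-n]); right <- c(v[-1], -Inf)
  cand <- which(v > thr & v > left & v >= right)
  if (length(cand) <= 1L || min_sep <= 1L) return(cand)
  o <- cand[order(-v[cand])]
  kept <- integer(0)
  for (p in o) if (!length(kept) || min(abs(kept - p)) >= min_sep)
    kept <- c(kept, p)
  sort(kept)
}

# Rejoin track fragments separated by a long occlusion. When a moving
# mitochondrion pauses on top of (or right next to) another for longer
# than the bridgeable gap, only one peak survives and the losing track
# dies; it resumes as a new fragment departing from nearly the same
# position. A fragment starting within `tol_um` of where an earlier
# track ended, no more than `max_gap_frames` later, and with an implied
# drift below the pause threshold (so stitching can only ever bridge a
# stationary interval, never fabricate a run) is appended to it; the
# occluded interval is interpolated and reads as a pause at the merge
# site - the true state during such an occlusion.
stitch_fragments <- function(tracks, bin_size_um, frame_interval_s = 1,
                             tol_um = 1.8, max_gap_frames = 240L,
                             max_drift_um_s = 0.3) {
  if (length(tracks) < 2) return(tracks)
  starts <- vapply(tracks, function(t) t$frames[1], 0)
  ord <- order(starts)
  alive <- rep(TRUE, length(tracks))
  for (bi in ord) {
    if (starts[bi] == min(starts)) next
    b <- tracks[[bi]]
    b_start <- b$frames[1]; b_pos <- b$bins[1]
    best <- NA_integer_; best_cost <- Inf
    for (ai in seq_along(tracks)) {
      if (ai == bi || !alive[ai]) next
      a <- tracks[[ai]]
      a_end <- a$frames[length(a$frames)]
      if (a_end >= b_start || b_start - a_end > max_gap_frames) next
      dpos <- abs(b_pos - a$bins[length(a$bins)]) * bin_size_um
      if (dpos > tol_um) next
      drift <- dpos / ((b_start - a_end) * frame_interval_s)
      if (drift > max_drift_um_s) next
      cost <- (b_start - a_end) + dpos
      if (cost < best_cost) { best_cost <- cost; best <- ai }
    }
    if (!is.na(best)) {
      a <- tracks[[best]]
      a$frames <- c(a$frames, b$frames)
      a$bins <- c(a$bins, b$bins)
      tracks[[best]] <- a
      alive[bi] <- FALSE
    }
  }
  tracks[alive]
}

empty_track_table <- function() {
  d <- data.frame(mito_id = integer(0), frame = integer(0),
                  time_s = numeric(0), position_um = numeric(0),
                  interpolated = logical(0))
  class(d) <- c("track_table", "data.frame")
  d
}

track_frame_interval <- function(track, frame_interval_s = NULL) {
  frame_interval_s %||% attr(track, "frame_interval_s") %||% {
    dt <- diff(sort(unique(track$time_s)))
    if (length(dt)) min(dt) else 1
  }
}

#' Segment a track into runs and pauses
#'
#' Each frame's speed is the smaller of its two adjacent displacement
#' rates - a conservative 3-sample window that is robust to single-frame
#' localization jitter and attributes run/pause transition frames to the
#' pause. Frames below `min_speed_um_s` are paused; maximal
#' constant-sign excursions between pauses form runs. Run speed is the
#' least-squares slope of position against time over the run (the
#' classical kymograph slope measurement), fitted without the partial
#' boundary frames.
#'
#' @param track one mitochondrion's rows of a `track_table` (>= 2 samples).
#' @param criterion a [motility_criterion()]; its speed threshold is the
#'   pause cutoff.
#' @param frame_interval_s sampling interval override.
#' @return data.frame of class `run_table`: state, start_frame, end_frame,
#'   n_frames, duration_s, displacement_um, speed_um_s.
#' @export
segment_runs <- function(track, criterion = motility_criterion(),
                         frame_interval_s = NULL) {
  stop_field(nrow(track) >= 2, "track must have >= 2 samples")
  dt <- track_frame_interval(track, frame_interval_s)
  p <- track$position_um
  n <- length(p)
  dv <- diff(p) / dt
  vmag <- numeric(n)
  vmag[1] <- abs(dv[1]); vmag[n] <- abs(dv[n - 1])
  if (n > 2) vmag[2:(n - 1)] <- pmin(abs(dv[1:(n - 2)]), abs(dv[2:(n - 1)]))
  thr <- criterion$min_speed_um_s
  paused <- vmag < thr
  # direction of moving frames: sign of the larger adjacent displacement
  dir <- integer(n)
  if (n > 2) {
    pick <- ifelse(abs(dv[1:(n - 2)]) >= abs(dv[2:(n - 1)]),
                   dv[1:(n - 2)], dv[2:(n - 1)])
    dir[2:(n - 1)] <- sign(pick)
  }
  dir[1] <- sign(dv[1]); dir[n] <- sign(dv[n - 1])
  state <- ifelse(paused, "paused",
                  ifelse(dir >= 0, "anterograde", "retrograde"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- lapply(seq_along(r$values), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    st <- r$values[k]
    # include the launch frame so run displacement spans the full excursion
    j0 <- if (st != "paused" && i0 > 1L) i0 - 1L else i0
    idx <- j0:i1
    disp <- track$position_um[i1] - track$position_um[j0]
    # boundary samples carry partial-frame displacements (the state flips
    # somewhere inside the interval); drop them from the slope fit when
    # the run is long enough, otherwise they bias speeds low
    fit_idx <- if (st != "paused" && length(idx) >= 5) idx[-c(1, length(idx))]
      else idx
    speed <- if (length(fit_idx) >= 2) {
      abs(stats::coef(stats::lm.fit(cbind(1, track$time_s[fit_idx]),
                                    track$position_um[fit_idx]))[2])
    } else vmag[i0]
    data.frame(state = st,
               start_frame = track$frame[i0], end_frame = track$frame[i1],
               n_frames = i1 - i0 + 1L,
               duration_s = (i1 - i0 + 1L) * dt,
               displacement_um = disp, speed_um_s = unname(speed))
  })
  out <- do.call(rbind, segs)
  class(out) <- c("run_table", "data.frame")
  attr(out, "frame_states") <- state
  out
}

#' Apply the motility criterion to a track
#'
#' `TRUE` iff at least one non-paused run covers `min_travel_um` or more
#' at a run speed of `min_speed_um_s` or more.
#'
#' @inheritParams segment_runs
#' @param runs optional precomputed [segment_runs()] output.
#' @return logical.
#' @export
classify_motile <- function(track, criterion = motility_criterion(),
                            runs = NULL, frame_interval_s = NULL) {
  runs <- runs %||% segment_runs(track, criterion, frame_interval_s)
  mv <- runs[runs$state != "paused", , drop = FALSE]
  any(abs(mv$displacement_um) >= criterion$min_travel_um &
        mv$speed_um_s >= criterion$min_speed_um_s)
}

#' Transport summary statistics for a set of tracks
#'
#' Computes the published transport panel: percent motile (over all
#' tracks), per-direction time fractions and percent distance retrograde
#' (motile mitochondria only, averaged per mitochondrion and then across
#' mitochondria, weighting each organelle equally), and mean run speeds
#' over uninterrupted runs.
#'
#' @param tracks a `track_table` (all mitochondria, tidy).
#' @param criterion a [motility_criterion()].
#' @param frame_interval_s sampling interval override.
#' @param min_run_frames runs must span at least this many frames to
#'   contribute a speed estimate; shorter runlets have too few samples
#'   for a reliable slope. Time and distance fractions use all runs.
#' @return object of class `transport_summary`.
#' @export
summarize_transport <- function(tracks, criterion = motility_criterion(),
                                frame_interval_s = NULL,
                                min_run_frames = 4L) {
  stop_field(nrow(tracks) >= 1, "no tracks supplied")
  dt <- track_frame_interval(tracks, frame_interval_s)
  # one unit per organelle: fragments sharing a group_id (identity-
  # insensitive grouping from extract_tracks) are pooled
  gcol <- if ("group_id" %in% names(tracks)) tracks$group_id else tracks$mito_id
  per <- lapply(split(seq_len(nrow(tracks)), gcol), function(gix) {
    st <- character(0); runs_list <- list(); motile <- FALSE
    for (ix in split(gix, tracks$mito_id[gix])) {
      tr <- tracks[ix, , drop = FALSE]
      if (nrow(tr) < 2) next
      runs <- segment_runs(tr, criterion, dt)
      st <- c(st, attr(runs, "frame_states"))
      runs_list[[length(runs_list) + 1L]] <- runs
      motile <- motile || classify_motile(tr, criterion, runs = runs)
    }
    if (!length(st)) return(NULL)
    runs <- do.call(rbind, runs_list)
    mv <- runs[runs$state != "paused", , drop = FALSE]
    dist_total <- sum(abs(mv$displacement_um))
    list(motile = motile,
         t_ant = mean(st == "anterograde") * 100,
         t_ret = mean(st == "retrograde") * 100,
         t_pau = mean(st == "paused") * 100,
         d_ret = if (dist_total > 0)
           100 * sum(abs(mv$displacement_um[mv$state == "retrograde"])) / dist_total
         else NA_real_,
         ant_speeds = mv$speed_um_s[mv$state == "anterograde" &
                                      mv$n_frames >= min_run_frames],
         ret_speeds = mv$speed_um_s[mv$state == "retrograde" &
                                      mv$n_frames >= min_run_frames])
  })
  per <- per[!vapply(per, is.null, TRUE)]
  n_total <- length(per)
  stop_field(n_total >= 1, "no usable tracks")
  motile <- vapply(per, `[[`, TRUE, "motile")
  n_motile <- sum(motile)
  mot <- per[motile]
  g <- function(field) vapply(mot, `[[`, 0, field)
  res <- list(
    n_total = n_total, n_motile = n_motile,
    pct_motile = 100 * n_motile / n_total,
    pct_time_anterograde = if (n_motile) mean(g("t_ant")) else NA_real_,
    pct_time_retrograde = if (n_motile) mean(g("t_ret")) else NA_real_,
    pct_time_paused = if (n_motile) mean(g("t_pau")) else NA_real_,
    pct_distance_retrograde = if (n_motile) {
      d <- vapply(mot, `[[`, 0, "d_ret"); mean(d[!is.na(d)])
    } else NA_real_,
    mean_anterograde_speed = if (n_motile) {
      s <- unlist(lapply(mot, `[[`, "ant_speeds"))
      if (length(s)) mean(s) else NA_real_
    } else NA_real_,
    mean_retrograde_speed = if (n_motile) {
      s <- unlist(lapply(mot, `[[`, "ret_speeds"))
      if (length(s)) mean(s) else NA_real_
    } else NA_real_
  )
  structure(res, class = "transport_summary")
}

#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf("<transport_summary> %d mitochondria, %d motile (%.1f%%)\n",
              x$n_total, x$n_motile, x$pct_motile))
  if (x$n_motile > 0) {
    cat(sprintf("  %% time  antero %.1f | retro %.1f | paused %.1f\n",
                x$pct_time_anterograde, x$pct_time_retrograde, x$pct_time_paused))
    cat(sprintf("  %% distance retrograde %.1f\n", x$pct_distance_retrograde))
    cat(sprintf("  run speed antero %.3g um/s | retro %.3g um/s\n",
                x$mean_anterograde_speed, x$mean_retrograde_speed))
  } else {
    cat("  no motile mitochondria: time/distance fields undefined\n")
  }
  invisible(x)
}
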