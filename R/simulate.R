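# Synthetic-data generators. Every generator takes an explicit seed and
# returns exact ground truth alongside the rendered data, so downstream
# measurement stages can be validated against known truth.

SPEED_FLOOR_UM_S <- 0.12  # runs are truncated-normal above this, i.e. always
                          # faster than the 0.1 um/s pause threshold

# Piecewise-constant-velocity trajectory of one motile mitochondrion.
# Exponential run/pause dwell times; per-run direction Bernoulli. A run
# that reaches a segment boundary leaves the imaged field of view (as
# organelles do in vivo): later frames carry state "exited" and no
# position. Started in the stationary regime (state probabilities equal
# to the long-run time fractions; exponential dwells are memoryless, so
# fresh draws are also the correct residual times).
sim_motile_path <- function(profile, L, frame_times) {
  t_end <- frame_times[length(frame_times)]
  pos0 <- stats::runif(1, 0, L)
  moving <- stats::runif(1) < (1 - profile$target_time_fraction_paused)
  t <- 0; pos <- pos0
  exit_time <- Inf
  bt <- numeric(0); bp <- numeric(0); bv <- numeric(0)  # breakpoints + segment v
  add <- function(t0, v, dur) {
    bt[length(bt) + 1L] <<- t0
    bp[length(bp) + 1L] <<- pos
    bv[length(bv) + 1L] <<- v
    pos <<- pos + v * dur
    t <<- t0 + dur
  }
  while (t <= t_end && !is.finite(exit_time)) {
    if (moving) {
      dur <- stats::rexp(1, 1 / profile$mean_run_duration)
      retro <- stats::runif(1) < profile$prob_next_run_retrograde
      sp <- if (retro) {
        rtnorm(1, profile$retrograde_run_speed_mean,
               profile$retrograde_run_speed_sd, lower = SPEED_FLOOR_UM_S)
      } else {
        rtnorm(1, profile$anterograde_run_speed_mean,
               profile$anterograde_run_speed_sd, lower = SPEED_FLOOR_UM_S)
      }
      v <- if (retro) -sp else sp
      t_hit <- if (v > 0) (L - pos) / v else pos / (-v)
      if (dur >= t_hit) {           # run carries it out of the field
        add(t, v, t_hit)
        exit_time <- t
      } else {
        add(t, v, dur)
      }
    } else {
      dur <- stats::rexp(1, 1 / profile$mean_pause_duration)
      add(t, 0, dur)
    }
    moving <- !moving
  }
  # sample at frame times
  idx <- findInterval(frame_times, bt)
  position <- bp[idx] + bv[idx] * (frame_times - bt[idx])
  state <- ifelse(bv[idx] == 0, "paused",
                  ifelse(bv[idx] > 0, "anterograde", "retrograde"))
  gone <- frame_times >= exit_time
  position[gone] <- NA_real_
  state[gone] <- "exited"
  list(position_um = clamp(position, 0, L), state = state)
}

# Initial positions with a minimum spacing (organelles are discrete and do
# not overlap at rest); falls back to a jittered grid if rejection fails.
spaced_positions <- function(n, L, min_sep = 1.5) {
  if (n * min_sep >= L) min_sep <- L / (n + 1)
  for (i in 1:200) {
    p <- sort(stats::runif(n, 0, L))
    if (n < 2 || min(diff(p)) >= min_sep) return(sample(p))
  }
  jit <- stats::runif(n, -min_sep / 4, min_sep / 4)
  sample(clamp(seq(L / (2 * n), L - L / (2 * n), length.out = n) + jit, 0, L))
}

#' Simulate a mitochondrial transport time-lapse movie
#'
#' Generates a calibrated image stack of labeled mitochondria moving along
#' a straight 50-um-class axon segment, plus a ground-truth table with the
#' exact position and kinetic state of every mitochondrion in every frame.
#' Motility is a per-mitochondrion latent label (Bernoulli
#' `motile_fraction`): motile mitochondria follow the run/pause renewal
#' process of the [transport_profile()]; stationary ones jitter by less
#' than half a pixel.
#'
#' @param profile a [transport_profile()].
#' @param sim a [sim_config()].
#' @param n_mito number of mitochondria in the segment (>= 1).
#' @param seed integer seed (defaults to `sim$rng_seed`).
#' @return list with `stack` ([image_stack()]), `truth` (data.frame:
#'   mito_id, frame, time_s, position_um, state, motile) and `trace`
#'   (the straight [axon_trace()] along the segment).
#' @export
simulate_transport_movie <- function(profile, sim = sim_config(), n_mito,
                                     seed = NULL) {
  stopifnot(inherits(profile, "transport_profile"), inherits(sim, "sim_config"))
  stop_field(n_mito >= 1, "n_mito must be >= 1")
  seed <- seed %||% sim$rng_seed
  n_frames <- floor(sim$movie_duration_s / sim$frame_interval_s)
  stop_field(n_frames >= 2, "need >= 2 frames")
  L <- sim$segment_length_um
  px <- sim$pixel_size_um
  frame_times <- (seq_len(n_frames) - 1) * sim$frame_interval_s
  with_seed(seed, {
    motile <- stats::runif(n_mito) < profile$motile_fraction
    x0 <- spaced_positions(n_mito, L)
    pos <- matrix(0, n_mito, n_frames)
    state <- matrix("paused", n_mito, n_frames)
    for (i in seq_len(n_mito)) {
      if (motile[i]) {
        p <- sim_motile_path(profile, L, frame_times)
        pos[i, ] <- p$position_um
        state[i, ] <- p$state
      } else {
        jit <- clamp(stats::rnorm(n_frames, 0, 0.03), -0.45 * px, 0.45 * px)
        pos[i, ] <- clamp(x0[i] + jit, 0, L)
      }
    }
    amps <- stats::runif(n_mito, 140, 215)
    stack <- render_movie(pos, amps, sim, n_frames)
    truth <- data.frame(
      mito_id = rep(seq_len(n_mito), times = n_frames),
      frame = rep(seq_len(n_frames), each = n_mito),
      time_s = rep(frame_times, each = n_mito),
      position_um = as.vector(pos),
      state = as.vector(state),
      motile = rep(motile, times = n_frames),
      in_fov = !is.na(as.vector(pos))
    )
    truth <- truth[order(truth$mito_id, truth$frame), ]
    rownames(truth) <- NULL
    ny <- dim(stack$frames)[2]
    y_mid <- (ny - 1) / 2           # 0-based center row
    trace <- axon_trace(c(0, dim(stack$frames)[3] - 1), c(y_mid, y_mid), px)
    list(stack = stack, truth = truth, trace = trace)
  })
}

# Render frames: mitochondria are PSF-blurred points on a straight axon at
# the vertical center; separable Gaussian rendering, 8-bit output.
render_movie <- function(pos, amps, sim, n_frames) {
  px <- sim$pixel_size_um
  nx <- ceiling(sim$segment_length_um / px)
  ny <- 9L
  sig <- sim$psf_sigma_um / px
  y0 <- (ny + 1) / 2
  y_prof <- exp(-((seq_len(ny) - y0)^2) / (2 * sig^2))
  half <- max(3L, ceiling(4 * sig))
  bg <- 10
  arr <- array(0, dim = c(n_frames, ny, nx))
  for (f in seq_len(n_frames)) {
    rowvec <- numeric(nx)
    xc <- pos[, f] / px + 0.5    # column units, center of px 1 at 0.5
    for (i in seq_along(xc)) {
      if (is.na(xc[i])) next     # left the field of view
      c0 <- max(1L, floor(xc[i] - half)); c1 <- min(nx, ceiling(xc[i] + half))
      cols <- c0:c1
      rowvec[cols] <- rowvec[cols] +
        amps[i] * exp(-((cols - xc[i])^2) / (2 * sig^2))
    }
    fr <- outer(y_prof, rowvec) + bg
    if (sim$noise_sigma > 0)
      fr <- fr + matrix(stats::rnorm(ny * nx, 0, sim$noise_sigma), ny, nx)
    arr[f, , ] <- round(clamp(fr, 0, 255))
  }
  image_stack(arr, sim$frame_interval_s, px)
}

#' Simulate a single-frame mitochondrial morphology image
#'
#' Renders `Poisson(density x length / 100)` ellipses along a straight
#' axon with sampled length:width ratios, then blurs with the PSF and adds
#' noise. Morphology rendering defaults to finer optics than the movie
#' default (0.1 um pixels, 0.1 um PSF sigma), since sub-micrometre widths
#' are not measurable at coarser blur.
#'
#' @param profile a [morphology_profile()].
#' @param sim a [sim_config()]; `pixel_size_um`/`psf_sigma_um` are taken
#'   from it.
#' @param axon_length_um length of the rendered axon (um), > 0.
#' @param seed integer seed.
#' @return list with `image` (matrix, y x x), `truth` (data.frame:
#'   mito_id, centroid_x_um, centroid_y_um, length_um, width_um, ratio),
#'   and `pixel_size_um`.
#' @export
simulate_morphology_image <- function(profile, sim = morph_sim_config(),
                                      axon_length_um, seed = NULL) {
  stopifnot(inherits(profile, "morphology_profile"), inherits(sim, "sim_config"))
  stop_field(axon_length_um > 0, "axon_length_um must be > 0")
  seed <- seed %||% sim$rng_seed
  px <- sim$pixel_size_um
  with_seed(seed, {
    n <- stats::rpois(1, profile$density_per_100um * axon_length_um / 100)
    ratios <- sample_aspect_ratios(n, profile)
    widths <- profile$mito_minor_axis_um * stats::runif(n, 0.9, 1.1)
    lengths <- ratios * widths
    # sequential placement with clearance so objects never touch
    xs <- place_along_axon(lengths, axon_length_um, clearance = 0.5)
    keep <- !is.na(xs)
    xs <- xs[keep]; widths <- widths[keep]; lengths <- lengths[keep]
    ratios <- ratios[keep]; n <- sum(keep)
    nx <- ceiling(axon_length_um / px)
    ny <- max(15L, 2L * ceiling(1.5 / px) + 1L)
    ycen_um <- ((ny + 1) / 2 - 0.5) * px
    img <- matrix(0, ny, nx)
    amps <- stats::runif(max(n, 1), 150, 220)
    xg <- ((seq_len(nx)) - 0.5) * px
    yg <- ((seq_len(ny)) - 0.5) * px
    for (i in seq_len(n)) {
      a <- lengths[i] / 2; b <- widths[i] / 2
      c0 <- max(1L, floor((xs[i] - a) / px)); c1 <- min(nx, ceiling((xs[i] + a) / px))
      r0 <- max(1L, floor((ycen_um - b) / px)); r1 <- min(ny, ceiling((ycen_um + b) / px))
      for (cc in c0:c1) {
        dx2 <- ((xg[cc] - xs[i]) / a)^2
        inside <- dx2 + ((yg[r0:r1] - ycen_um) / b)^2 <= 1
        img[(r0:r1)[inside], cc] <- amps[i]
      }
    }
    sig_px <- sim$psf_sigma_um / px
    if (sig_px > 0.05) img <- gaussian_blur(img, sig_px)
    img <- img + 10
    if (sim$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(ny * nx, 0, sim$noise_sigma), ny, nx)
    img <- round(clamp(img, 0, 255))
    truth <- data.frame(mito_id = seq_len(n),
                        centroid_x_um = xs, centroid_y_um = rep(ycen_um, n),
                        length_um = lengths, width_um = widths, ratio = ratios)
    list(image = img, truth = truth, pixel_size_um = px)
  })
}

#' Default optics for morphology images
#'
#' High-zoom confocal scale: 0.1 um pixels, 0.1 um PSF sigma, one frame.
#' @param ... overrides passed to [sim_config()].
#' @export
morph_sim_config <- function(...) {
  args <- list(pixel_size_um = 0.1, psf_sigma_um = 0.1, noise_sigma = 3,
               movie_duration_s = 2, frame_interval_s = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

sample_aspect_ratios <- function(n, profile) {
  if (n == 0) return(numeric(0))
  swollen <- stats::runif(n) < profile$swollen_fraction
  ratios <- numeric(n)
  ratios[swollen] <- 1 + stats::rexp(sum(swollen), rate = 1 / 0.08)
  n_el <- sum(!swollen)
  if (n_el > 0) {
    # calibrate the elongated component so the mixture mean hits the target
    sf <- profile$swollen_fraction
    m_el <- (profile$aspect_ratio_mean - sf * 1.08) / max(1 - sf, 1e-9)
    excess_mean <- max(m_el - 1, 1e-6)
    if (profile$aspect_ratio_sd == 0) {
      ratios[!swollen] <- 1 + excess_mean
    } else {
      shape <- (excess_mean / profile$aspect_ratio_sd)^2
      ratios[!swollen] <- 1 + stats::rgamma(n_el, shape = shape,
                                            scale = excess_mean / shape)
    }
  }
  ratios
}

place_along_axon <- function(lengths, L, clearance = 0.5) {
  n <- length(lengths)
  if (n == 0) return(numeric(0))
  xs <- rep(NA_real_, n)
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in order(-lengths)) {
    a <- lengths[i] / 2
    for (try in 1:80) {
      x <- stats::runif(1, a, L - a)
      lo <- x - a - clearance; hi <- x + a + clearance
      if (nrow(occupied) == 0 ||
          all(hi < occupied[, 1] | lo > occupied[, 2])) {
        xs[i] <- x
        occupied <- rbind(occupied, c(x - a, x + a))
        break
      }
    }
  }
  xs
}

# Separable Gaussian blur with a discrete kernel (reflective edges).
gaussian_blur <- function(img, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rev(seq_len(min(half, n))), , drop = FALSE], m,
                 m[rev(seq(max(1, n - half + 1), n)), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    off0 <- min(half, n)
    for (j in seq_along(k))
      out <- out + k[j] * pad[(off0 + j - half):(off0 + j - half + n - 1), ,
                              drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

#' Simulate a 1D axon intensity profile at a given axonopathy stage
#'
#' Produces the intensity-vs-arc-length signature of each stage of the
#' 5-point rubric: (1) smooth continuous ridge; (2) sparse beads on a
#' continuous ridge; (3) dense beads plus at least one large varicosity;
#' (4) beading with fragmentation gaps over 10-70% of the length; (5) more
#' than 90% of the length at background.
#'
#' @param stage integer 1-5.
#' @param sim a [sim_config()]; `pixel_size_um` sets the arc step and
#'   `noise_sigma` the additive noise (0 for noise-free fixtures).
#' @param axon_length_um profile length (um).
#' @param seed integer seed.
#' @return numeric intensity profile with attributes `step_um` and
#'   `background`.
#' @export
simulate_axon_profile <- function(stage, sim = sim_config(noise_sigma = 0),
                                  axon_length_um = 50, seed = NULL) {
  stop_field(stage %in% 1:5, "stage must be in 1..5")
  stop_field(axon_length_um > 0, "axon_length_um must be > 0")
  seed <- seed %||% sim$rng_seed
  step <- sim$pixel_size_um
  n <- ceiling(axon_length_um / step)
  x <- (seq_len(n) - 0.5) * step
  base <- 100; bg <- 5
  add_bead <- function(p, center, sigma, amp) {
    p + amp * exp(-((x - center)^2) / (2 * sigma^2))
  }
  with_seed(seed, {
    ripple <- 3 * sin(2 * pi * x / axon_length_um + stats::runif(1, 0, 2 * pi))
    p <- rep(base, n) + ripple
    if (stage == 2) {
      k <- sample(2:4, 1)   # 4-8 beads/100um on a 50-um axon: below the 10 boundary
      centers <- spaced_positions(k, axon_length_um - 6, min_sep = 6) + 3
      for (cc in centers) p <- add_bead(p, cc, stats::runif(1, 0.3, 0.5),
                                        stats::runif(1, 130, 160))
    } else if (stage == 3) {
      k <- max(8L, ceiling(0.16 * axon_length_um))  # >= 16 beads/100um
      vc <- stats::runif(1, 10, axon_length_um - 10)
      # beads keep clear of the varicosity so peaks do not stack
      lseg <- c(2, vc - 4.5); rseg <- c(vc + 4.5, axon_length_um - 2)
      wl <- diff(lseg); wr <- diff(rseg)
      kl <- round(k * wl / (wl + wr)); kr <- k - kl
      centers <- c(
        if (kl > 0) spaced_positions(kl, wl, min_sep = 3) + lseg[1] else numeric(0),
        if (kr > 0) spaced_positions(kr, wr, min_sep = 3) + rseg[1] else numeric(0))
      for (cc in centers) p <- add_bead(p, cc, stats::runif(1, 0.3, 0.5),
                                        stats::runif(1, 130, 160))
      p <- add_bead(p, vc, stats::runif(1, 1.8, 2.4), stats::runif(1, 130, 160))
    } else if (stage == 4) {
      # disjoint gaps (one per equal sector) covering 20-60% of the length
      gap_total <- stats::runif(1, 0.2, 0.6) * axon_length_um
      n_gaps <- sample(2:3, 1)
      w <- gap_total / n_gaps
      sector <- axon_length_um / n_gaps
      for (g in seq_len(n_gaps)) {
        s0 <- (g - 1) * sector + stats::runif(1, 0.5, max(sector - w - 0.5, 0.6))
        p[x >= s0 & x <= s0 + w] <- bg
      }
      # beads on the surviving segments
      alive <- which(p > bg + 20)
      if (length(alive) > 10)
        for (cc in x[sample(alive, 2)]) p <- add_bead(p, cc, 0.4, 130)
    } else if (stage == 5) {
      # residual fragments in disjoint halves, 4-8% of the length in total
      p <- rep(bg, n)
      frag_frac <- stats::runif(1, 0.04, 0.08)
      w <- frag_frac * axon_length_um / 2
      half <- axon_length_um / 2
      s1 <- stats::runif(1, 1, half - w - 1)
      s2 <- stats::runif(1, half + 1, axon_length_um - w - 1)
      p[(x >= s1 & x <= s1 + w) | (x >= s2 & x <= s2 + w)] <- base
    }
    if (sim$noise_sigma > 0) p <- pmax(p + stats::rnorm(n, 0, sim$noise_sigma), 0)
    structure(p, step_um = step, background = bg)
  })
}

#' Simulate one embryo's neuron cohort between 2 and 3 dpf
#'
#' Each cell survives to 3 dpf with probability `survival_2to3dpf`; stages
#' evolve by the per-day axonopathy transition matrix; dying cells are
#' recorded at stage 5 with a dead soma; additional cells newly express
#' the reporter with probability `new_expression_rate` each.
#'
#' @param profile a [condition_profile()].
#' @param n_cells number of reporter-positive cells at 2 dpf (>= 1).
#' @param seed integer seed.
#' @return data.frame of class `cohort_table`: cell_id, condition,
#'   present_at_t1, present_at_t2, newly_appeared, stage_t1, stage_t2,
#'   soma_alive_t2.
#' @export
simulate_cohort <- function(profile, n_cells, seed = NULL) {
  stopifnot(inherits(profile, "condition_profile"))
  stop_field(n_cells >= 1, "n_cells must be >= 1")
  ax <- profile$axonopathy
  with_seed(seed, {
    stage1 <- sample.int(5, n_cells, replace = TRUE,
                         prob = ax$stage_probabilities_at_2dpf)
    survive <- stats::runif(n_cells) < profile$survival_2to3dpf
    stage2 <- vapply(seq_len(n_cells), function(i) {
      if (!survive[i]) return(5L)
      sample.int(5, 1, prob = ax$stage_transition_matrix_per_day[stage1[i], ])
    }, integer(1))
    stage2 <- pmax(stage2, stage1)  # monotone by construction; belt and braces
    # a fully degenerated axon usually reflects a dead or dying soma
    soma_alive <- survive & !(stage2 == 5L &
                                stats::runif(n_cells) < ax$death_given_stage5)
    n_new <- stats::rbinom(1, n_cells, profile$new_expression_rate)
    d <- data.frame(
      cell_id = sprintf("c%03d", seq_len(n_cells + n_new)),
      condition = profile$name,
      present_at_t1 = c(rep(TRUE, n_cells), rep(FALSE, n_new)),
      present_at_t2 = c(survive, rep(TRUE, n_new)),
      newly_appeared = c(rep(FALSE, n_cells), rep(TRUE, n_new)),
      stage_t1 = c(stage1, rep(NA_integer_, n_new)),
      stage_t2 = c(stage2,
                   if (n_new > 0) sample.int(5, n_new, replace = TRUE,
                                             prob = ax$stage_probabilities_at_2dpf)
                   else integer(0)),
      soma_alive_t2 = c(soma_alive, rep(TRUE, n_new))
    )
    class(d) <- c("cohort_table", "data.frame")
    d
  })
}

#' Simulate a post-transection Wallerian-degeneration time course
#'
#' Draws a true lag (transection to fragmentation) and clearance interval
#' from zero-truncated normal distributions and emits a per-frame event
#' series sampled every `sampling_interval` minutes: fragmentation is
#' synchronous (fragment count jumps from 1 to its maximum within one
#' inter-frame interval) and debris then clears linearly over the
#' clearance interval.
#'
#' @param profile a [timing_profile()].
#' @param seed integer seed.
#' @param total_min observation window (minutes); default 12 h.
#' @return data.frame of class `event_series` (time_min, debris_fraction,
#'   n_fragments, soma_alive) with attribute `truth` holding the drawn lag
#'   and clearance.
#' @export
simulate_wd_timecourse <- function(profile, seed = NULL, total_min = 720) {
  stopifnot(inherits(profile, "timing_profile"))
  dt <- profile$sampling_interval
  stop_field(dt > 0, "sampling_interval must be > 0")
  with_seed(seed, {
    lag <- rtnorm(1, profile$lag_mean, profile$lag_sd, lower = 0)
    clearance <- rtnorm(1, profile$clearance_mean, profile$clearance_sd, lower = 0)
    times <- seq(0, total_min, by = dt)
    n_max <- 5L + stats::rpois(1, 5)
    debris <- ifelse(times < lag, 1,
                     pmax(0, 1 - (times - lag) / max(clearance, 1e-9)))
    n_frag <- ifelse(times < lag, 1L, pmax(0L, ceiling(n_max * debris)))
    d <- data.frame(time_min = times, debris_fraction = debris,
                    n_fragments = as.integer(n_frag),
                    soma_alive = TRUE)
    attr(d, "truth") <- list(lag_min = lag, clearance_min = clearance)
    class(d) <- c("event_series", "data.frame")
    d
  })
}
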