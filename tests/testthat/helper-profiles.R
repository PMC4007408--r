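# Shared fixtures: shipped condition profiles and hand-built kymographs.

shipped_profiles <- load_condition_profiles()

# Kymograph built directly from ridge position functions (one per object),
# bypassing the movie renderer: the independent fixture for the tracker.
make_ridge_kymograph <- function(pos_fns, n_frames = 120, n_bins = 250,
                                 bin_size = 0.2, amp = 180, bg = 10,
                                 sigma_bins = 1.5, noise = 0, seed = 1) {
  with_seed(seed, {
    m <- matrix(bg, n_frames, n_bins)
    cols <- seq_len(n_bins)
    for (f in seq_len(n_frames)) {
      for (fn in pos_fns) {
        p_um <- fn(f)
        if (is.na(p_um)) next
        cc <- p_um / bin_size + 0.5
        m[f, ] <- m[f, ] + amp * exp(-((cols - cc)^2) / (2 * sigma_bins^2))
      }
      if (noise > 0) m[f, ] <- m[f, ] + stats::rnorm(n_bins, 0, noise)
    }
    structure(list(matrix = m, bin_size_um = bin_size, frame_interval_s = 1),
              class = "kymograph")
  })
}

# A bare track table for run-segmentation tests.
make_track <- function(position_um, frame_interval_s = 1, mito_id = 1L) {
  d <- data.frame(mito_id = mito_id,
                  frame = seq_along(position_um),
                  time_s = (seq_along(position_um) - 1) * frame_interval_s,
                  position_um = position_um,
                  interpolated = FALSE)
  class(d) <- c("track_table", "data.frame")
  attr(d, "frame_interval_s") <- frame_interval_s
  d
}
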