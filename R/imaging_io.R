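#' Time-lapse image stack
#'
#' A calibrated multi-frame grayscale stack. Frames are stored as a 3D
#' array indexed `[frame, y, x]`.
#'
#' @param frames 3D numeric array (time x y x x) or a list of matrices of
#'   identical shape.
#' @param frame_interval_s seconds between frames.
#' @param pixel_size_um um per pixel.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval_s, pixel_size_um) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    stop_field(length(dims) == 1L, "all frames must have the same shape")
    arr <- array(0, dim = c(length(frames), dims[[1]]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  stop_field(is.array(frames) && length(dim(frames)) == 3L,
             "frames must be a 3D array (time x y x x)")
  stop_field(dim(frames)[1] >= 1L, "stack needs >= 1 frame")
  stop_field(frame_interval_s > 0, "frame_interval_s must be > 0")
  stop_field(pixel_size_um > 0, "pixel_size_um must be > 0")
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px | %.3g um/px | dt = %.3g s | duration %.4g s\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s,
              (d[1] - 1) * x$frame_interval_s))
  invisible(x)
}

#' Duration of a stack in seconds
#'
#' `(n_frames - 1) * frame_interval`, i.e. the time between the first and
#' last frame.
#' @param stack an [image_stack()].
#' @return seconds.
#' @export
stack_duration_s <- function(stack) {
  (dim(stack$frames)[1] - 1) * stack$frame_interval_s
}

stack_sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a calibrated multi-page TIFF stack
#'
#' Stacks are written as uncompressed 16-bit grayscale multi-page TIFF with
#' a JSON sidecar (`<path>.json`) holding the calibration. Integer data in
#' `[0, 65535]` round-trips losslessly.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  stop_field(min(fr) >= 0 && max(fr) <= 65535,
             "intensities must lie in [0, 65535] for 16-bit TIFF export")
  pages <- lapply(seq_len(dim(fr)[1]), function(i) fr[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(frame_interval_s = stack$frame_interval_s,
                            pixel_size_um = stack$pixel_size_um),
                       stack_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param frame_interval_s,pixel_size_um calibration overrides; required if
#'   no JSON sidecar accompanies the file.
#' @export
read_stack <- function(path, frame_interval_s = NULL, pixel_size_um = NULL) {
  stop_field(file.exists(path), paste0("no such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    p
  })
  side <- stack_sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
    pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  }
  stop_field(!is.null(frame_interval_s) && !is.null(pixel_size_um),
             "calibration missing: supply frame_interval_s and pixel_size_um or a sidecar")
  image_stack(pages, frame_interval_s, pixel_size_um)
}

#' Axon trace polyline
#'
#' Ordered pixel vertices of a traced axon, proximal (cell-body) end first.
#' Coordinates are 0-based pixel indices, as exported by common tracing
#' tools; anterograde is increasing arc length.
#'
#' @param x_px,y_px numeric vertex coordinates (0-based pixels).
#' @param pixel_size_um um per pixel.
#' @return object of class `axon_trace` with `$calibrated_length_um`.
#' @export
axon_trace <- function(x_px, y_px, pixel_size_um) {
  stop_field(length(x_px) == length(y_px) && length(x_px) >= 2L,
             "trace needs >= 2 vertices")
  stop_field(pixel_size_um > 0, "pixel_size_um must be > 0")
  seg <- sqrt(diff(x_px)^2 + diff(y_px)^2)
  structure(list(x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                 pixel_size_um = pixel_size_um,
                 arc_px = c(0, cumsum(seg)),
                 calibrated_length_um = sum(seg) * pixel_size_um),
            class = "axon_trace")
}

#' Read / write an axon trace as CSV
#'
#' Two-column CSV (`x_px`, `y_px`) with header, proximal vertex first.
#'
#' @param path CSV path.
#' @param pixel_size_um calibration (um per pixel).
#' @return `read_axon_trace` returns an [axon_trace()].
#' @export
read_axon_trace <- function(path, pixel_size_um) {
  d <- utils::read.csv(path)
  stop_field(all(c("x_px", "y_px") %in% names(d)),
             "trace CSV must have columns x_px, y_px")
  axon_trace(d$x_px, d$y_px, pixel_size_um)
}

#' @rdname read_axon_trace
#' @param trace an [axon_trace()].
#' @export
write_axon_trace <- function(trace, path) {
  utils::write.csv(data.frame(x_px = trace$x_px, y_px = trace$y_px),
                   path, row.names = FALSE)
  invisible(path)
}

#' Build a kymograph along an axon trace
#'
#' Resamples the trace at `bin_size_um` steps of arc length and, for every
#' frame and every arc-length bin, records the maximum intensity over a
#' band of `+/- band_halfwidth_px` pixels normal to the trace (maximum
#' rather than mean, to preserve punctate mitochondrial signal at low SNR).
#' Rows are time frames (time runs down), columns are arc-length bins with
#' the proximal end at column 1.
#'
#' @param stack an [image_stack()].
#' @param trace an [axon_trace()]; must lie within the frame bounds.
#' @param band_halfwidth_px half-width of the sampling band (pixels).
#' @param bin_size_um arc-length bin size; defaults to the pixel size
#'   (no sub-pixel resampling).
#' @return object of class `kymograph`: `$matrix` (time x arc bins),
#'   `$bin_size_um`, `$frame_interval_s`.
#' @export
build_kymograph <- function(stack, trace, band_halfwidth_px = 3L,
                            bin_size_um = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(trace, "axon_trace"))
  stop_field(band_halfwidth_px >= 0, "band_halfwidth_px must be >= 0")
  d <- dim(stack$frames)
  stop_field(d[1] >= 2L, "kymograph needs a stack with >= 2 frames")
  px <- stack$pixel_size_um
  bin_size_um <- bin_size_um %||% px
  stop_field(bin_size_um <= px + 1e-12,
             "bin_size_um must not exceed the pixel size")
  # 0-based trace coords -> 1-based array indices
  vx <- trace$x_px + 1; vy <- trace$y_px + 1
  stop_field(all(vx >= 1 & vx <= d[3] & vy >= 1 & vy <= d[2]),
             "trace lies outside the image bounds")
  total_um <- trace$calibrated_length_um
  n_bins <- ceiling(total_um / bin_size_um)
  s_centers_px <- ((seq_len(n_bins) - 0.5) * bin_size_um) / px
  s_centers_px <- pmin(s_centers_px, max(trace$arc_px))
  cx <- stats::approx(trace$arc_px, vx, xout = s_centers_px, rule = 2)$y
  cy <- stats::approx(trace$arc_px, vy, xout = s_centers_px, rule = 2)$y
  # unit tangents per bin from the segment each bin falls in
  seg_idx <- pmin(findInterval(s_centers_px, trace$arc_px,
                               rightmost.closed = TRUE), length(vx) - 1L)
  tx <- (vx[seg_idx + 1L] - vx[seg_idx])
  ty <- (vy[seg_idx + 1L] - vy[seg_idx])
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  nx <- -ty / nrm; ny <- tx / nrm   # unit normal
  offs <- seq(-band_halfwidth_px, band_halfwidth_px)
  nb <- length(offs)
  # sample index matrices: (band position) x (bin); floor(x + 0.5 + eps)
  # rather than round() so the half-pixel coordinates this resampling
  # generically produces map consistently (round() alternates to-even and
  # interpolation leaves half-integers a ULP short of exact)
  eps <- 1e-9
  sy <- floor(matrix(cy, nrow = nb, ncol = n_bins, byrow = TRUE) +
                outer(offs, ny) + 0.5 + eps)
  sx <- floor(matrix(cx, nrow = nb, ncol = n_bins, byrow = TRUE) +
                outer(offs, nx) + 0.5 + eps)
  sy <- clamp(sy, 1L, d[2]); sx <- clamp(sx, 1L, d[3])
  lin <- (sx - 1L) * d[2] + sy   # column-major index into a [y, x] matrix
  kymo <- matrix(0, nrow = d[1], ncol = n_bins)
  for (f in seq_len(d[1])) {
    fr <- stack$frames[f, , ]
    vals <- matrix(fr[lin], nrow = nb)
    cm <- vals[1, ]
    if (nb > 1) for (r in 2:nb) cm <- pmax(cm, vals[r, ])
    kymo[f, ] <- cm
  }
  structure(list(matrix = kymo, bin_size_um = bin_size_um,
                 frame_interval_s = stack$frame_interval_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d arc bins | bin %.3g um | dt %.3g s\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size_um, x$frame_interval_s))
  invisible(x)
}

#' Export a kymograph as TIFF + JSON metadata
#'
#' @param kymo a [build_kymograph()] result.
#' @param path TIFF path; metadata goes to `<path>.json`.
#' @export
write_kymograph <- function(kymo, path) {
  m <- kymo$matrix
  tiff::writeTIFF(m / max(max(m), 1), path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(bin_size_um = kymo$bin_size_um,
                            frame_interval_s = kymo$frame_interval_s,
                            intensity_scale = max(max(m), 1)),
                       stack_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
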