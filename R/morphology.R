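#' Segment mitochondria in a single-frame image
#'
#' Otsu threshold, connected-component labeling, removal of components
#' smaller than `min_area_px` pixels, then length and width from the
#' second-moment (best-fit ellipse) major and minor axes of each
#' component mask.
#'
#' @param image 2D numeric matrix (rows = y, columns = x).
#' @param pixel_size_um um per pixel.
#' @param min_area_px minimum component area (pixels), default 4.
#' @return data.frame: mito_id, centroid_x_um, centroid_y_um, length_um,
#'   width_um, area_um2, ratio. A blank image yields zero rows.
#' @export
segment_mitochondria <- function(image, pixel_size_um, min_area_px = 4L) {
  stop_field(is.matrix(image), "image must be a 2D matrix")
  stop_field(pixel_size_um > 0, "pixel_size_um must be > 0")
  empty <- data.frame(mito_id = integer(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), length_um = numeric(0),
                      width_um = numeric(0), area_um2 = numeric(0),
                      ratio = numeric(0))
  rng <- range(image)
  if (diff(rng) == 0) return(empty)
  thr <- otsu_threshold(image)
  mask <- image > thr
  if (!any(mask)) return(empty)
  # EBImage indexes images [x, y]; transpose our [y, x] matrices
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  if (is.null(mom) || nrow(mom) == 0) return(empty)
  keep <- shp[, "s.area"] >= min_area_px
  if (!any(keep)) return(empty)
  mom <- mom[keep, , drop = FALSE]
  shp <- shp[keep, , drop = FALSE]
  major <- mom[, "m.majoraxis"]
  minor <- major * sqrt(pmax(1 - mom[, "m.eccentricity"]^2, 0))
  minor <- pmax(minor, 1)  # a 1-px-thin mask is still one pixel wide
  d <- data.frame(
    mito_id = seq_len(nrow(mom)),
    centroid_x_um = (mom[, "m.cx"] - 0.5) * pixel_size_um,
    centroid_y_um = (mom[, "m.cy"] - 0.5) * pixel_size_um,
    length_um = major * pixel_size_um,
    width_um = minor * pixel_size_um,
    area_um2 = shp[, "s.area"] * pixel_size_um^2,
    ratio = major / minor
  )
  rownames(d) <- NULL
  d
}

#' Summarize mitochondrial morphology along an axon
#'
#' Density per 100 um, length:width mean and s.e.m., and the binned
#' frequency distribution of ratios (right-open bins starting at 1.0).
#'
#' @param shapes output of [segment_mitochondria()] (or any data.frame
#'   with a `ratio` column).
#' @param axon_length_um axon length (um), > 0.
#' @param bin_width histogram bin width for the ratio distribution.
#' @return object of class `morphology_summary`.
#' @export
summarize_morphology <- function(shapes, axon_length_um, bin_width = 0.25) {
  stop_field(axon_length_um > 0, "axon_length_um must be > 0")
  n <- nrow(shapes)
  ratios <- shapes$ratio
  if (n > 0) {
    top <- max(ratios, 1 + bin_width)
    breaks <- seq(1, top + bin_width, by = bin_width)
    h <- graphics::hist(ratios, breaks = breaks, right = FALSE, plot = FALSE)
    histo <- list(breaks = h$breaks, counts = h$counts)
  } else {
    histo <- list(breaks = numeric(0), counts = integer(0))
  }
  structure(list(
    n_mito = n,
    axon_length_um = axon_length_um,
    density_per_100um = 100 * n / axon_length_um,
    ratios = ratios,
    ratio_mean = if (n) mean(ratios) else NA_real_,
    ratio_sem = if (n > 1) stats::sd(ratios) / sqrt(n) else if (n == 1) 0 else NA_real_,
    histogram = histo
  ), class = "morphology_summary")
}

#' @export
print.morphology_summary <- function(x, ...) {
  cat(sprintf("<morphology_summary> %d mitochondria on %.4g um: density %.3g / 100 um\n",
              x$n_mito, x$axon_length_um, x$density_per_100um))
  if (x$n_mito)
    cat(sprintf("  length:width %.3g +/- %.2g (mean +/- s.e.m.)\n",
                x$ratio_mean, x$ratio_sem))
  invisible(x)
}
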