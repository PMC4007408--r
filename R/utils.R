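#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators never leak global state. If `seed` is
#' `NULL` the expression runs against the ambient RNG.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Truncated normal sampler via inverse-CDF; exact, no rejection loop.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Otsu threshold of a numeric array
#'
#' Histogram-based threshold maximizing between-class variance; used to
#' separate fluorescent signal from background in kymographs and images.
#'
#' @param x numeric vector, matrix or array of intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w1 <- w[-n_bins]; m1 <- m[-n_bins]
  w2 <- n - w1
  ok <- w1 > 0 & w2 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[ok] <- (mt * w1[ok] - n * m1[ok])^2 / (w1[ok] * w2[ok])
  breaks[which.max(between) + 1L]
}

is_prob <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) && p >= 0 && p <= 1

stop_field <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
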