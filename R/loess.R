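#' Locally weighted polynomial regression (LOESS)
#'
#' Classical non-robust loess at the observed design points: at each
#' evaluation site, a polynomial of the given degree is fitted by weighted
#' least squares over the `span` nearest neighbours, with tricube weights
#' `w = (1 - (d/dmax)^3)^3` where `dmax` is the distance to the k-th nearest
#' neighbour (boundary ties all included), and evaluated at the site. There
#' are no robustness iterations. Tied predictor values form a single
#' evaluation site. Windows in which all predictors coincide, or in which the
#' local design is rank-deficient, fall back to the (weighted) local mean.
#'
#' This is the smoothing engine used both for allele frequency along the
#' chromosome ([smooth_frequency_by_position()], span in points) and for the
#' among-replicate standard deviation against allele frequency
#' ([smooth_sd_by_frequency()], span as a fraction of markers).
#'
#' @param x Numeric predictor, sorted non-decreasingly (ties allowed).
#' @param y Numeric response, same length as `x`; `NA`s are not allowed.
#' @param span Window size: a number of points (`span_mode = "points"`) or a
#'   fraction of the points (`span_mode = "fraction"`, `k = ceiling(span * n)`).
#' @param span_mode `"points"` or `"fraction"`.
#' @param degree Local polynomial degree, 0, 1 or 2.
#' @return Numeric vector of fitted values at each `x`.
#' @examples
#' x <- sort(runif(200, 0, 100))
#' y <- sin(x / 10) + rnorm(200, sd = 0.2)
#' f <- loess_fit(x, y, span = 40, degree = 2)
#' @export
loess_fit <- function(x, y, span = 80, span_mode = c("points", "fraction"),
                      degree = 2) {
  span_mode <- match.arg(span_mode)
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  if (is.unsorted(x)) stop("x must be sorted non-decreasingly")
  if (!degree %in% 0:2) stop("degree must be 0, 1 or 2")
  k <- if (span_mode == "points") as.integer(round(span))
       else as.integer(ceiling(span * n))
  if (k < degree + 1L)
    stop("span must cover at least degree + 1 points")
  if (n < degree + 1L)
    stop("need at least degree + 1 points")
  k <- min(k, n)

  sites <- unique(x)
  fit_site <- numeric(length(sites))
  n_fallback <- 0L
  lo <- 1L
  for (s in seq_along(sites)) {
    x0 <- sites[s]
    while (lo + k <= n && (x[lo + k] - x0) < (x0 - x[lo])) lo <- lo + 1L
    hi <- lo + k - 1L
    dmax <- max(x0 - x[lo], x[hi] - x0)
    lo2 <- lo; hi2 <- hi
    while (lo2 > 1L && (x0 - x[lo2 - 1L]) <= dmax) lo2 <- lo2 - 1L
    while (hi2 < n && (x[hi2 + 1L] - x0) <= dmax) hi2 <- hi2 + 1L
    idx <- lo2:hi2
    if (dmax <= 0) {  # every neighbour at the site itself
      fit_site[s] <- mean(y[idx])
      n_fallback <- n_fallback + 1L
      next
    }
    d <- abs(x[idx] - x0)
    w <- (1 - (d / dmax)^3)^3
    pos <- w > 0
    xi <- x[idx][pos] - x0
    yi <- y[idx][pos]
    wi <- w[pos]
    X <- outer(xi, 0:degree, `^`)
    fit <- stats::lm.wfit(X, yi, wi)
    if (fit$rank < degree + 1L || is.na(fit$coefficients[1L])) {
      fit_site[s] <- sum(wi * yi) / sum(wi)
      n_fallback <- n_fallback + 1L
    } else {
      fit_site[s] <- fit$coefficients[1L]
    }
  }
  if (n_fallback > 0L)
    message("loess_fit: fell back to local weighted mean at ",
            n_fallback, " site(s)")
  fit_site[match(x, sites)]
}

#' Smooth allele frequencies along each chromosome
#'
#' Smooths each (category, subpool) frequency column against base-pair
#' position, independently per chromosome, with a window of `span_points`
#' nearest markers (chromosomes shorter than the span use all of their
#' markers). Fitted frequencies are clipped to `[0, 1]`. Chromosomes with
#' fewer than three markers are passed through unsmoothed. Missing values stay
#' missing and do not enter neighbouring fits.
#'
#' @param freqs A `freq_matrix` (stage `"raw"`).
#' @param span_points Window size in markers; default 80.
#' @param degree Local polynomial degree; default 2.
#' @return A `freq_matrix` with stage `"smoothed"`.
#' @export
smooth_frequency_by_position <- function(freqs, span_points = 80, degree = 2) {
  vals <- freqs$values
  chrom <- freqs$markers$chrom
  pos <- as.numeric(freqs$markers$pos)
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    if (length(rows) < 3L) {
      message("chromosome ", ch, " has fewer than 3 markers; not smoothed")
      next
    }
    for (j in seq_len(ncol(vals))) {
      ok <- rows[!is.na(vals[rows, j])]
      if (length(ok) < max(3L, degree + 1L)) next
      k <- min(span_points, length(ok))
      fitted <- loess_fit(pos[ok], vals[ok, j], span = max(k, degree + 1L),
                          span_mode = "points", degree = degree)
      vals[ok, j] <- pmin(1, pmax(0, fitted))
    }
  }
  freq_matrix(freqs$markers, vals, freqs$design, stage = "smoothed")
}

#' Smooth among-replicate SD by allele frequency
#'
#' The among-replicate standard deviation of pool frequencies depends on the
#' allele frequency itself (binomial-type sampling), so per-marker SDs are
#' smoothed genome-wide against frequency with a window spanning
#' `span_fraction` of the markers. Markers are sorted by frequency for the
#' fit and results are mapped back to marker order; negative fits are clipped
#' to zero. If all frequencies are identical the global mean SD is returned.
#'
#' @param sd Per-marker among-replicate SD for one category.
#' @param freq Per-marker mean allele frequency in that category, aligned to
#'   `sd`.
#' @param span_fraction Window size as a fraction of the markers; default 0.10.
#' @param degree Local polynomial degree; default 2.
#' @return Numeric vector of smoothed SDs in marker order (`NA` where either
#'   input is `NA`).
#' @export
smooth_sd_by_frequency <- function(sd, freq, span_fraction = 0.10, degree = 2) {
  if (length(sd) != length(freq)) stop("sd and freq must be aligned")
  out <- rep(NA_real_, length(sd))
  ok <- which(!is.na(sd) & !is.na(freq))
  if (length(ok) == 0L) return(out)
  if (length(unique(freq[ok])) == 1L) {
    message("all frequencies identical; returning the global mean SD")
    out[ok] <- mean(sd[ok])
    return(out)
  }
  ord <- ok[order(freq[ok])]
  k <- max(ceiling(span_fraction * length(ord)), degree + 1L)
  fitted <- loess_fit(freq[ord], sd[ord], span = k, span_mode = "points",
                      degree = degree)
  out[ord] <- pmax(0, fitted)
  out
}
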