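#' Per-marker subpool mean and among-replicate variance
#'
#' For one category, computes at each marker the arithmetic mean and the
#' sample variance (denominator n - 1) of the allele frequency across the
#' category's replicate subpools. Markers with any missing subpool value are
#' masked (`NA`) for the category.
#'
#' @param freqs A `freq_matrix` (normally position-smoothed).
#' @param category Category label, e.g. `"growth"`.
#' @return A list with numeric vectors `mean` and `var`, aligned to marker
#'   order, and `n_masked`.
#' @export
subpool_stats <- function(freqs, category) {
  cols <- grep(paste0("^", category, "_"), colnames(freqs$values))
  if (length(cols) == 0L) stop("category not present: ", category)
  v <- freqs$values[, cols, drop = FALSE]
  masked <- rowSums(is.na(v)) > 0L
  m <- rowMeans(v)
  s2 <- apply(v, 1L, stats::var)
  m[masked] <- NA_real_
  s2[masked] <- NA_real_
  if (any(masked))
    message(sum(masked), " marker(s) masked for category ", category,
            " (missing subpool value)")
  list(mean = m, var = s2, n_masked = sum(masked))
}

#' Tail-minus-control allele frequency difference (D-value)
#'
#' @param tail_mean Mean YE-531 frequency across the selected-tail subpools.
#' @param control_mean Mean YE-531 frequency across the control subpools.
#' @return `D = tail_mean - control_mean`, in `[-1, 1]`.
#' @export
d_value <- function(tail_mean, control_mean) {
  tail_mean - control_mean
}

#' Empirical standard error of the D-value
#'
#' Both the tail and the control frequency are means of `replicates` subpools,
#' so under the null the variance of their difference is the sum of the two
#' among-replicate variances, each divided by the number of replicates:
#' `SE^2 = VarS/replicates + VarCtrl/replicates`.
#'
#' @param var_tail Smoothed among-replicate variance of the selected pools.
#' @param var_control Smoothed among-replicate variance of the control pools.
#' @param replicates Number of replicate subpools per category; default 3.
#' @return The standard error (0 where both variances are 0; such markers are
#'   masked downstream because Z is undefined).
#' @examples
#' standard_error(0.0034, 0.0010) # ~0.038
#' standard_error(0.0044, 0.0010) # ~0.042
#' @export
standard_error <- function(var_tail, var_control, replicates = 3) {
  if (any(c(var_tail, var_control) < 0, na.rm = TRUE))
    stop("variances must be non-negative")
  sqrt(var_tail / replicates + var_control / replicates)
}

#' Comparison-wise Z statistic and P-value
#'
#' `Z = D/SE`; the comparison-wise (per-marker) P-value is two-sided on |Z|:
#' `P = 2 * (1 - pnorm(|Z|))`, clamped away from exact zero. Markers with
#' `SE <= 0` (or missing inputs) are masked (`NA`).
#'
#' @param d D-values.
#' @param se Standard errors.
#' @return A list with vectors `z` and `p`.
#' @export
cwer_test <- function(d, se) {
  ok <- !is.na(d) & !is.na(se) & se > 0
  z <- ifelse(ok, d / se, NA_real_)
  p <- ifelse(ok, 2 * stats::pnorm(abs(z), lower.tail = FALSE), NA_real_)
  p <- ifelse(!is.na(p), pmax(p, .Machine$double.xmin), p)
  list(z = z, p = p)
}

#' Single-marker association scan for one trait
#'
#' Runs the association stage on a position-smoothed frequency matrix, in the
#' fixed pipeline order: subpool means and among-replicate variances for the
#' trait and control categories; smoothing of the among-replicate SD by the
#' category's own mean allele frequency (genome-wide, window
#' `sd_span_fraction` of the markers); squaring of the smoothed SD back to a
#' variance; then D, SE, Z and the comparison-wise P per marker.
#'
#' With three replicates the sample SD underestimates the true SD by the
#' Gaussian small-sample factor c4 (about 0.886 at n = 3), which would inflate
#' Z by ~13 percent; by default the SDs are divided by c4 before smoothing so
#' that the smoothed SE is unbiased (`sd_bias_correct = FALSE` reproduces the
#' uncorrected behaviour).
#'
#' @param freqs A `freq_matrix`, normally with stage `"smoothed"`.
#' @param trait Trait category label (`"growth"` or `"survival"` in the
#'   default design).
#' @param control Control category label.
#' @param sd_span_fraction Span for SD-by-frequency smoothing; default 0.10.
#' @param degree Local polynomial degree for SD smoothing; default 2.
#' @param sd_bias_correct Apply the c4 small-sample SD correction; default
#'   `TRUE`.
#' @return A data frame of class `association_result` with columns `chrom`,
#'   `pos`, `freq_ctrl`, `freq_tail`, `D`, `SE`, `Z`, `P` and logical `masked`.
#' @export
associate_trait <- function(freqs, trait, control = "control",
                            sd_span_fraction = 0.10, degree = 2,
                            sd_bias_correct = TRUE) {
  st <- subpool_stats(freqs, trait)
  sc <- subpool_stats(freqs, control)
  n_rep_t <- length(grep(paste0("^", trait, "_"), colnames(freqs$values)))
  n_rep_c <- length(grep(paste0("^", control, "_"), colnames(freqs$values)))

  sd_t <- sqrt(st$var)
  sd_c <- sqrt(sc$var)
  if (sd_bias_correct) {
    sd_t <- sd_t / c4_factor(n_rep_t)
    sd_c <- sd_c / c4_factor(n_rep_c)
  }
  sm_sd_t <- smooth_sd_by_frequency(sd_t, st$mean, sd_span_fraction, degree)
  sm_sd_c <- smooth_sd_by_frequency(sd_c, sc$mean, sd_span_fraction, degree)

  D <- d_value(st$mean, sc$mean)
  SE <- sqrt(sm_sd_t^2 / n_rep_t + sm_sd_c^2 / n_rep_c)
  zt <- cwer_test(D, SE)

  out <- data.frame(chrom = freqs$markers$chrom, pos = freqs$markers$pos,
                    freq_ctrl = sc$mean, freq_tail = st$mean,
                    D = D, SE = SE, Z = zt$z, P = zt$p,
                    stringsAsFactors = FALSE)
  out$masked <- is.na(out$P)
  class(out) <- c("association_result", "data.frame")
  attr(out, "trait") <- trait
  out
}

# Gaussian small-sample bias factor of the sample SD: E[s] = c4(n) * sigma.
c4_factor <- function(n) {
  sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
}
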