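#' Estimate the number of true null markers
#'
#' Iterative histogram-based estimator of the number of true null hypotheses
#' among the tested markers. P-values are binned with width `bin_width`;
#' starting from `n2 = N`, each iteration finds `p*`, the left edge of the
#' lowest-P bin whose observed count does not exceed the count expected from
#' `n2` uniform nulls (`n2 * bin_width`), and re-estimates
#' `n2 = #(p > p*) / (1 - p*)`. Iteration stops when the estimate moves by
#' less than half a marker, or after 100 iterations. The result is rounded and
#' clipped to `[0, N]`.
#'
#' @param pvalues Numeric vector of P-values in (0, 1].
#' @param bin_width Histogram bin width; default 0.10.
#' @return Estimated number of true nulls, `n2`.
#' @export
estimate_true_nulls <- function(pvalues, bin_width = 0.10) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0L) stop("no P-values supplied")
  if (any(p <= 0 | p > 1)) stop("P-values must lie in (0, 1]")
  N <- length(p)
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  counts <- as.vector(table(cut(p, breaks = edges, include.lowest = TRUE,
                                right = TRUE)))
  left_edges <- edges[-length(edges)]

  n2 <- N
  for (iter in seq_len(100L)) {
    ok <- which(counts <= n2 * bin_width)
    if (length(ok) == 0L) { n2_new <- N } else {
      p_star <- left_edges[ok[1L]]
      n2_new <- sum(p > p_star) / (1 - p_star)
    }
    if (abs(n2_new - n2) < 0.5) { n2 <- n2_new; break }
    n2 <- n2_new
  }
  max(0L, min(N, as.integer(round(n2))))
}

#' Number of non-null (linked) markers
#'
#' @param N Total number of tested markers.
#' @param n2 Estimated number of true nulls.
#' @return `n1 = N - n2`.
#' @examples
#' n1_from_n2(35134, 26278) # 8856
#' n1_from_n2(35019, 22912) # 12107
#' @export
n1_from_n2 <- function(N, n2) {
  if (n2 < 0 || n2 > N) stop("n2 must lie in [0, N]")
  N - n2
}

#' False discovery rate thresholding (Benjamini-Hochberg step-up)
#'
#' Sorts the P-values and finds the largest `p(i)` with
#' `p(i) <= i * alpha / m`; all P-values at or below it are declared
#' significant. By default `m = N` (plain BH); supplying `n2` uses the
#' adaptive variant `m = n2`.
#'
#' @param pvalues Numeric vector of P-values.
#' @param alpha Target FDR level in (0, 1].
#' @param n2 Optional true-null count for the adaptive variant.
#' @return A list with `critical_p` (0 when nothing is significant),
#'   `significant` (logical vector aligned to `pvalues`) and `n_significant`.
#' @export
fdr_threshold <- function(pvalues, alpha, n2 = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  p <- pvalues
  ok <- !is.na(p)
  N <- sum(ok)
  m <- if (is.null(n2)) N else n2
  ps <- sort(p[ok])
  qualifies <- ps <= seq_len(N) * alpha / m
  if (m <= 0 || !any(qualifies)) {
    return(list(critical_p = 0,
                significant = ok & rep(FALSE, length(p)),
                n_significant = 0L))
  }
  critical_p <- ps[max(which(qualifies))]
  sig <- ok & !is.na(p) & p <= critical_p
  list(critical_p = critical_p, significant = sig,
       n_significant = sum(sig))
}

#' Detection power implied by an FDR row
#'
#' Of `R` markers declared significant at FDR level `fdr_level`, an expected
#' `R * (1 - fdr_level)` are true discoveries; dividing by the estimated
#' number of non-null markers `n1` gives the fraction of true associations
#' detected.
#'
#' @param R Number of declared significant markers.
#' @param fdr_level FDR level of the declaration.
#' @param n1 Estimated number of non-null markers.
#' @return Power in `[0, 1]`, or `NA` when `n1` is 0.
#' @examples
#' power_at_fdr(3043, 0.2, 8856)  # 0.275
#' power_at_fdr(7498, 0.2, 12107) # 0.495
#' @export
power_at_fdr <- function(R, fdr_level, n1) {
  if (is.na(n1) || n1 <= 0) return(NA_real_)
  min(1, max(0, R * (1 - fdr_level) / n1))
}

#' Multiplicity report across FDR levels
#'
#' Estimates the true-null and non-null marker counts and tabulates, for each
#' FDR level, the critical comparison-wise P-value, the number of declared
#' significant markers and the implied power. The declaration level used for
#' downstream QTL calling is `alpha = 0.2`.
#'
#' @param pvalues Numeric vector of per-marker P-values (masked markers `NA`).
#' @param fdr_levels FDR levels to tabulate; sorted increasingly in the output.
#' @param bin_width Bin width for [estimate_true_nulls()].
#' @param adaptive Use the adaptive (`m = n2`) BH variant; default plain BH.
#' @return An object of class `multiplicity_report`: a list with `N`, `n2`,
#'   `n1`, `adaptive` and `rows`, a data frame with columns `fdr_level`,
#'   `critical_p`, `n_significant`, `power`.
#' @export
build_report <- function(pvalues, fdr_levels = c(0.001, 0.01, 0.05, 0.1, 0.2),
                         bin_width = 0.10, adaptive = FALSE) {
  p <- pvalues[!is.na(pvalues)]
  N <- length(p)
  n2 <- estimate_true_nulls(p, bin_width = bin_width)
  n1 <- n1_from_n2(N, n2)
  fdr_levels <- sort(fdr_levels)
  rows <- do.call(rbind, lapply(fdr_levels, function(a) {
    th <- fdr_threshold(p, a, n2 = if (adaptive) n2 else NULL)
    data.frame(fdr_level = a, critical_p = th$critical_p,
               n_significant = th$n_significant,
               power = power_at_fdr(th$n_significant, a, n1))
  }))
  structure(list(N = N, n2 = n2, n1 = n1, adaptive = adaptive, rows = rows),
            class = "multiplicity_report")
}

#' @export
print.multiplicity_report <- function(x, ...) {
  cat(sprintf("Multiplicity report: N = %d, n2 = %d (true nulls), n1 = %d%s\n",
              x$N, x$n2, x$n1,
              if (x$adaptive) " [adaptive BH]" else " [plain BH]"))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Write a multiplicity report as TSV
#'
#' @param x A `multiplicity_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multiplicity_report <- function(x, path) {
  rows <- x$rows
  rows$N <- x$N; rows$n1 <- x$n1; rows$n2 <- x$n2
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
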