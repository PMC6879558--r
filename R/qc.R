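#' Marker quality-control filters
#'
#' Applies the four marker filters used before association testing:
#' \enumerate{
#'   \item caller concordance: keep only markers called concordantly by both
#'     variant callers (when the flag is supplied);
#'   \item parental purity: the YE-531 parent is haploid, so any genuine
#'     variant must have YE-531-allele frequency exactly 1 in pure YE-531
#'     samples. Markers failing this are removed only when the parental
#'     estimate is count-based with coverage of at least `parent_min_depth`
#'     reads; otherwise they are flagged but kept;
#'   \item dual-reference agreement: pool frequencies are estimated against
#'     both parental reference genomes; markers whose two estimates differ by
#'     more than `dual_ref_tol` (absolute) are removed. The primary estimate is
#'     the read-pooled frequency over all subpools;
#'   \item minor allele frequency: markers with pooled MAF below `maf_min` in
#'     the control category are removed (MAF exactly at the threshold is kept).
#' }
#' Filters with `NULL` inputs are skipped. Reporting uses first-failure
#' accounting in the order caller, parent, dual-reference, MAF, plus
#' independent per-rule tallies (a marker may fail several rules).
#'
#' @param markers A `marker_table`.
#' @param maf_min Minimum pooled minor allele frequency; default 0.05.
#' @param parent_freqs Optional numeric vector (aligned to `markers`) of
#'   YE-531-allele frequencies in pure YE-531 parental samples.
#' @param parent_depths Optional integer vector of parental read depths; when
#'   absent, the parental-purity rule flags rather than removes.
#' @param dual_ref Optional numeric vector: the frequency estimate obtained
#'   against the second reference genome.
#' @param caller_concordant Optional logical vector: concordant between the two
#'   variant callers.
#' @param dual_ref_tol Absolute tolerance for dual-reference agreement.
#' @param parent_min_depth Minimum parental coverage for the purity rule to
#'   remove (rather than flag) a marker.
#' @return A list with `markers` (the passing `marker_table`), and `report`,
#'   a list with `n_input`, `n_pass`, `first_failure` (named removal counts
#'   summing with `n_pass` to `n_input`), `per_rule` (independent tallies) and
#'   `flagged_parent_low_coverage`.
#' @export
filter_markers <- function(markers, maf_min = 0.05,
                           parent_freqs = NULL, parent_depths = NULL,
                           dual_ref = NULL, caller_concordant = NULL,
                           dual_ref_tol = 0.01, parent_min_depth = 10L) {
  n <- nrow(markers)
  for (arg in list(parent_freqs, parent_depths, dual_ref, caller_concordant))
    if (!is.null(arg) && length(arg) != n)
      stop("optional QC inputs must be aligned to the marker table")

  fail_caller <- if (is.null(caller_concordant)) rep(FALSE, n) else !caller_concordant

  flagged_parent <- rep(FALSE, n)
  if (is.null(parent_freqs)) {
    fail_parent <- rep(FALSE, n)
  } else {
    impure <- parent_freqs < 1
    if (is.null(parent_depths)) {
      fail_parent <- rep(FALSE, n)
      flagged_parent <- impure
    } else {
      deep <- !is.na(parent_depths) & parent_depths >= parent_min_depth
      fail_parent <- impure & deep
      flagged_parent <- impure & !deep
    }
  }

  if (is.null(dual_ref)) {
    fail_dual <- rep(FALSE, n)
  } else {
    primary <- pooled_frequency(markers)
    fail_dual <- !is.na(dual_ref) & !is.na(primary) &
      abs(dual_ref - primary) > dual_ref_tol
  }

  ctrl <- pooled_frequency(markers, category = "control")
  maf <- pmin(ctrl, 1 - ctrl)
  fail_maf <- !is.na(maf) & maf < maf_min

  per_rule <- c(caller_discordant = sum(fail_caller),
                parent_impure = sum(fail_parent),
                dual_ref_mismatch = sum(fail_dual),
                low_maf = sum(fail_maf))
  # first-failure accounting: caller -> parent -> dual-ref -> MAF
  ff_caller <- fail_caller
  ff_parent <- fail_parent & !ff_caller
  ff_dual <- fail_dual & !ff_caller & !ff_parent
  ff_maf <- fail_maf & !ff_caller & !ff_parent & !ff_dual
  first_failure <- c(caller_discordant = sum(ff_caller),
                     parent_impure = sum(ff_parent),
                     dual_ref_mismatch = sum(ff_dual),
                     low_maf = sum(ff_maf))

  pass <- !(fail_caller | fail_parent | fail_dual | fail_maf)
  out <- markers[pass, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(markers)
  attr(out, "design") <- attr(markers, "design")

  list(markers = out,
       report = list(n_input = n, n_pass = sum(pass),
                     first_failure = first_failure, per_rule = per_rule,
                     flagged_parent_low_coverage = sum(flagged_parent)))
}

# Read-pooled YE-531 frequency per marker, over all cells or one category.
pooled_frequency <- function(markers, category = NULL) {
  design <- attr(markers, "design")
  if (is.null(design)) design <- pool_design()
  cells <- design_cells(design)
  if (!is.null(category))
    cells <- cells[startsWith(cells, paste0(category, "_"))]
  ye <- rowSums(as.matrix(markers[paste0("cnt_", cells, "_ye531")]), na.rm = TRUE)
  ot <- rowSums(as.matrix(markers[paste0("cnt_", cells, "_other")]), na.rm = TRUE)
  tot <- ye + ot
  ifelse(tot > 0, ye / tot, NA_real_)
}

#' Parental origin of the major allele
#'
#' For one category of subpools, tabulates at how many markers the major
#' allele (frequency above 0.5, averaged over the category's subpools)
#' originates from YE-531 versus S288c, and counts markers where the YE-531
#' allele has been lost (frequency 0) or fixed (frequency 1). Under neutral
#' intercrossing from an F1 both proportions are expected near 0.5.
#'
#' @param freqs A `freq_matrix`.
#' @param category Category label, default `"control"`.
#' @return A list with `prop_ye531_major`, `prop_s288c_major` (proportions over
#'   non-tied markers, summing to 1), `n_tied` (frequency exactly 0.5),
#'   `n_lost`, `n_fixed` and `n_markers`.
#' @export
major_allele_origin <- function(freqs, category = "control") {
  cols <- grep(paste0("^", category, "_"), colnames(freqs$values))
  if (length(cols) == 0L) stop("category not present: ", category)
  f <- rowMeans(freqs$values[, cols, drop = FALSE])
  f <- f[!is.na(f)]
  if (length(f) == 0L) stop("no markers with defined frequency: result undefined")
  tied <- f == 0.5
  n_nontied <- sum(!tied)
  list(prop_ye531_major = if (n_nontied > 0) sum(f > 0.5) / n_nontied else NA_real_,
       prop_s288c_major = if (n_nontied > 0) sum(f < 0.5) / n_nontied else NA_real_,
       n_tied = sum(tied),
       n_lost = sum(f == 0),
       n_fixed = sum(f == 1),
       n_markers = length(f))
}
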