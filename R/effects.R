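#' Standardized truncation-selection intensity
#'
#' For a normally distributed trait, the mean standardized deviation of the
#' selected group when the top fraction `alpha` is kept is
#' `i = dnorm(qnorm(1 - alpha)) / alpha` (the standard-normal ordinate at the
#' truncation point over the selected proportion).
#'
#' @param alpha Selected proportion, in (0, 1).
#' @return Selection intensity `i`.
#' @examples
#' selection_intensity(0.5)   # ~0.798
#' selection_intensity(0.105) # ~1.732
#' @export
selection_intensity <- function(alpha) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  stats::dnorm(stats::qnorm(1 - alpha)) / alpha
}

#' Two-stage one-tail selection scheme
#'
#' Describes the selection design: a first mass-selection stage (fraction
#' surviving the stress) followed by a second stage keeping the top fraction
#' of individually phenotyped survivors. The combined selected proportion is
#' the product of the stages. In a one-tail design (one selected tail compared
#' against the unselected population) the mapping power is equivalent to a
#' two-tail design at twice the combined proportion; `intensity_alpha` is the
#' proportion actually fed to [selection_intensity()] for effect estimation
#' and defaults to the combined one-tail proportion.
#'
#' @param stage1 First-stage selected proportion; default 0.35.
#' @param stage2 Second-stage selected proportion; default 0.30.
#' @param design `"one_tail"` or `"two_tail"`.
#' @param intensity_alpha Proportion used for the intensity; default the
#'   combined proportion (`stage1 * stage2`).
#' @return An object of class `selection_scheme`.
#' @export
selection_scheme <- function(stage1 = 0.35, stage2 = 0.30,
                             design = c("one_tail", "two_tail"),
                             intensity_alpha = NULL) {
  design <- match.arg(design)
  if (any(c(stage1, stage2) <= 0 | c(stage1, stage2) > 1))
    stop("stage proportions must lie in (0, 1]")
  combined <- stage1 * stage2
  equivalent <- if (design == "one_tail") 2 * combined else combined
  if (is.null(intensity_alpha)) intensity_alpha <- combined
  structure(list(stage1_proportion = stage1, stage2_proportion = stage2,
                 combined = combined, design = design,
                 equivalent_proportion = equivalent,
                 intensity_alpha = intensity_alpha,
                 intensity = selection_intensity(intensity_alpha)),
            class = "selection_scheme")
}

#' @export
print.selection_scheme <- function(x, ...) {
  cat(sprintf("Selection scheme (%s): stages %.0f%% x %.0f%% = %.1f%%",
              x$design, 100 * x$stage1_proportion, 100 * x$stage2_proportion,
              100 * x$combined),
      sprintf("(two-tail equivalent %.0f%%); intensity i(%.3f) = %.3f\n",
              100 * x$equivalent_proportion, x$intensity_alpha, x$intensity))
  invisible(x)
}

#' Allele substitution effect from a tail-versus-control frequency shift
#'
#' Under truncation selection of the top fraction `alpha` on a normal trait,
#' the expected shift of an additive marker's allele frequency between the
#' selected tail and the unselected population is approximately
#' `D = p * q * (delta / sigma_p) * i(alpha)`, where `delta` is the allele
#' substitution effect (the phenotypic change per allele copy substituted).
#' Inverting gives `delta = D * sigma_p / (p * q * i)`.
#'
#' @param D Tail-minus-control frequency difference.
#' @param sigma_p Phenotypic standard deviation of the unselected population,
#'   in trait units.
#' @param p Frequency of the measured (YE-531) allele in the unselected
#'   population; `q = 1 - p`.
#' @param i Selection intensity from [selection_intensity()].
#' @param q Complementary allele frequency; default `1 - p`.
#' @return `delta` in trait units (`NA` where `p` is 0 or 1).
#' @export
allele_effect <- function(D, sigma_p, p, i, q = 1 - p) {
  if (sigma_p <= 0) stop("sigma_p must be positive")
  if (i <= 0) stop("selection intensity must be positive")
  ifelse(p > 0 & p < 1, D * sigma_p / (p * q * i), NA_real_)
}

#' Per-QTL allele effect from its top markers
#'
#' Aggregates per-marker allele effects within a QTL: the three members with
#' the smallest P-values (all members when fewer than three; ties broken by
#' larger |D| and then by position) supply the effect estimate. The QTL effect
#' is the mean of their absolute per-marker effects, signed by the majority
#' sign of their D-values, and `p_bar`/`q_bar` are the mean control-category
#' frequencies of the same markers. The favourable parent is YE-531 when the
#' signed effect is positive (YE-531 allele enriched in the tail).
#'
#' @param members Data frame of the QTL's member markers with columns `pos`,
#'   `P`, `D`, `freq_ctrl` and `delta` (per-marker effect from
#'   [allele_effect()]).
#' @return A one-row data frame with `delta`, `p_bar`, `q_bar`,
#'   `favorable_parent` and `n_top`.
#' @export
qtl_effect <- function(members) {
  if (nrow(members) == 0L) stop("QTL must have at least one member marker")
  ok <- members[!is.na(members$delta) & !is.na(members$P), , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(delta = NA_real_, p_bar = NA_real_, q_bar = NA_real_,
                      favorable_parent = NA_character_, n_top = 0L))
  ord <- order(ok$P, -abs(ok$D), ok$pos)
  top <- ok[ord[seq_len(min(3L, nrow(ok)))], , drop = FALSE]
  sign_major <- sign(sum(sign(top$D)))
  if (sign_major == 0) sign_major <- sign(top$D[1L])
  delta <- mean(abs(top$delta)) * sign_major
  p_bar <- mean(top$freq_ctrl)
  data.frame(delta = delta, p_bar = p_bar, q_bar = 1 - p_bar,
             favorable_parent = if (is.na(delta)) NA_character_
                                else if (delta >= 0) "YE-531" else "S288c",
             n_top = nrow(top), stringsAsFactors = FALSE)
}

#' Contribution of a QTL to the phenotypic variance
#'
#' For a biallelic additive QTL with allele frequencies `p_bar`, `q_bar` and
#' allele substitution effect `delta`, the contributed variance is
#' `VarQ = 2 * p_bar * q_bar * delta^2`; the fraction of the phenotypic
#' variance is `VarQ / var_pheno`.
#'
#' @param delta Allele substitution effect in trait units.
#' @param p_bar,q_bar Mean allele frequencies of the QTL's top markers.
#' @param var_pheno Phenotypic variance of the trait.
#' @return A list with `var_q` and `fraction`.
#' @examples
#' variance_contribution(0.018, 0.5, 0.5, 0.148^2)$fraction # ~0.0074
#' @export
variance_contribution <- function(delta, p_bar, q_bar, var_pheno) {
  if (var_pheno <= 0) stop("var_pheno must be positive")
  var_q <- 2 * p_bar * q_bar * delta^2
  list(var_q = var_q, fraction = var_q / var_pheno)
}

#' Estimate allele effects for a set of called QTLs
#'
#' Convenience wrapper tying the association scan to the effect model:
#' per-marker effects are computed with [allele_effect()] using the control
#' frequency at each member marker, aggregated per QTL with [qtl_effect()],
#' and converted to variance contributions.
#'
#' @param qtls A `qtl_intervals` data frame with `members` indexing `assoc`.
#' @param assoc The matching `association_result`.
#' @param scheme A [selection_scheme()].
#' @param sigma_p Phenotypic SD of the trait in the unselected population.
#' @param var_pheno Phenotypic variance; default `sigma_p^2`.
#' @return Data frame with one row per QTL: `chrom`, `peak_pos`, `delta`,
#'   `delta_sdu`, `p_bar`, `var_q`, `var_fraction`, `favorable_parent`.
#' @export
estimate_qtl_effects <- function(qtls, assoc, scheme, sigma_p,
                                 var_pheno = sigma_p^2) {
  i <- scheme$intensity
  rows <- lapply(seq_len(nrow(qtls)), function(r) {
    m <- assoc[qtls$members[[r]], , drop = FALSE]
    m$delta <- allele_effect(m$D, sigma_p, m$freq_ctrl, i)
    eff <- qtl_effect(m)
    vc <- variance_contribution(eff$delta, eff$p_bar, eff$q_bar, var_pheno)
    data.frame(chrom = qtls$chrom[r], peak_pos = qtls$peak_pos[r],
               delta = eff$delta, delta_sdu = eff$delta / sigma_p,
               p_bar = eff$p_bar, var_q = vc$var_q,
               var_fraction = vc$fraction,
               favorable_parent = eff$favorable_parent,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), peak_pos = integer(0),
                      delta = numeric(0), delta_sdu = numeric(0),
                      p_bar = numeric(0), var_q = numeric(0),
                      var_fraction = numeric(0),
                      favorable_parent = character(0)))
  do.call(rbind, rows)
}

#' Summaries of QTL allele effects
#'
#' Expresses QTL effects on the standard-deviation and percent-of-mean scales
#' and totals their variance contributions; when a heritability is supplied,
#' the total phenotypic-variance fraction is also expressed as a fraction of
#' the genetic variance (`total / h2`, capped at 1).
#'
#' @param effects Data frame from [estimate_qtl_effects()].
#' @param sigma_p Phenotypic SD in trait units.
#' @param trait_mean Trait mean in trait units.
#' @param heritability Optional narrow-sense heritability.
#' @return A list with mean/min/max of `|delta|` and `|delta_sdu|`,
#'   `pct_of_mean` (mean |delta| over the trait mean), `total_fraction` of
#'   phenotypic variance and optionally `genetic_fraction`.
#' @export
summarize_effects <- function(effects, sigma_p, trait_mean,
                              heritability = NULL) {
  if (sigma_p <= 0) stop("sigma_p must be positive")
  d <- abs(effects$delta)
  d <- d[!is.na(d)]
  out <- list(n = length(d),
              delta_mean = mean(d), delta_min = suppressWarnings(min(d)),
              delta_max = suppressWarnings(max(d)),
              delta_sdu_mean = mean(d) / sigma_p,
              pct_of_mean = 100 * mean(d) / trait_mean,
              total_fraction = sum(effects$var_fraction, na.rm = TRUE))
  if (!is.null(heritability))
    out$genetic_fraction <- min(1, out$total_fraction / heritability)
  out
}
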