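test_that("selection_intensity matches the normal-theory ordinate formula", {
  expect_equal(selection_intensity(0.5), dnorm(0) / 0.5)
  expect_equal(selection_intensity(0.105),
               dnorm(qnorm(1 - 0.105)) / 0.105)
  expect_equal(round(selection_intensity(0.105), 3), 1.732)
  # monotone: stronger selection, larger intensity
  expect_true(selection_intensity(0.05) > selection_intensity(0.5))
  expect_error(selection_intensity(0), "\\(0, 1\\)")
  expect_error(selection_intensity(1), "\\(0, 1\\)")
})

test_that("selection_scheme encodes the two-stage design arithmetic", {
  sc <- selection_scheme()
  expect_equal(sc$combined, 0.35 * 0.30)
  expect_equal(sc$combined, 0.105)
  expect_equal(sc$equivalent_proportion, 0.21)  # one-tail ~ two-tail at 21%
  expect_equal(sc$intensity_alpha, 0.105)
  expect_equal(sc$intensity, selection_intensity(0.105))
  # equivalent number of segregants scored in a two-tail design
  expect_equal(round(90 / sc$equivalent_proportion), 429)
  sc2 <- selection_scheme(design = "two_tail")
  expect_equal(sc2$equivalent_proportion, sc2$combined)
  sc3 <- selection_scheme(intensity_alpha = 0.21)
  expect_equal(sc3$intensity, selection_intensity(0.21))
  expect_error(selection_scheme(stage1 = 0), "\\(0, 1\\]")
})

test_that("allele_effect inverts D = p q (delta/sigma) i exactly", {
  i <- selection_intensity(0.105)
  for (p in c(0.2, 0.5, 0.8)) {
    for (delta in c(-0.3, 0.05, 0.4)) {
      sigma <- 1.7
      D <- p * (1 - p) * (delta / sigma) * i
      expect_equal(allele_effect(D, sigma, p, i), delta)
    }
  }
  expect_true(is.na(allele_effect(0.1, 1, 0, i)))
  expect_true(is.na(allele_effect(0.1, 1, 1, i)))
  expect_error(allele_effect(0.1, 0, 0.5, i), "sigma_p")
  expect_error(allele_effect(0.1, 1, 0.5, 0), "intensity")
})

test_that("qtl_effect averages the top three markers with tie rules", {
  members <- data.frame(
    pos = c(100L, 200L, 300L, 400L, 500L),
    P = c(1e-3, 1e-6, 1e-6, 1e-2, 0.5),
    D = c(0.10, 0.20, -0.20, 0.05, 0.01),
    freq_ctrl = c(0.5, 0.4, 0.6, 0.5, 0.5),
    delta = c(0.10, 0.22, -0.21, 0.06, 0.01))
  eff <- qtl_effect(members)
  # top three by P: rows 2, 3 (tied P, |D| tied, position breaks), then 1
  expect_equal(eff$n_top, 3L)
  expect_equal(abs(eff$delta), mean(abs(c(0.22, -0.21, 0.10))))
  # majority D sign among the top three is positive -> YE-531 favorable
  expect_equal(eff$favorable_parent, "YE-531")
  expect_gt(eff$delta, 0)
  expect_equal(eff$p_bar, mean(c(0.4, 0.6, 0.5)))
  expect_equal(eff$q_bar, 1 - eff$p_bar)

  # negative majority flips the favorable parent
  members$D <- -members$D
  members$delta <- -members$delta
  eff2 <- qtl_effect(members)
  expect_equal(eff2$favorable_parent, "S288c")
  expect_equal(eff2$delta, -eff$delta)

  # fewer than three usable markers: use all of them
  eff3 <- qtl_effect(members[1:2, ])
  expect_equal(eff3$n_top, 2L)
  expect_error(qtl_effect(members[0, ]), "at least one member")
})

test_that("variance_contribution reproduces the printed worked examples", {
  vc <- variance_contribution(0.018, 0.5, 0.5, 0.148^2)
  expect_equal(vc$var_q, 2 * 0.25 * 0.018^2)
  expect_equal(round(100 * vc$fraction, 1), 0.7)
  expect_error(variance_contribution(0.1, 0.5, 0.5, 0), "positive")
})

test_that("estimate_qtl_effects ties the scan to the effect model", {
  # two synthetic QTLs with known per-marker D consistent with delta
  i <- selection_intensity(0.105)
  sigma <- 2
  assoc <- data.frame(
    chrom = rep("chr01", 6), pos = seq(100L, 600L, by = 100L),
    freq_ctrl = 0.5, freq_tail = NA_real_,
    D = 0.25 * (0.3 / sigma) * i * c(1, 1, 1, -1, -1, -1),
    SE = 0.01, Z = 1, P = c(1e-5, 1e-6, 1e-5, 1e-4, 1e-6, 1e-4),
    masked = FALSE)
  qtls <- data.frame(chrom = "chr01", start = c(100L, 400L),
                     end = c(300L, 600L), peak_pos = c(200L, 500L),
                     peak_score = c(6, 6), n_markers = 3L, length_bp = 201L)
  qtls$members <- list(1:3, 4:6)
  eff <- estimate_qtl_effects(qtls, assoc, selection_scheme(), sigma)
  expect_equal(nrow(eff), 2L)
  expect_equal(eff$delta, c(0.3, -0.3))
  expect_equal(eff$delta_sdu, c(0.15, -0.15))
  expect_equal(eff$favorable_parent, c("YE-531", "S288c"))
  expect_equal(eff$var_q, 2 * 0.25 * 0.3^2 * c(1, 1))
  expect_equal(eff$var_fraction, eff$var_q / sigma^2)
  # empty input gives an empty, well-typed frame
  expect_equal(nrow(estimate_qtl_effects(qtls[0, ], assoc,
                                         selection_scheme(), sigma)), 0L)
})

test_that("summarize_effects aggregates to the published bookkeeping scales", {
  eff <- data.frame(delta = c(0.018, -0.018),
                    var_fraction = c(0.007, 0.007))
  s <- summarize_effects(eff, sigma_p = 0.148, trait_mean = 0.698,
                         heritability = 0.5)
  expect_equal(round(s$pct_of_mean, 1), 2.6)
  expect_equal(s$delta_sdu_mean, 0.018 / 0.148)
  expect_equal(s$total_fraction, 0.014)
  expect_equal(s$genetic_fraction, 0.014 / 0.5)
  # fraction of genetic variance capped at 1; e.g. 34.7% of 50% -> 69%
  s2 <- summarize_effects(data.frame(delta = 0.1, var_fraction = 0.347),
                          sigma_p = 1, trait_mean = 1, heritability = 0.5)
  expect_equal(round(100 * s2$genetic_fraction), 69)
})
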