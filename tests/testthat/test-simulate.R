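# Desk-scale config: pop_size 900 keeps the study's stage proportions exact
# (stage 1 keeps 315 >= stage2_sample 300).
small_config <- function(pop_size = 900, ...) {
  sim_config(chrom_lengths = c(chrA = 1e5, chrB = 1e5),
             markers_per_chrom = 100, pop_size = pop_size, ...)
}

test_that("make_parents lays out the map and fixed-different founders", {
  cfg <- small_config()
  par <- make_parents(cfg)
  expect_equal(nrow(par$map), 200L)
  expect_equal(unique(par$map$chrom), c("chrA", "chrB"))
  expect_true(all(par$hap_s288c == 0L))
  expect_true(all(par$hap_ye531 == 1L))
  # genetic positions follow the configured cM/kb rate (Morgans)
  expect_equal(par$map$gpos,
               par$map$pos / 1000 * cfg$recomb_rate_cm_per_kb / 100)
})

test_that("meiosis recombines at a Poisson rate on the genetic map", {
  cfg <- small_config()
  par <- make_parents(cfg)
  set.seed(41)
  g <- meiosis(par$hap_s288c, par$hap_ye531, par$map)
  expect_true(all(g %in% 0:1))
  # crossover counts are Poisson with mean = total genetic length
  n_xo <- replicate(400, attr(meiosis(par$hap_s288c, par$hap_ye531,
                                      par$map), "n_crossovers"))
  L <- sum(tapply(par$map$gpos, par$map$chrom, function(g) diff(range(g))))
  expect_equal(mean(n_xo), L, tolerance = 0.15)
  # each chromosome starts on a single parental haplotype (no new alleles)
  expect_true(all(diff(which(diff(g) != 0)) >= 1))
})

test_that("neutral AIL keeps frequencies near 0.5 (martingale) and drifts", {
  cfg <- small_config(n_generations = 4, seed = 42)
  set.seed(cfg$seed)
  pop <- advance_generations(cfg)
  f <- colMeans(pop$h1 + pop$h2) / 2
  expect_true(all(f >= 0 & f <= 1))           # no new alleles
  expect_equal(mean(f), 0.5, tolerance = 0.03)
  expect_gt(stats::sd(f), 0)                  # drift happened
  # drift_multiplier > 1 increases the frequency dispersion (averaged over
  # replicate populations: per-run SDs are noisy under linkage)
  mean_sd <- function(mult) {
    mean(vapply(1:5, function(s) {
      set.seed(s)
      pop <- advance_generations(small_config(
        pop_size = 400, n_generations = 4, drift_multiplier = mult))
      stats::sd(colMeans(pop$h1 + pop$h2) / 2)
    }, numeric(1)))
  }
  expect_gt(mean_sd(20), mean_sd(1))
})

test_that("assign_phenotypes applies the additive model and h2 scaling", {
  cfg <- small_config(seed = 43)
  map <- make_parents(cfg)$map
  qtl <- data.frame(chrom = c("chrA", "chrB"), pos = map$pos[c(50, 150)],
                    delta = c(0.4, 0.3),
                    favorable_parent = c("YE-531", "S288c"),
                    trait = c("survival", "both"))
  cfg <- small_config(qtl_truth = qtl, h2 = c(growth = 0.4, survival = 0.6),
                      seed = 43)
  set.seed(43)
  pop <- advance_generations(cfg)
  ph <- assign_phenotypes(pop, cfg, "survival")
  # genotypic value equals dosage (favorable-allele count) times delta
  dos_a <- pop$h1[, qtl$pos[1] == pop$map$pos & pop$map$chrom == "chrA"] +
    pop$h2[, qtl$pos[1] == pop$map$pos & pop$map$chrom == "chrA"]
  dos_b <- 2 - (pop$h1[, pop$map$chrom == "chrB" & pop$map$pos == qtl$pos[2]] +
                pop$h2[, pop$map$chrom == "chrB" & pop$map$pos == qtl$pos[2]])
  expect_equal(ph$genotypic, dos_a * 0.4 + dos_b * 0.3)
  # realized heritability close to the configured value
  h2_real <- stats::var(ph$genotypic) / stats::var(ph$latent)
  expect_equal(h2_real, 0.6, tolerance = 0.12)
  # growth sees only the "both" QTL
  ph_g <- assign_phenotypes(pop, cfg, "growth")
  expect_equal(ph_g$genotypic, dos_b * 0.3)
  # a QTL off the marker map errors
  bad <- cfg; bad$qtl_truth$pos[1] <- 12345L
  expect_error(assign_phenotypes(pop, bad, "survival"), "absent from")
})

test_that("survival scores span 0-14 with no mass outside", {
  cfg <- small_config(seed = 44)
  set.seed(44)
  pop <- advance_generations(cfg)
  ph <- assign_phenotypes(pop, cfg, "survival")
  expect_true(all(ph$observed %in% 0:14))
  expect_equal(sort(unique(ph$observed)), 0:14)
  # growth stays continuous
  ph_g <- assign_phenotypes(pop, cfg, "growth")
  expect_equal(ph_g$observed, ph_g$latent)
})

test_that("two_stage_select truncates on survival then per-trait", {
  cfg <- small_config(stage2_sample = 60, stage2_top = 30, seed = 45)
  set.seed(45)
  pop <- advance_generations(cfg)
  ph_g <- assign_phenotypes(pop, cfg, "growth")
  ph_s <- assign_phenotypes(pop, cfg, "survival")
  sel <- two_stage_select(ph_g, ph_s, cfg)
  n1 <- round(0.35 * 900)
  expect_length(sel$stage1, n1)
  expect_equal(min(ph_s$latent[sel$stage1]),
               sort(ph_s$latent, decreasing = TRUE)[n1])
  expect_true(all(sel$stage2 %in% sel$stage1))
  expect_length(sel$tail_survival, 30L)
  expect_true(all(sel$tail_survival %in% sel$stage2))
  # survival tail = the top 30 of the stage-2 sample by survival
  expect_setequal(sel$tail_survival,
                  sel$stage2[order(ph_s$latent[sel$stage2],
                                   decreasing = TRUE)[1:30]])
  expect_error(two_stage_select(ph_g, ph_s,
                                small_config(stage2_sample = 400)),
               "too small")
})

test_that("pool_and_sequence reproduces pool frequencies within noise", {
  cfg <- small_config(coverage = 5000, seed = 46)
  set.seed(46)
  pop <- advance_generations(cfg)
  d <- pool_design()
  cells <- ailqtl:::design_cells(d)
  members <- stats::setNames(
    lapply(seq_along(cells), function(j) sample(nrow(pop$h1), 30L)), cells)
  out <- pool_and_sequence(pop, members, cfg, d)
  expect_s3_class(out$markers, "marker_table")
  fr <- pool_frequencies(out$markers)
  err <- abs(fr$values - out$true_freq)
  expect_lt(max(err, na.rm = TRUE), 0.06)   # binomial noise at 5000x
  expect_lt(mean(err, na.rm = TRUE), 0.01)
  # base_error pulls observed frequencies towards 0.5
  cfg2 <- small_config(coverage = 5000, base_error = 0.4)
  set.seed(1)
  out2 <- pool_and_sequence(pop, members, cfg2, d)
  fr2 <- pool_frequencies(out2$markers)
  dev0 <- mean(abs(fr$values - 0.5), na.rm = TRUE)
  dev4 <- mean(abs(fr2$values - 0.5), na.rm = TRUE)
  expect_lt(dev4, dev0)
})

test_that("zero-depth cells become missing counts", {
  cfg <- small_config(coverage = 0.5, seed = 47)
  set.seed(47)
  pop <- advance_generations(cfg)
  d <- pool_design()
  cells <- ailqtl:::design_cells(d)
  members <- stats::setNames(
    lapply(seq_along(cells), function(j) 1:30), cells)
  out <- pool_and_sequence(pop, members, cfg, d)
  expect_true(anyNA(out$markers$cnt_growth_1_ye531))
  na_ye <- is.na(out$markers$cnt_growth_1_ye531)
  expect_equal(na_ye, is.na(out$markers$cnt_growth_1_other))
})

test_that("simulate_ail is reproducible and its truth is self-consistent", {
  map <- make_parents(small_config())$map
  qtl <- data.frame(chrom = "chrA", pos = map$pos[40], delta = 0.5,
                    favorable_parent = "YE-531", trait = "survival")
  cfg <- small_config(qtl_truth = qtl, seed = 48)
  sim1 <- simulate_ail(cfg)
  sim2 <- simulate_ail(cfg)
  expect_equal(sim1$markers, sim2$markers)   # same seed, same data
  tq <- sim1$truth$qtl
  expect_equal(tq$realized_shift, tq$tail_freq - tq$pop_freq)
  expect_equal(tq$delta_sdu_realized, tq$delta / tq$sigma_p)
  expect_gt(tq$realized_shift[1], 0)         # favorable allele enriched
  # aliquot controls: replicates are the census population
  expect_equal(sim1$truth$members$control_1, seq_len(cfg$pop_size))
  expect_equal(unname(sim1$truth$true_pool_freq[, "control_2"]),
               unname(sim1$truth$pop_freq))
  # subpool mode draws disjoint 30-member control pools
  sim3 <- simulate_ail(small_config(qtl_truth = qtl, seed = 48,
                                    control_mode = "subpool"))
  ctrl <- sim3$truth$members[paste0("control_", 1:3)]
  expect_true(all(lengths(ctrl) == 30L))
  expect_equal(anyDuplicated(unlist(ctrl)), 0L)
})

test_that("expected tail-control D at a QTL matches p q (delta/sigma) i", {
  # closes the loop with the effect estimator: average the realized shift at
  # a strong QTL over replicate simulations and compare with the truncation
  # formula at the combined selected proportion
  map <- make_parents(small_config())$map
  qtl <- data.frame(chrom = "chrA", pos = map$pos[50], delta = 0.6,
                    favorable_parent = "YE-531", trait = "survival")
  i_exp <- selection_intensity(0.35 * 0.30)
  diffs <- vapply(1:12, function(s) {
    sim <- simulate_ail(small_config(pop_size = 2000, qtl_truth = qtl,
                                     seed = 500 + s,
                                     h2 = c(growth = 0.5, survival = 0.1)))
    tq <- sim$truth$qtl
    expected <- tq$pop_freq * (1 - tq$pop_freq) * tq$delta_sdu_realized * i_exp
    tq$realized_shift - expected
  }, numeric(1))
  mc_se <- stats::sd(diffs) / sqrt(length(diffs))
  # allow a small margin for the first-order approximation of the formula
  expect_lt(abs(mean(diffs)), 3 * mc_se + 0.02)
})

test_that("emit_simulation writes markers, truth and config; reruns identical", {
  map <- make_parents(small_config())$map
  qtl <- data.frame(chrom = "chrA", pos = map$pos[40], delta = 0.5,
                    favorable_parent = "YE-531", trait = "both")
  cfg <- small_config(qtl_truth = qtl, seed = 49)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  emit_simulation(simulate_ail(cfg), dir1)
  emit_simulation(simulate_ail(cfg), dir2)
  for (f in c("markers.tsv", "truth.json", "config.json")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  back <- read_marker_table(file.path(dir1, "markers.tsv"))
  expect_equal(nrow(back), 200L)
  truth <- jsonlite::read_json(file.path(dir1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$qtl$pos, rep(qtl$pos, 2L))  # both traits
  expect_equal(truth$members$control_1, "all")   # census pools compressed
})

test_that("simulate_drift matches binomial theory", {
  set.seed(50)
  p <- simulate_drift(p0 = 0.5, ne = 1000, n_generations = 6,
                      n_reps = 20000)
  expect_equal(mean(p), 0.5, tolerance = 0.005)   # martingale
  # cumulative SD ~ sqrt(sum_g p q / ne) ~ sqrt(6 * 0.25 / 1000)
  expect_equal(stats::sd(p), sqrt(6 * 0.25 / 1000), tolerance = 0.05)
  # one generation
  p1 <- simulate_drift(n_generations = 1, n_reps = 20000)
  expect_equal(stats::sd(p1), sqrt(0.25 / 1000), tolerance = 0.03)
})
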