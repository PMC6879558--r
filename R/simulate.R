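#' Configuration of a simulated AIL pool-seq experiment
#'
#' Collects every parameter of the forward simulation: genome and marker map,
#' recombination rate, intercross depth and population size, the additive QTL
#' truth, trait heritabilities, the two-stage one-tail selection design,
#' pooling layout and sequencing noise. Defaults reproduce the study design
#' (six AIL generations, 35 percent stage-1 survival, 300 sampled segregants
#' with the top 90 kept, three subpools of 30 diploids per category, about
#' 1,000x coverage) on a reduced two-chromosome genome that keeps forward
#' simulation tractable on a desktop.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param markers_per_chrom Markers per chromosome (evenly spaced); the default
#'   gives about 3 markers per kb on the default 300 kb chromosomes, the
#'   study's marker density, so that an 80-marker smoothing span covers the
#'   same physical window (about 28 kb).
#' @param recomb_rate_cm_per_kb Recombination rate; default 0.38 cM/kb, a
#'   yeast-like value.
#' @param n_generations AIL depth, counting the F1 as generation 1; default 6
#'   (five rounds of intercrossing).
#' @param pop_size Population size per generation; default 10,000.
#' @param qtl_truth Data frame with columns `chrom`, `pos`, `delta`
#'   (allele substitution effect per allele copy, on the latent trait scale),
#'   `favorable_parent` (`"YE-531"` or `"S288c"`) and `trait`
#'   (`"growth"`, `"survival"` or `"both"`). May be empty (neutral run).
#' @param h2 Named vector of trait heritabilities; default 0.5 for both traits.
#' @param stage1_survival Fraction surviving the stage-1 ethanol shock
#'   (selection on the survival phenotype); default 0.35.
#' @param stage2_sample Segregants sampled from stage-1 survivors; default 300.
#' @param stage2_top Top-ranked segregants kept per trait; default 90.
#' @param subpools Replicate subpools per category; default 3.
#' @param subpool_size Diploid individuals per tail subpool; default 30.
#' @param control_mode How control replicates are formed. `"aliquot"` (the
#'   default) treats each control replicate as a bulk aliquot of the entire
#'   unselected population, so replicates differ only by sequencing noise --
#'   matching the small among-replicate variance of bulk control pools.
#'   `"subpool"` draws `subpools` disjoint random subpools of `subpool_size`
#'   individuals, adding individual-sampling variance.
#' @param coverage Mean sequencing depth per marker and subpool; default 1000.
#' @param base_error Per-read allele flip probability; default 0.
#' @param drift_multiplier Clonal-amplification factor: each breeding round
#'   draws parents from a random subset of `pop_size / drift_multiplier`
#'   individuals, inflating drift; default 1 (off).
#' @param discretize_survival Report the survival phenotype as a 0-14 score
#'   (equal-probability bins of the latent scale); default `TRUE`. Selection
#'   always uses the latent value.
#' @param seed Optional random seed applied by [simulate_ail()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr01 = 3e5, chr02 = 3e5),
                       markers_per_chrom = 900,
                       recomb_rate_cm_per_kb = 0.38,
                       n_generations = 6,
                       pop_size = 10000,
                       qtl_truth = NULL,
                       h2 = c(growth = 0.5, survival = 0.5),
                       stage1_survival = 0.35,
                       stage2_sample = 300,
                       stage2_top = 90,
                       subpools = 3,
                       subpool_size = 30,
                       control_mode = c("aliquot", "subpool"),
                       coverage = 1000,
                       base_error = 0,
                       drift_multiplier = 1,
                       discretize_survival = TRUE,
                       seed = NULL) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%02d", seq_along(chrom_lengths))
  if (stage2_top > stage2_sample)
    stop("stage2_top must not exceed stage2_sample")
  stopifnot(stage1_survival > 0, stage1_survival <= 1,
            n_generations >= 2, pop_size >= 2)
  if (is.null(qtl_truth))
    qtl_truth <- data.frame(chrom = character(0), pos = integer(0),
                            delta = numeric(0),
                            favorable_parent = character(0),
                            trait = character(0))
  structure(list(chrom_lengths = chrom_lengths,
                 markers_per_chrom = markers_per_chrom,
                 recomb_rate_cm_per_kb = recomb_rate_cm_per_kb,
                 n_generations = n_generations, pop_size = as.integer(pop_size),
                 qtl_truth = qtl_truth, h2 = h2,
                 stage1_survival = stage1_survival,
                 stage2_sample = as.integer(stage2_sample),
                 stage2_top = as.integer(stage2_top),
                 subpools = as.integer(subpools),
                 subpool_size = as.integer(subpool_size),
                 control_mode = match.arg(control_mode),
                 coverage = coverage, base_error = base_error,
                 drift_multiplier = drift_multiplier,
                 discretize_survival = discretize_survival, seed = seed),
            class = "sim_config")
}

#' Founder genomes and marker map
#'
#' Lays out evenly spaced markers on each chromosome and returns the two
#' haploid founder genomes: parent A (S288c) carries allele 0 at every marker,
#' parent B (YE-531) allele 1, so markers are fixed-different between parents
#' and the F1 is heterozygous everywhere (YE-531 frequency exactly 0.5).
#' Genetic positions follow the configured uniform cM/kb rate.
#'
#' @param config A [sim_config()].
#' @return A list with `map` (data frame `chrom`, `pos`, `gpos` in Morgans),
#'   `hap_s288c` and `hap_ye531` (integer vectors).
#' @export
make_parents <- function(config) {
  pieces <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    m <- config$markers_per_chrom
    if (m == 0L) return(NULL)
    pos <- as.integer(round(seq(1, len, length.out = m)))
    pos <- unique(pos)
    data.frame(chrom = ch, pos = pos,
               gpos = pos / 1000 * config$recomb_rate_cm_per_kb / 100,
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  map <- if (length(pieces) > 0L) do.call(rbind, pieces)
         else data.frame(chrom = character(0), pos = integer(0),
                         gpos = numeric(0))
  rownames(map) <- NULL
  list(map = map,
       hap_s288c = rep(0L, nrow(map)),
       hap_ye531 = rep(1L, nrow(map)))
}

#' Simulate one meiotic gamete
#'
#' Crossovers per chromosome are Poisson with mean equal to the chromosome's
#' genetic length in Morgans, positions uniform on the genetic map, with no
#' interference (Haldane model). The gamete starts on a random parental
#' haplotype and switches at each crossover.
#'
#' @param h1,h2 The diploid's two haplotypes (integer vectors over the map).
#' @param map Marker map from [make_parents()].
#' @return Integer vector: the gamete's allele at every marker. The realized
#'   crossover count is attached as attribute `"n_crossovers"`.
#' @export
meiosis <- function(h1, h2, map) {
  out <- integer(nrow(map))
  n_xo <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    g <- map$gpos[idx]
    L <- g[length(g)] - g[1L]
    k <- stats::rpois(1L, L)
    n_xo <- n_xo + k
    start <- sample(0:1, 1L)
    phase <- if (k == 0L) rep(start, length(g)) else
      (start + findInterval(g, sort(stats::runif(k, g[1L], g[length(g)])))) %% 2L
    out[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
  }
  structure(out, n_crossovers = n_xo)
}

# Vectorised gamete factory: one gamete per row of `parents` (indices into
# pop). Same crossover model as meiosis().
make_gametes <- function(pop, map, parents) {
  n <- length(parents)
  out <- matrix(0L, n, nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    g <- map$gpos[idx]
    L <- g[length(g)] - g[1L]
    K <- stats::rpois(n, L)
    start <- sample(0:1, n, replace = TRUE)
    h1 <- pop$h1[parents, idx, drop = FALSE]
    h2 <- pop$h2[parents, idx, drop = FALSE]
    for (i in seq_len(n)) {
      if (K[i] == 0L) {
        out[i, idx] <- if (start[i] == 0L) h1[i, ] else h2[i, ]
      } else {
        xo <- sort(stats::runif(K[i], g[1L], g[length(g)]))
        phase <- (start[i] + findInterval(g, xo)) %% 2L
        row <- h1[i, ]
        sel <- phase == 1L
        row[sel] <- h2[i, sel]
        out[i, idx] <- row
      }
    }
  }
  out
}

#' Advance an intercross population to the final AIL generation
#'
#' Starts from a fully heterozygous F1 of `pop_size` diploids and performs
#' `n_generations - 1` rounds of random intercrossing: each offspring receives
#' one recombinant gamete from each of two parents drawn at random with
#' replacement. A `drift_multiplier` above 1 restricts each round's breeders
#' to a random subset, emulating the extra allele-frequency variance from
#' clonal reproduction and fitness selection between sexual generations.
#'
#' @param config A [sim_config()].
#' @return A list with `map` and haplotype matrices `h1`, `h2`
#'   (`pop_size` x markers, 0 = S288c allele, 1 = YE-531 allele).
#' @export
advance_generations <- function(config) {
  founders <- make_parents(config)
  map <- founders$map
  n <- config$pop_size
  M <- nrow(map)
  pop <- list(h1 = matrix(0L, n, M), h2 = matrix(1L, n, M))
  n_rounds <- config$n_generations - 1L
  for (gen in seq_len(n_rounds)) {
    breeders <- seq_len(n)
    if (config$drift_multiplier > 1) {
      n_eff <- max(2L, as.integer(round(n / config$drift_multiplier)))
      breeders <- sample.int(n, n_eff)
    }
    mothers <- sample(breeders, n, replace = TRUE)
    fathers <- sample(breeders, n, replace = TRUE)
    pop <- list(h1 = make_gametes(pop, map, mothers),
                h2 = make_gametes(pop, map, fathers))
  }
  pop$map <- map
  pop
}

#' Assign trait phenotypes to a simulated population
#'
#' The genotypic value of an individual is the sum over the trait's QTLs of
#' its favorable-allele count times the allele substitution effect `delta`
#' (additive model, effect per allele copy). Environmental noise is normal
#' and scaled so that the genotypic variance is the fraction `h2` of the total
#' phenotypic variance. For the survival trait the observed phenotype is a
#' 0-14 score obtained from equal-probability bins of the latent value
#' (selection and truth bookkeeping use the latent value).
#'
#' @param pop Population from [advance_generations()].
#' @param config A [sim_config()].
#' @param trait `"growth"` or `"survival"`.
#' @return A list with `latent` (continuous phenotype), `observed` (equals
#'   `latent` for growth; the 0-14 score for survival when configured),
#'   `genotypic` (QTL genotypic values), `sigma_p` (SD of the latent
#'   phenotype) and `qtl` (the trait's QTL table with marker indices).
#' @export
assign_phenotypes <- function(pop, config, trait) {
  n <- nrow(pop$h1)
  qt <- config$qtl_truth
  qt <- qt[qt$trait %in% c(trait, "both"), , drop = FALSE]
  idx <- integer(0)
  g <- numeric(n)
  if (nrow(qt) > 0L) {
    idx <- match(paste(qt$chrom, qt$pos), paste(pop$map$chrom, pop$map$pos))
    if (anyNA(idx))
      stop("QTL at a position absent from the marker map: ",
           paste(paste(qt$chrom, qt$pos)[is.na(idx)], collapse = ", "))
    dosage <- pop$h1[, idx, drop = FALSE] + pop$h2[, idx, drop = FALSE]
    flip <- qt$favorable_parent == "S288c"
    dosage[, flip] <- 2L - dosage[, flip]
    g <- as.vector(dosage %*% qt$delta)
  }
  vg <- stats::var(g)
  h2 <- config$h2[[trait]]
  if (h2 <= 0) {
    latent <- stats::rnorm(n)   # trait carries no genetic signal
  } else {
    ve <- if (h2 >= 1) 0 else if (vg > 0) vg * (1 - h2) / h2 else 1
    latent <- g + stats::rnorm(n, 0, sqrt(ve))
  }
  observed <- latent
  if (trait == "survival" && config$discretize_survival) {
    br <- stats::quantile(latent, probs = seq(0, 1, length.out = 16L),
                          names = FALSE)
    br[1L] <- -Inf; br[16L] <- Inf
    observed <- as.integer(cut(latent, breaks = br, labels = FALSE,
                               include.lowest = TRUE)) - 1L
  }
  list(latent = latent, observed = observed, genotypic = g,
       sigma_p = stats::sd(latent), qtl = cbind(qt, marker = idx))
}

#' Two-stage one-tail selection
#'
#' Stage 1 (the ethanol shock, common to both traits) keeps the top
#' `stage1_survival` fraction of the population by the survival phenotype.
#' Stage 2 samples `stage2_sample` survivors uniformly and keeps, separately
#' per trait, the `stage2_top` with the highest phenotype for that trait. The
#' control is the full unselected population, sequenced as independent random
#' subpools.
#'
#' @param pheno_growth,pheno_survival Phenotype lists from
#'   [assign_phenotypes()].
#' @param config A [sim_config()].
#' @return A list with integer index vectors `tail_growth`, `tail_survival`
#'   (length `stage2_top` each), `stage1` (survivor indices) and `stage2`
#'   (the sampled segregants).
#' @export
two_stage_select <- function(pheno_growth, pheno_survival, config) {
  n <- length(pheno_survival$latent)
  n1 <- as.integer(round(config$stage1_survival * n))
  if (config$stage2_sample > n1)
    stop("population too small for the stage-2 sample")
  stage1 <- order(pheno_survival$latent, decreasing = TRUE)[seq_len(n1)]
  stage2 <- sample(stage1, config$stage2_sample)
  top_of <- function(ph) {
    stage2[order(ph$latent[stage2], decreasing = TRUE)[seq_len(config$stage2_top)]]
  }
  list(tail_growth = top_of(pheno_growth),
       tail_survival = top_of(pheno_survival),
       stage1 = stage1, stage2 = stage2)
}

#' Pool individuals and simulate sequencing reads
#'
#' Each subpool's true YE-531 frequency at a marker is the mean allele dosage
#' over its diploid members divided by two. Sequencing depth per marker and
#' subpool is Poisson with the configured mean coverage, YE-531 read counts
#' are binomial at the pool frequency (optionally perturbed by a per-read
#' allele flip probability), and zero-depth cells become missing counts.
#'
#' @param pop Population from [advance_generations()].
#' @param members Named list mapping design cells (e.g. `"growth_1"`) to
#'   integer vectors of member individuals.
#' @param config A [sim_config()].
#' @param design A [pool_design()].
#' @return A list with `markers` (a `marker_table`) and `true_freq`
#'   (markers x cells matrix of the noiseless pool frequencies).
#' @export
pool_and_sequence <- function(pop, members, config, design = pool_design()) {
  M <- nrow(pop$map)
  cells <- design_cells(design)
  stopifnot(setequal(names(members), cells))
  out <- data.frame(chrom = pop$map$chrom, pos = pop$map$pos,
                    allele_s288c = "A", allele_ye531 = "C",
                    stringsAsFactors = FALSE)
  true_freq <- matrix(NA_real_, M, length(cells),
                      dimnames = list(NULL, cells))
  for (cell in cells) {
    idx <- members[[cell]]
    f <- colMeans(pop$h1[idx, , drop = FALSE] + pop$h2[idx, , drop = FALSE]) / 2
    true_freq[, cell] <- f
    f_obs <- f * (1 - config$base_error) + (1 - f) * config$base_error
    depth <- stats::rpois(M, config$coverage)
    ye <- suppressWarnings(stats::rbinom(M, depth, f_obs))
    ot <- depth - ye
    ye[depth == 0L] <- NA_integer_
    ot[depth == 0L] <- NA_integer_
    out[[paste0("cnt_", cell, "_ye531")]] <- as.integer(ye)
    out[[paste0("cnt_", cell, "_other")]] <- as.integer(ot)
  }
  class(out) <- c("marker_table", "data.frame")
  attr(out, "design") <- design
  list(markers = out, true_freq = true_freq)
}

#' Simulate a complete AIL selective-pooling experiment
#'
#' Runs the full forward simulation: founder genomes, `n_generations - 1`
#' rounds of intercrossing with recombination and drift, phenotype assignment
#' for both traits, two-stage one-tail selection, random subdivision of each
#' 90-segregant tail into three subpools of 30, three control replicates from
#' the unselected F-final population (bulk aliquots by default, or random
#' subpools; see `control_mode` in [sim_config()]), and pooled sequencing with
#' Poisson depth and binomial read sampling.
#'
#' @param config A [sim_config()]. `config$seed`, when set, makes the run
#'   reproducible.
#' @return A list of class `ail_sim` with `markers` (pipeline-ready
#'   `marker_table`), `truth` (QTL table with realized tail/control frequency
#'   shifts and realized effects in s.d.u., per-trait `sigma_p`, true pool
#'   frequencies, memberships) and `config`.
#' @export
simulate_ail <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- advance_generations(config)
  ph_g <- assign_phenotypes(pop, config, "growth")
  ph_s <- assign_phenotypes(pop, config, "survival")
  sel <- two_stage_select(ph_g, ph_s, config)

  split_subpools <- function(ids, k, size) {
    ids <- sample(ids, k * size)
    split(ids, rep(seq_len(k), each = size))
  }
  k <- config$subpools; sz <- config$subpool_size
  if (length(sel$tail_growth) < k * sz)
    stop("tail smaller than the pooling layout")
  ctrl_mode <- config$control_mode %||% "aliquot"
  ctrl_members <- if (ctrl_mode == "aliquot") {
    # each control replicate is a bulk aliquot of the whole population:
    # replicates differ by sequencing noise only
    replicate(k, seq_len(nrow(pop$h1)), simplify = FALSE)
  } else {
    split_subpools(seq_len(nrow(pop$h1)), k, sz)
  }
  members <- c(
    stats::setNames(split_subpools(sel$tail_growth, k, sz),
                    paste0("growth_", seq_len(k))),
    stats::setNames(split_subpools(sel$tail_survival, k, sz),
                    paste0("survival_", seq_len(k))),
    stats::setNames(ctrl_members, paste0("control_", seq_len(k))))

  seq_out <- pool_and_sequence(pop, members, config)

  pop_freq <- colMeans(pop$h1 + pop$h2) / 2
  truth_qtl <- NULL
  for (tr in c("growth", "survival")) {
    ph <- if (tr == "growth") ph_g else ph_s
    if (nrow(ph$qtl) == 0L) next
    tail_ids <- sel[[paste0("tail_", tr)]]
    tail_freq <- colMeans(pop$h1[tail_ids, ph$qtl$marker, drop = FALSE] +
                          pop$h2[tail_ids, ph$qtl$marker, drop = FALSE]) / 2
    q <- ph$qtl
    q$map_trait <- tr
    q$pop_freq <- pop_freq[q$marker]
    q$tail_freq <- tail_freq
    q$realized_shift <- tail_freq - pop_freq[q$marker]
    q$sigma_p <- ph$sigma_p
    q$delta_sdu_realized <- q$delta / ph$sigma_p
    truth_qtl <- rbind(truth_qtl, q)
  }

  structure(list(
    markers = seq_out$markers,
    truth = list(qtl = truth_qtl,
                 sigma_p = c(growth = ph_g$sigma_p, survival = ph_s$sigma_p),
                 sd_observed = c(growth = stats::sd(ph_g$observed),
                                 survival = stats::sd(ph_s$observed)),
                 true_pool_freq = seq_out$true_freq,
                 pop_freq = pop_freq,
                 members = members,
                 tail_growth = sel$tail_growth,
                 tail_survival = sel$tail_survival),
    config = config), class = "ail_sim")
}

#' Write a simulated experiment to disk
#'
#' Emits the pipeline-ready tabular marker file, a `truth.json` with the QTL
#' ground truth, realized shifts and memberships, and a snapshot of the
#' configuration.
#'
#' @param sim An `ail_sim` from [simulate_ail()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(markers = file.path(dir, "markers.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.json"))
  write_marker_table(sim$markers, paths[["markers"]])
  truth <- sim$truth
  truth$true_pool_freq <- round(truth$true_pool_freq, 6)
  # census control memberships compress to "all"
  truth$members <- lapply(truth$members, function(ids)
    if (length(ids) == sim$config$pop_size &&
        identical(ids, seq_along(ids))) "all" else ids)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = FALSE, dataframe = "columns")
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Allele-frequency drift under pure binomial resampling
#'
#' Simulates neutral Wright-Fisher style drift of a biallelic marker: in each
#' generation the allele frequency is resampled binomially with `ne` draws
#' (per-generation frequency SD `sqrt(p q / ne)`). Used to quantify how much
#' frequency dispersion cumulative sampling alone can generate across an
#' intercross.
#'
#' @param p0 Starting allele frequency; default 0.5.
#' @param ne Effective number of sampled genomes per generation; default 1000.
#' @param n_generations Number of resampling rounds; default 6.
#' @param n_reps Number of independent replicate lineages; default 10,000.
#' @return Numeric vector of final allele frequencies (length `n_reps`).
#' @examples
#' sd(simulate_drift(n_reps = 1000)) # about 0.038
#' @export
simulate_drift <- function(p0 = 0.5, ne = 1000, n_generations = 6,
                           n_reps = 10000) {
  p <- rep(p0, n_reps)
  for (g in seq_len(n_generations))
    p <- stats::rbinom(n_reps, ne, p) / ne
  p
}
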