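#' Run the full mapping pipeline
#'
#' Orchestrates the whole inference chain for each requested trait: marker
#' quality control, LOESS smoothing of allele frequencies by position,
#' association testing (D, empirical SE, Z, comparison-wise P), multiplicity
#' report with true-null estimation and FDR thresholding, 1-log-drop QTL
#' calling, and allele-effect estimation. All result tables are written under
#' `out_dir` together with the effective configuration and seed.
#'
#' @param config A nested list. Recognised entries (all numeric values have
#'   the package defaults):
#'   \describe{
#'     \item{`input`}{either `list(path = "markers.tsv")` or
#'       `list(simulate = sim_config(...))`.}
#'     \item{`traits`}{character vector of trait categories; required.}
#'     \item{`qc`}{arguments passed to [filter_markers()].}
#'     \item{`loess`}{`position_span_points` (80), `sd_span_fraction` (0.10),
#'       `degree` (2).}
#'     \item{`fdr`}{`alpha` (0.2), `levels`, `adaptive` (FALSE),
#'       `bin_width` (0.1).}
#'     \item{`qtl`}{`log_drop` (1.0).}
#'     \item{`effects`}{`scheme` (a [selection_scheme()]), per-trait `sigma_p`
#'       and `trait_mean`; for simulated input `sigma_p` defaults to the
#'       simulation truth.}
#'     \item{`out_dir`}{output directory; default a temporary directory.}
#'     \item{`seed`}{random seed recorded in the run report.}
#'   }
#' @return A list of class `ailmap_run` with per-trait elements
#'   (`association`, `multiplicity`, `critical_p`, `qtls`, `effects`), the QC
#'   report, the cross-trait `overlaps` table when two or more traits are
#'   mapped, and `paths` of all written files.
#' @export
run_pipeline <- function(config) {
  traits <- config$traits
  if (is.null(traits) || length(traits) == 0L)
    stop("configuration error: no traits to map")
  if (!is.null(config$seed)) set.seed(config$seed)
  out_dir <- config$out_dir %||% tempfile("ailmap_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- input -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input$simulate)) {
    simcfg <- config$input$simulate
    simcfg$seed <- simcfg$seed %||% config$seed
    sim <- simulate_ail(simcfg)
    markers <- sim$markers
    truth <- sim$truth
  } else if (!is.null(config$input$path)) {
    design <- config$input$design %||% pool_design()
    markers <- read_marker_table(config$input$path, design)
  } else stop("configuration error: no input (path or simulate)")

  # --- qc --------------------------------------------------------------
  qc_args <- config$qc %||% list()
  qc <- do.call(filter_markers, c(list(markers = markers), qc_args))

  # --- smoothing -------------------------------------------------------
  lo <- config$loess %||% list()
  span_pts <- lo$position_span_points %||% 80
  sd_span <- lo$sd_span_fraction %||% 0.10
  degree <- lo$degree %||% 2
  freqs <- pool_frequencies(qc$markers)
  freqs_sm <- smooth_frequency_by_position(freqs, span_points = span_pts,
                                           degree = degree)

  fdr_cfg <- config$fdr %||% list()
  alpha <- fdr_cfg$alpha %||% 0.2
  levels <- fdr_cfg$levels %||% c(0.001, 0.01, 0.05, 0.1, 0.2)
  drop <- (config$qtl %||% list())$log_drop %||% 1.0
  scheme <- (config$effects %||% list())$scheme %||% selection_scheme()

  paths <- character(0)
  per_trait <- list()
  for (tr in traits) {
    assoc <- associate_trait(freqs_sm, tr, sd_span_fraction = sd_span,
                             degree = degree)
    report <- build_report(assoc$P, fdr_levels = sort(unique(c(levels, alpha))),
                           bin_width = fdr_cfg$bin_width %||% 0.10,
                           adaptive = isTRUE(fdr_cfg$adaptive))
    crit <- report$rows$critical_p[report$rows$fdr_level == alpha][1L]
    qtls <- call_qtls_all(assoc, crit, drop = drop)

    sigma_p <- config$effects$sigma_p[[tr]] %||%
      (if (!is.null(truth)) unname(truth$sigma_p[[tr]]) else 1)
    effects <- estimate_qtl_effects(qtls, assoc, scheme, sigma_p)

    p_assoc <- file.path(out_dir, paste0("association_", tr, ".tsv"))
    utils::write.table(
      assoc[c("chrom", "pos", "freq_ctrl", "freq_tail", "D", "SE", "Z", "P")],
      p_assoc, sep = "\t", quote = FALSE, row.names = FALSE)
    p_rep <- file.path(out_dir, paste0("multiplicity_report_", tr, ".tsv"))
    write_multiplicity_report(report, p_rep)
    p_bed <- file.path(out_dir, paste0("qtls_", tr, ".bed"))
    write_qtl_bed(qtls, p_bed)
    p_qtl <- file.path(out_dir, paste0("qtls_", tr, ".tsv"))
    utils::write.table(
      qtls[c("chrom", "start", "end", "peak_pos", "peak_score",
             "n_markers", "length_bp")],
      p_qtl, sep = "\t", quote = FALSE, row.names = FALSE)
    p_eff <- file.path(out_dir, paste0("effects_", tr, ".tsv"))
    utils::write.table(effects, p_eff, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p_assoc, p_rep, p_bed, p_qtl, p_eff)

    per_trait[[tr]] <- list(association = assoc, multiplicity = report,
                            critical_p = crit, qtls = qtls, effects = effects)
  }

  overlaps <- NULL
  if (length(traits) >= 2L) {
    overlaps <- overlap_qtls(per_trait[[traits[1L]]]$qtls,
                             per_trait[[traits[2L]]]$qtls)
    p_ovl <- file.path(out_dir, "qtl_overlaps.tsv")
    utils::write.table(overlaps, p_ovl, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p_ovl)
  }

  eff_config <- list(traits = traits, seed = config$seed,
                     qc = qc_args,
                     loess = list(position_span_points = span_pts,
                                  sd_span_fraction = sd_span, degree = degree),
                     fdr = list(alpha = alpha, levels = levels,
                                adaptive = isTRUE(fdr_cfg$adaptive)),
                     qtl = list(log_drop = drop),
                     selection = unclass(scheme))
  p_cfg <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(eff_config, p_cfg, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, p_cfg)

  structure(list(traits = per_trait, qc_report = qc$report,
                 overlaps = overlaps, truth = truth,
                 out_dir = out_dir, paths = paths, config = eff_config),
            class = "ailmap_run")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a declarative configuration file. The `input$simulate` section, when
#' present, is passed to [sim_config()]; everything else is handed to
#' [run_pipeline()] as-is.
#'
#' @param path Path to a YAML file.
#' @return A configuration list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$input$simulate)) {
    sc <- cfg$input$simulate
    if (!is.null(sc$qtl_truth)) sc$qtl_truth <- as.data.frame(sc$qtl_truth)
    if (!is.null(sc$chrom_lengths)) sc$chrom_lengths <- unlist(sc$chrom_lengths)
    if (!is.null(sc$h2)) sc$h2 <- unlist(sc$h2)
    cfg$input$simulate <- do.call(sim_config, sc)
  }
  if (!is.null(cfg$effects$scheme))
    cfg$effects$scheme <- do.call(selection_scheme, cfg$effects$scheme)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
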