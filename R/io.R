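#' Read a marker-by-subpool allele count table
#'
#' Reads the tab-separated marker format used throughout the package: a header
#' line naming `chrom`, `pos`, `allele_s288c`, `allele_ye531` followed by one
#' pair of count columns `cnt_<category>_<j>_ye531` / `cnt_<category>_<j>_other`
#' per (category, subpool) cell of the design. Parsing is header-driven, so
#' column order is irrelevant. Missing counts are encoded as `"."`.
#'
#' @param path Path to the tab-separated file.
#' @param design A [pool_design()].
#' @return A `marker_table`: a data frame with marker annotation columns and
#'   one integer count column per design cell, sorted by `(chrom, pos)`.
#' @seealso [write_marker_table()], [pool_frequencies()]
#' @export
read_marker_table <- function(path, design = pool_design()) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = ".", comment.char = "")
  required <- c("chrom", "pos", "allele_s288c", "allele_ye531",
                design_count_columns(design))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop("marker table is missing required column(s): ",
         paste(missing, collapse = ", "))

  x <- raw[required]
  x$pos <- suppressWarnings(as.integer(x$pos))
  cnt_cols <- design_count_columns(design)
  for (cc in cnt_cols) x[[cc]] <- suppressWarnings(as.integer(raw[[cc]]))

  # data rows start at file line 2 (after the header)
  line_no <- seq_len(nrow(x)) + 1L

  bad_pos <- is.na(x$pos) | x$pos < 1L
  if (any(bad_pos))
    stop("invalid position at file line(s): ",
         paste(line_no[bad_pos], collapse = ", "))
  neg <- rowSums(as.matrix(x[cnt_cols]) < 0L, na.rm = TRUE) > 0L
  if (any(neg))
    stop("negative allele count at file line(s): ",
         paste(line_no[neg], collapse = ", "))
  key <- paste(x$chrom, x$pos)
  if (anyDuplicated(key))
    stop("duplicate marker (chrom, pos) at file line(s): ",
         paste(line_no[duplicated(key)], collapse = ", "))

  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("marker_table", "data.frame")
  attr(x, "design") <- design
  x
}

#' Write a marker table
#'
#' Writes the tab-separated marker format read by [read_marker_table()].
#' Missing counts are written as `"."`. The round trip preserves positions and
#' counts exactly.
#'
#' @param x A `marker_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(x, path) {
  out <- as.data.frame(x)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' YE-531 allele frequencies per marker and subpool
#'
#' Converts marker allele counts to frequencies of the YE-531 allele, the
#' arbitrary reference allele on which all downstream statistics are based
#' (the S288c frequency is its complement). Frequencies are undefined (`NA`)
#' where a cell has zero total reads.
#'
#' @param markers A `marker_table`.
#' @return A `freq_matrix`: a list with `markers` (chrom/pos data frame),
#'   `values` (markers x design-cells matrix of frequencies in `[0, 1]`,
#'   columns named `<category>_<j>`), `design` and `stage` (`"raw"`).
#' @export
pool_frequencies <- function(markers) {
  design <- attr(markers, "design")
  if (is.null(design)) design <- pool_design()
  cells <- design_cells(design)
  vals <- matrix(NA_real_, nrow(markers), length(cells),
                 dimnames = list(NULL, cells))
  for (cell in cells) {
    ye <- markers[[paste0("cnt_", cell, "_ye531")]]
    ot <- markers[[paste0("cnt_", cell, "_other")]]
    tot <- ye + ot
    vals[, cell] <- ifelse(!is.na(tot) & tot > 0L, ye / tot, NA_real_)
  }
  freq_matrix(markers[c("chrom", "pos")], vals, design, stage = "raw")
}

freq_matrix <- function(markers, values, design, stage = "raw") {
  stopifnot(nrow(markers) == nrow(values))
  ok <- is.na(values) | (values >= 0 & values <= 1)
  if (!all(ok)) stop("frequencies must lie in [0, 1]")
  structure(list(markers = as.data.frame(markers)[c("chrom", "pos")],
                 values = values, design = design, stage = stage),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("freq_matrix: %d markers x %d subpool cells (stage: %s)\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Read pooled allele depths from a VCF file
#'
#' Builds a `marker_table` from a VCF 4.x file with per-sample allele depths
#' (`AD` in FORMAT), mapping sequenced pool samples to (category, subpool)
#' cells. Only biallelic SNP records are used; multi-allelic records are
#' skipped and counted. The parental origin of each alternative allele must be
#' supplied so that counts can be oriented to the YE-531 allele.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_map Named character vector mapping VCF sample names to design
#'   cells, e.g. `c(pool_g1 = "growth_1", ...)`. Every design cell must be
#'   covered exactly once.
#' @param ye531_alleles Data frame with columns `chrom`, `pos`, `allele` giving
#'   the YE-531 (non-S288c-reference) nucleotide at each marker. Records absent
#'   from this table are dropped.
#' @param design A [pool_design()].
#' @return A `marker_table` with attribute `n_skipped_multiallelic`.
#' @export
read_vcf_pools <- function(path, sample_map, ye531_alleles,
                           design = pool_design()) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_pools() requires the 'vcfR' package")
  cells <- design_cells(design)
  if (!setequal(unname(sample_map), cells))
    stop("sample_map must cover every design cell exactly once")

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  absent <- setdiff(names(sample_map), samples)
  if (length(absent) > 0L)
    stop("sample(s) in sample_map absent from VCF: ",
         paste(absent, collapse = ", "))

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0L)
    message(n_multi, " multi-allelic record(s) skipped")
  snp <- !multi & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L

  ad <- vcfR::extract.gt(vcf, element = "AD")
  ref_ad <- vcfR::masplit(ad, record = 1L, sort = 0L, decreasing = 0L)
  alt_ad <- vcfR::masplit(ad, record = 2L, sort = 0L, decreasing = 0L)

  keep <- which(snp)
  key <- paste(fix$CHROM[keep], fix$POS[keep])
  orient <- ye531_alleles$allele[match(key, paste(ye531_alleles$chrom,
                                                  ye531_alleles$pos))]
  known <- !is.na(orient)
  keep <- keep[known]
  orient <- orient[known]

  out <- data.frame(chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    allele_s288c = NA_character_,
                    allele_ye531 = orient,
                    stringsAsFactors = FALSE)
  ye_is_alt <- orient == fix$ALT[keep]
  ye_is_ref <- orient == fix$REF[keep]
  if (any(!ye_is_alt & !ye_is_ref))
    stop("ye531_alleles allele matches neither REF nor ALT at some records")
  out$allele_s288c <- ifelse(ye_is_alt, fix$REF[keep], fix$ALT[keep])

  for (s in names(sample_map)) {
    cell <- sample_map[[s]]
    ye <- ifelse(ye_is_alt, alt_ad[keep, s], ref_ad[keep, s])
    ot <- ifelse(ye_is_alt, ref_ad[keep, s], alt_ad[keep, s])
    out[[paste0("cnt_", cell, "_ye531")]] <- as.integer(ye)
    out[[paste0("cnt_", cell, "_other")]] <- as.integer(ot)
  }
  out <- out[c("chrom", "pos", "allele_s288c", "allele_ye531",
               design_count_columns(design))]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  attr(out, "design") <- design
  attr(out, "n_skipped_multiallelic") <- n_multi
  out
}
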