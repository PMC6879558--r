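test_that("call_qtls seeds at significant local maxima and extends by 1 log", {
  pos <- seq(100L, by = 100L, length.out = 11L)
  #        1  2  3    4    5    6    7    8  9  10 11
  score <- c(1, 2, 3, 4.5, 6.0, 4.5, 3.0, 2, 1, 1, 1)
  crit <- 10^-4  # threshold 4: only the peak (6.0) and its shoulders qualify
  q <- call_qtls(pos, score, crit)
  expect_s3_class(q, "qtl_intervals")
  expect_equal(nrow(q), 1L)
  expect_equal(q$peak_pos, 500L)
  expect_equal(q$peak_score, 6.0)
  # extension: markers strictly above 6 - 1 = 5 stay; 4.5 (<= 5) is excluded
  expect_equal(q$start, 500L)
  expect_equal(q$end, 500L)
  # a gentler drop keeps the shoulders
  q2 <- call_qtls(pos, score, crit, drop = 2)
  expect_equal(c(q2$start, q2$end), c(400L, 600L))
  expect_equal(q2$n_markers, 3L)
  expect_equal(q2$length_bp, 201L)
  expect_equal(q2$members[[1L]], 4:6)
})

test_that("adjacent peaks split only when the valley drops below peak - 1", {
  pos <- seq(100L, by = 100L, length.out = 9L)
  crit <- 10^-4
  # deep valley (5, 3.5, 6): valley is 1.5 below the lower peak -> two QTLs
  deep <- c(1, 2, 5, 3.5, 2.0, 3.5, 6, 2, 1)
  q <- call_qtls(pos, deep, crit)
  expect_equal(nrow(q), 2L)
  expect_equal(q$peak_pos, c(300L, 700L))
  # shallow valley (5, 4.5, 6): only 0.5 below the lower peak -> one QTL,
  # named by the higher peak
  shallow <- c(1, 2, 5, 4.8, 4.5, 4.8, 6, 2, 1)
  q2 <- call_qtls(pos, shallow, crit)
  expect_equal(nrow(q2), 1L)
  expect_equal(q2$peak_pos, 700L)
  expect_equal(q2$peak_score, 6)
  # split_adjacent_peaks is the same rule
  expect_equal(split_adjacent_peaks(pos, shallow, crit), q2)
})

test_that("plateaus seed at the central marker, ties broken left", {
  pos <- seq(100L, by = 100L, length.out = 8L)
  score <- c(1, 5, 5, 5, 5, 1, 1, 1)   # run of 4 -> centre is the 2nd (left)
  q <- call_qtls(pos, score, 10^-4)
  expect_equal(nrow(q), 1L)
  expect_equal(q$peak_pos, 300L)
  score3 <- c(1, 5, 5, 5, 1, 1, 1, 1)  # run of 3 -> exact centre
  expect_equal(call_qtls(pos, score3, 10^-4)$peak_pos, 300L)
})

test_that("no significant marker means no QTLs; inputs validated", {
  pos <- c(100L, 200L, 300L)
  q <- call_qtls(pos, c(1, 2, 1), 10^-4)
  expect_equal(nrow(q), 0L)
  expect_equal(nrow(call_qtls(pos, c(1, 5, 1), 0)), 0L)
  expect_error(call_qtls(pos, c(1, 2), 0.05), "aligned")
  expect_error(call_qtls(c(100L, 100L, 300L), c(1, 2, 1), 0.05),
               "strictly increasing")
  # boundary: a peak exactly at the threshold is significant
  expect_equal(nrow(call_qtls(pos, c(1, -log10(0.05), 1), 0.05)), 1L)
})

test_that("call_qtls_all maps members into association rows per chromosome", {
  n <- 40L
  assoc <- data.frame(
    chrom = rep(c("chr01", "chr02"), each = n / 2),
    pos = rep(seq(100L, by = 100L, length.out = n / 2), 2),
    P = rep(0.5, n), masked = FALSE)
  assoc$P[8:12] <- c(1e-3, 1e-5, 1e-6, 1e-5, 1e-3)    # QTL on chr01
  assoc$P[28:30] <- c(1e-3, 1e-4, 1e-3)               # QTL on chr02
  assoc$P[15] <- 1e-8; assoc$masked[15] <- TRUE       # masked: ignored
  class(assoc) <- c("association_result", "data.frame")
  q <- call_qtls_all(assoc, critical_p = 1e-3)
  expect_equal(q$chrom, c("chr01", "chr02"))
  expect_equal(q$peak_pos, c(1000L, 900L))
  expect_true(all(q$members[[1L]] %in% 1:20))
  expect_equal(assoc$pos[q$members[[2L]]],
               seq(q$start[2L], q$end[2L], by = 100L))
  # masked marker did not seed a QTL
  expect_false(any(vapply(q$members, function(m) 15L %in% m, logical(1))))
})

test_that("overlap_qtls finds same-chromosome 1bp-inclusive overlaps", {
  a <- data.frame(chrom = c("chr01", "chr01", "chr02"),
                  start = c(100L, 500L, 100L), end = c(200L, 600L, 200L))
  b <- data.frame(chrom = c("chr01", "chr02"),
                  start = c(200L, 300L), end = c(300L, 400L))
  ov <- overlap_qtls(a, b)
  expect_equal(nrow(ov), 1L)  # touching at a single bp counts; chr02 disjoint
  expect_equal(ov$idx_a, 1L)
  expect_equal(ov$overlap_start, 200L)
  expect_equal(ov$overlap_end, 200L)
  expect_equal(nrow(overlap_qtls(a[0, ], b)), 0L)
})

test_that("summarize_qtls reports sizes, gaps and gene content", {
  q <- data.frame(chrom = c("chr01", "chr01", "chr02"),
                  start = c(100L, 1000L, 50L), end = c(300L, 1200L, 60L),
                  length_bp = c(201L, 201L, 11L))
  genes <- data.frame(chrom = c("chr01", "chr01", "chr02"),
                      start = c(150L, 250L, 500L), end = c(220L, 1100L, 600L),
                      gene = c("G1", "G2", "G3"))
  s <- summarize_qtls(q, genes)
  expect_equal(s$n, 3L)
  expect_equal(s$length_mean, mean(c(201, 201, 11)))
  expect_equal(s$inter_qtl_distances, 700L)  # 1000 - 300
  expect_equal(s$genes_per_qtl, c(2, 1, 0))
  expect_equal(s$n_single_gene, 1L)
  expect_equal(s$n_no_orf, 1L)
})

test_that("BED output is 0-based half-open", {
  q <- data.frame(chrom = "chr01", start = 101L, end = 200L,
                  peak_pos = 150L, peak_score = 5.2, n_markers = 3L,
                  length_bp = 100L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_qtl_bed(q, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, 100L)
  expect_equal(bed$V3, 200L)
})
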