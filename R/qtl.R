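#' Call QTL intervals on one chromosome by the 1-log-drop rule
#'
#' Seeds are local maxima of the -log10(P) track whose P-value meets the FDR
#' critical threshold. From each seed the interval is extended outward in both
#' directions, including consecutive markers while their score stays strictly
#' above `peak - drop` (the first marker at or below the drop line is
#' excluded). Overlapping extensions from distinct seeds are resolved by
#' [split_adjacent_peaks()]: two adjacent significant peaks are reported as
#' separate QTLs only when the valley between them falls at least `drop` below
#' the lower peak; otherwise they merge into one interval whose peak is the
#' higher maximum.
#'
#' Plateaus (maximal runs of tied scores flanked by lower values) count as a
#' single local maximum, seeded at the central marker of the run (ties broken
#' towards the left).
#'
#' @param pos Marker base-pair positions, sorted increasingly.
#' @param score Per-marker `-log10(P)` track (from smoothed frequencies).
#' @param critical_p FDR critical comparison-wise P-value; markers with
#'   `P <= critical_p` are significant.
#' @param drop Support-interval log drop; default 1.0.
#' @return A data frame of class `qtl_intervals` with columns `chrom` (`NA`
#'   here; filled by [call_qtls_all()]), `start`, `end`, `peak_pos`,
#'   `peak_score`, `n_markers`, `length_bp`, and a list column `members` of
#'   marker indices.
#' @export
call_qtls <- function(pos, score, critical_p, drop = 1.0) {
  n <- length(pos)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_pos = integer(0),
                      peak_score = numeric(0), n_markers = integer(0),
                      length_bp = integer(0))
  empty$members <- list()
  class(empty) <- c("qtl_intervals", "data.frame")
  if (n == 0L || critical_p <= 0) return(empty)
  if (length(score) != n) stop("pos and score must be aligned")
  if (is.unsorted(pos, strictly = TRUE)) stop("pos must be strictly increasing")

  threshold <- -log10(critical_p)
  significant <- score >= threshold - 1e-12
  seeds <- local_maxima(score)
  seeds <- seeds[significant[seeds]]
  if (length(seeds) == 0L) return(empty)

  iv <- lapply(seeds, function(s) {
    lo <- s
    while (lo > 1L && score[lo - 1L] > score[s] - drop) lo <- lo - 1L
    hi <- s
    while (hi < n && score[hi + 1L] > score[s] - drop) hi <- hi + 1L
    c(lo, hi, s)
  })
  iv <- do.call(rbind, iv)

  # merge overlapping extensions; the higher peak names the merged interval
  ord <- order(iv[, 1L], iv[, 2L])
  iv <- iv[ord, , drop = FALSE]
  merged <- list()
  cur <- iv[1L, ]
  for (r in seq_len(nrow(iv))[-1L]) {
    if (iv[r, 1L] <= cur[2L]) {
      cur[2L] <- max(cur[2L], iv[r, 2L])
      cur[1L] <- min(cur[1L], iv[r, 1L])
      if (score[iv[r, 3L]] > score[cur[3L]]) cur[3L] <- iv[r, 3L]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- iv[r, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur

  out <- do.call(rbind, lapply(merged, function(m) {
    data.frame(chrom = NA_character_, start = pos[m[1L]], end = pos[m[2L]],
               peak_pos = pos[m[3L]], peak_score = score[m[3L]],
               n_markers = m[2L] - m[1L] + 1L,
               length_bp = pos[m[2L]] - pos[m[1L]] + 1L)
  }))
  out$members <- lapply(merged, function(m) seq.int(m[1L], m[2L]))
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

# Indices of local maxima with plateau handling: a maximal run of equal
# values flanked by strictly lower values (or the chromosome end) is one
# peak at the run's central marker, ties broken left.
local_maxima <- function(score) {
  n <- length(score)
  if (n == 0L) return(integer(0))
  r <- rle(score)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    left_ok && right_ok
  }, logical(1))
  centre <- starts + (r$lengths - 1L) %/% 2L
  centre[is_max]
}

#' Split a candidate region at valleys between adjacent significant peaks
#'
#' Applies the adjacent-peak rule to a single candidate region: the region is
#' split at the minimum between two significant local maxima if and only if
#' that valley score is at least `drop` below the lower of the two peaks;
#' otherwise the two peaks form one interval whose peak is the higher maximum.
#' With one (or no) significant maximum the region is returned unchanged as a
#' single interval.
#'
#' @inheritParams call_qtls
#' @return A `qtl_intervals` data frame with one row per resulting QTL.
#' @export
split_adjacent_peaks <- function(pos, score, critical_p, drop = 1.0) {
  call_qtls(pos, score, critical_p, drop = drop)
}

#' Call QTLs for every chromosome of an association scan
#'
#' @param assoc An `association_result` data frame (from [associate_trait()]).
#' @param critical_p FDR critical P-value (e.g. from [build_report()] at
#'   `alpha = 0.2`).
#' @param drop Support-interval log drop; default 1.0.
#' @return A `qtl_intervals` data frame over all chromosomes, with `members`
#'   holding row indices into `assoc`.
#' @export
call_qtls_all <- function(assoc, critical_p, drop = 1.0) {
  pieces <- lapply(unique(assoc$chrom), function(ch) {
    rows <- which(assoc$chrom == ch & !assoc$masked)
    if (length(rows) == 0L) return(NULL)
    q <- call_qtls(assoc$pos[rows], -log10(assoc$P[rows]), critical_p, drop)
    if (nrow(q) == 0L) return(NULL)
    q$chrom <- ch
    q$members <- lapply(q$members, function(m) rows[m])
    q
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    out <- call_qtls(numeric(0), numeric(0), critical_p)
    return(out)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

#' Overlapping QTL pairs between two traits
#'
#' Two intervals overlap when they are on the same chromosome and share at
#' least one base pair (bounds inclusive).
#'
#' @param qtls_a,qtls_b `qtl_intervals` data frames.
#' @return Data frame with columns `idx_a`, `idx_b`, `chrom`,
#'   `overlap_start`, `overlap_end`.
#' @export
overlap_qtls <- function(qtls_a, qtls_b) {
  out <- data.frame(idx_a = integer(0), idx_b = integer(0),
                    chrom = character(0), overlap_start = integer(0),
                    overlap_end = integer(0))
  if (nrow(qtls_a) == 0L || nrow(qtls_b) == 0L) return(out)
  for (i in seq_len(nrow(qtls_a))) {
    same <- which(qtls_b$chrom == qtls_a$chrom[i] &
                    qtls_b$start <= qtls_a$end[i] &
                    qtls_b$end >= qtls_a$start[i])
    for (j in same) {
      out <- rbind(out, data.frame(
        idx_a = i, idx_b = j, chrom = qtls_a$chrom[i],
        overlap_start = max(qtls_a$start[i], qtls_b$start[j]),
        overlap_end = min(qtls_a$end[i], qtls_b$end[j])))
    }
  }
  out
}

#' Summary statistics of a set of QTL intervals
#'
#' Computes interval-size statistics, inter-QTL distances per chromosome
#' (gap between the end of one interval and the start of the next, exclusive
#' of both), and, when a gene annotation is supplied, the number of genes
#' overlapping each QTL by at least 1 bp, the count of single-gene QTLs and
#' the count of QTLs containing no gene.
#'
#' @param qtls A `qtl_intervals` data frame.
#' @param genes Optional annotation data frame with columns `chrom`, `start`,
#'   `end` and `gene` (1-based inclusive bounds).
#' @return A list with `n`, `length_mean`, `length_min`, `length_max`,
#'   `inter_qtl_distances`, `distance_mean`, and (with annotation)
#'   `genes_per_qtl`, `n_single_gene`, `n_no_orf`.
#' @export
summarize_qtls <- function(qtls, genes = NULL) {
  out <- list(n = nrow(qtls))
  if (nrow(qtls) == 0L) return(out)
  out$length_mean <- mean(qtls$length_bp)
  out$length_min <- min(qtls$length_bp)
  out$length_max <- max(qtls$length_bp)

  gaps <- unlist(lapply(split(qtls, qtls$chrom), function(q) {
    if (nrow(q) < 2L) return(numeric(0))
    q <- q[order(q$start), ]
    q$start[-1L] - q$end[-nrow(q)]
  }), use.names = FALSE)
  out$inter_qtl_distances <- gaps
  out$distance_mean <- if (length(gaps) > 0L) mean(gaps) else NA_real_

  if (!is.null(genes)) {
    counts <- vapply(seq_len(nrow(qtls)), function(i) {
      sum(genes$chrom == qtls$chrom[i] &
            genes$start <= qtls$end[i] &
            genes$end >= qtls$start[i])
    }, numeric(1))
    out$genes_per_qtl <- counts
    out$n_single_gene <- sum(counts == 1L)
    out$n_no_orf <- sum(counts == 0L)
  }
  out
}

#' Write QTL intervals as BED
#'
#' Internally coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so `start - 1` and `end` are written.
#'
#' @param qtls A `qtl_intervals` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qtl_bed <- function(qtls, path) {
  bed <- data.frame(chrom = qtls$chrom, start = qtls$start - 1L,
                    end = qtls$end,
                    name = sprintf("qtl_%03d", seq_len(max(nrow(qtls), 0L))),
                    score = round(qtls$peak_score, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
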