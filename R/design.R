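#' Pooling design of a selective DNA pooling experiment
#'
#' Describes how selected and control individuals are partitioned into
#' replicate subpools for sequencing. The default mirrors the standard
#' two-trait design: three categories (growth-selected, survival-selected,
#' unselected control), each sequenced as three independent subpools of 30
#' diploid segregants (60 chromosomes).
#'
#' @param categories Named integer vector mapping category labels to their
#'   numeric codes. The control category must be named `"control"`.
#' @param subpools_per_category Number of replicate subpools per category.
#' @param individuals_per_subpool Number of diploid individuals per subpool.
#'
#' @return An object of class `"pool_design"`: a list with elements
#'   `categories`, `subpools_per_category`, `individuals_per_subpool` and
#'   `chromosomes_per_subpool` (twice the individual count, diploids).
#' @examples
#' pool_design()
#' @export
pool_design <- function(categories = c(growth = 1L, survival = 2L, control = 3L),
                        subpools_per_category = 3L,
                        individuals_per_subpool = 30L) {
  if (is.null(names(categories)) || any(names(categories) == ""))
    stop("'categories' must be a named vector")
  if (!"control" %in% names(categories))
    stop("the design must include a 'control' category")
  if (subpools_per_category < 2L)
    stop("at least two replicate subpools per category are required")
  structure(
    list(categories = categories,
         subpools_per_category = as.integer(subpools_per_category),
         individuals_per_subpool = as.integer(individuals_per_subpool),
         chromosomes_per_subpool = 2L * as.integer(individuals_per_subpool)),
    class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat("Selective DNA pooling design\n")
  cat("  categories:", paste(sprintf("%s(k=%d)", names(x$categories), x$categories),
                             collapse = ", "), "\n")
  cat("  subpools per category:", x$subpools_per_category, "\n")
  cat("  individuals per subpool:", x$individuals_per_subpool,
      sprintf("(%d chromosomes)\n", x$chromosomes_per_subpool))
  invisible(x)
}

# Column labels of the (category, subpool) cells of a design, in fixed order:
# all subpools of category 1, then category 2, ...
design_cells <- function(design) {
  cats <- names(design$categories)[order(design$categories)]
  as.vector(t(outer(cats, seq_len(design$subpools_per_category), paste, sep = "_")))
}

# Count-column names of the tabular marker format for a design.
design_count_columns <- function(design) {
  cells <- design_cells(design)
  as.vector(rbind(paste0("cnt_", cells, "_ye531"),
                  paste0("cnt_", cells, "_other")))
}
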