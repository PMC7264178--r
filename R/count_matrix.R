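#' Feature-by-sample count matrix with genotype design
#'
#' The shared container for RNA gene counts and ChIP region counts: a
#' non-negative integer matrix (features in rows, samples in columns) plus a
#' design table mapping each sample to a genotype, assay, and role.
#'
#' @param counts Numeric matrix of non-negative integers with feature row
#'   names and sample column names.
#' @param design Data frame with columns `sample`, `genotype`, and optionally
#'   `assay` (`"rna"` or `"chip"`) and `role` (`"IP"`, `"input"`, or
#'   `"none"`). `design$sample` must match `colnames(counts)`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `design`.
#' @examples
#' m <- matrix(rpois(40, 20), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' d <- data.frame(sample = paste0("s", 1:4),
#'                 genotype = c("WT", "WT", "B_KO", "B_KO"))
#' cm <- count_matrix(m, d)
#' @export
count_matrix <- function(counts, design) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("`counts` must be a numeric matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    abort("`counts` must contain non-negative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have feature row names and sample column names")
  if (!is.data.frame(design) || !all(c("sample", "genotype") %in% names(design)))
    abort("`design` must be a data frame with columns `sample` and `genotype`")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!"assay" %in% names(design)) design$assay <- "rna"
  if (!"role" %in% names(design)) design$role <- "none"
  if (!identical(colnames(counts), as.character(design$sample)))
    abort("`design$sample` must match `colnames(counts)` in order")
  if (anyNA(design$genotype))
    abort("every sample needs a genotype")
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$design$genotype, x$design$role))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# samples of a given role (default: the testable, non-input samples)
ip_samples <- function(x) {
  x$design$sample[x$design$role != "input"]
}

subset_samples <- function(x, samples) {
  keep <- match(samples, x$design$sample)
  if (anyNA(keep)) abort("unknown sample(s): ",
                         paste(samples[is.na(keep)], collapse = ", "))
  count_matrix(x$counts[, keep, drop = FALSE], x$design[keep, , drop = FALSE])
}
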