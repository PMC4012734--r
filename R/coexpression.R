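## Coexpression of two genes: the Pearson product-moment correlation of
## their per-sample rank profiles, the quantity the greedy split maximises.

#' Extract one gene's profile from a (rank) matrix
#'
#' @param x numeric matrix with gene symbols (after probe collapsing) or
#'   probe ids as rownames, or a SummarizedExperiment whose `"ranks"` (or
#'   `"exprs"`) assay carries one.
#' @param gene the row to extract.
#' @return a named numeric vector, one value per sample, in matrix column
#'   order. If `gene` is absent the error message lists near-matches.
#' @export
extractProfile <- function(x, gene) {
  if (methods::is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    x <- SummarizedExperiment::assay(x, if ("ranks" %in% nm) "ranks" else "exprs")
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (!gene %in% rownames(x)) {
    near <- agrep(gene, rownames(x), max.distance = 0.3,
                  ignore.case = TRUE, value = TRUE)
    stop("gene '", gene, "' not found",
         if (length(near)) paste0("; near matches: ",
                                  paste(head(near, 5L), collapse = ", "))
         else "")
  }
  stats::setNames(x[gene, ], colnames(x))
}

#' Pearson correlation of two gene profiles
#'
#' The coexpression measure of the pipeline: the standard product-moment
#' correlation, computed over all shared samples or a named subset. In this
#' pipeline profiles are rank-transformed first, so the coefficient is the
#' Spearman correlation of the raw values whenever ties are absent.
#'
#' @param x,y named numeric vectors over the same samples in the same order.
#' @param subset optional character vector of sample ids to restrict to.
#' @param minN smallest admissible number of samples (default 3); fewer is an
#'   error rather than an undefined value.
#' @return the correlation coefficient, a single number in `[-1, 1]`.
#' @export
pearsonCor <- function(x, y, subset = NULL, minN = 3L) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("profiles must carry sample ids as names")
  if (!identical(names(x), names(y)))
    stop("profiles must share sample ids and order")
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(x))
    if (length(missing))
      stop("subset sample(s) absent from profiles: ",
           paste(head(missing, 5L), collapse = ", "))
    x <- x[subset]
    y <- y[subset]
  }
  if (length(x) < minN)
    stop("cohort too small for correlation: n = ", length(x),
         " < ", minN)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("profiles contain non-finite values")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a profile over the requested samples; ",
         "correlation undefined")
  r <- cor(x, y)
  # guard against rounding just outside [-1, 1]
  max(-1, min(1, r))
}
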