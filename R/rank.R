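## Per-sample percentile-rank normalisation on the 0-100 scale.
## Within each sample (column), a value's rank is 100 times the fraction of
## the sample's probes with strictly lower measured values, so rank 55 means
## 55 per cent of that sample's probes are expressed below it. Ranking is a
## within-sample operation and needs no cross-sample normalisation.

.rankColumn <- function(v, ties) {
  n <- length(v)
  if (ties == "strict_lower") {
    # rank(ties = "min") - 1 == number of strictly smaller values
    (rank(v, ties.method = "min") - 1) * 100 / n
  } else {  # midrank: strictly-lower count plus half the other tied values
    (rank(v, ties.method = "average") - 1) * 100 / n
  }
}

#' @describeIn rankTransform per-sample percentile ranks of a probes-by-samples
#'   matrix.
#'
#' @param ties tie policy. `"strict_lower"` (default) assigns
#'   `100 * (number of strictly smaller values) / N` so that tied raw values
#'   share the rank of their lowest member; `"midrank"` instead centres tied
#'   values on their mid-position. Both leave untied values identical.
#' @return a numeric matrix of the same shape and dimnames with entries in
#'   `[0, 100)`; within each column ranks are a monotone non-decreasing
#'   function of the raw values.
#' @examples
#' m <- matrix(c(10, 20, 30, 40), ncol = 1,
#'             dimnames = list(paste0("p", 1:4), "S1"))
#' rankTransform(m)   # 0, 25, 50, 75
#' @export
setMethod("rankTransform", "matrix",
          function(x, ties = c("strict_lower", "midrank")) {
  ties <- match.arg(ties)
  if (!is.numeric(x))
    stop("expression matrix must be numeric")
  if (nrow(x) < 2L)
    stop("rank transformation needs at least 2 probes per sample")
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values; clean or impute first")
  out <- apply(x, 2L, .rankColumn, ties = ties)
  dimnames(out) <- dimnames(x)
  out
})

#' @describeIn rankTransform ranks the `"exprs"` assay of a
#'   SummarizedExperiment and stores the result as a new `"ranks"` assay.
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setMethod("rankTransform", "SummarizedExperiment",
          function(x, ties = c("strict_lower", "midrank")) {
  ranks <- rankTransform(SummarizedExperiment::assay(x, "exprs"), ties = ties)
  SummarizedExperiment::assay(x, "ranks") <- ranks
  x
})
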