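#' Accessors for CohortPartition objects
#'
#' @param object a [CohortPartition-class] object.
#' @return `cohort1` and `cohort2` return character vectors of sample ids
#'   (cohort 2 in removal order); `correlationTrace` returns the numeric
#'   vector of cohort-1 correlations, starting at the full-sample value;
#'   `splitParams` returns the configuration list.
#' @name CohortPartition-accessors
NULL

#' @rdname CohortPartition-accessors
#' @export
setGeneric("cohort1", function(object) standardGeneric("cohort1"))

#' @rdname CohortPartition-accessors
#' @export
setGeneric("cohort2", function(object) standardGeneric("cohort2"))

#' @rdname CohortPartition-accessors
#' @export
setGeneric("correlationTrace",
           function(object) standardGeneric("correlationTrace"))

#' @rdname CohortPartition-accessors
#' @export
setGeneric("splitParams", function(object) standardGeneric("splitParams"))

#' @rdname CohortPartition-accessors
#' @export
setMethod("cohort1", "CohortPartition", function(object) object@cohort1)

#' @rdname CohortPartition-accessors
#' @export
setMethod("cohort2", "CohortPartition", function(object) object@cohort2)

#' @rdname CohortPartition-accessors
#' @export
setMethod("correlationTrace", "CohortPartition",
          function(object) object@trace)

#' @rdname CohortPartition-accessors
#' @export
setMethod("splitParams", "CohortPartition", function(object) object@params)

#' Per-sample percentile-rank transformation
#'
#' @param x a numeric matrix (probes in rows, samples in columns) or a
#'   [SummarizedExperiment::SummarizedExperiment-class] carrying one.
#' @param ... passed to methods.
#' @export
setGeneric("rankTransform", function(x, ...) standardGeneric("rankTransform"))

#' Accessors for LogRankResult objects
#'
#' @param object a [LogRankResult-class] object.
#' @return `chisqStatistic` the chi-square statistic, `pValue` the two-sided
#'   p-value.
#' @name LogRankResult-accessors
NULL

#' @rdname LogRankResult-accessors
#' @export
setGeneric("chisqStatistic",
           function(object) standardGeneric("chisqStatistic"))

#' @rdname LogRankResult-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname LogRankResult-accessors
#' @export
setMethod("chisqStatistic", "LogRankResult",
          function(object) object@statistic)

#' @rdname LogRankResult-accessors
#' @export
setMethod("pValue", "LogRankResult", function(object) object@pValue)
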