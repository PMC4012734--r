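#' coexSplit: rank-based coexpression, greedy cohort splitting and survival
#'
#' The package implements a four-stage analysis of a gene pair in a patient
#' cohort: per-sample percentile-rank normalisation of expression values
#' (0--100 scale), Pearson coexpression of the two rank profiles, a greedy
#' leave-one-out partition of the cohort into a correlation-maximised
#' "interaction" cohort and its removed complement, and Kaplan--Meier /
#' log-rank comparison of patient survival between groups. A synthetic-data
#' generator with a planted correlated subpopulation and proportional-hazards
#' survival makes every stage testable without external data.
#'
#' @seealso [rankTransform()], [greedySplit()], [runInteractionSurvival()],
#'   [simulateDataset()]
#' @import methods
#' @importFrom stats cor median quantile rexp rnorm sd var complete.cases
#' @importFrom utils read.delim head tail
#' @name coexSplit-package
#' @aliases coexSplit
#' @keywords internal
"_PACKAGE"

#' CohortPartition: result of the greedy correlation-maximising split
#'
#' Produced by [greedySplit()]. Cohort 1 holds the retained samples whose
#' pairwise gene--gene correlation the procedure maximised; cohort 2 holds the
#' removed samples, in removal order. The trace records the cohort-1
#' correlation after each accepted removal (element 1 is the correlation on
#' the full sample set), and is strictly increasing from element 2 onward:
#' every accepted removal increased the correlation by more than the
#' configured tolerance.
#'
#' @slot cohort1 character vector of retained sample ids (input order).
#' @slot cohort2 character vector of removed sample ids, in removal order.
#' @slot trace numeric vector of cohort-1 correlations; `trace[1]` is the
#'   full-sample correlation, `trace[k + 1]` the correlation after the k-th
#'   removal, so `length(trace) == length(cohort2) + 1`.
#' @slot params named list of the configuration used (`minCohort1`, `tol`,
#'   `method`, `n`).
#'
#' @seealso [cohort1()], [cohort2()], [correlationTrace()], [splitParams()]
#' @exportClass CohortPartition
setClass("CohortPartition",
  representation(
    cohort1 = "character",
    cohort2 = "character",
    trace = "numeric",
    params = "list"
  )
)

setValidity("CohortPartition", function(object) {
  msg <- character(0)
  if (length(intersect(object@cohort1, object@cohort2)) > 0L)
    msg <- c(msg, "cohort1 and cohort2 must be disjoint")
  if (anyDuplicated(c(object@cohort1, object@cohort2)))
    msg <- c(msg, "sample ids must be unique across cohorts")
  if (length(object@trace) != length(object@cohort2) + 1L)
    msg <- c(msg, "trace must have one entry per removal plus the initial correlation")
  if (length(object@trace) > 1L && any(diff(object@trace) <= 0))
    msg <- c(msg, "trace must be strictly increasing after its first element")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortPartition-class compact display
#' @param object a `CohortPartition`
#' @export
setMethod("show", "CohortPartition", function(object) {
  cat("CohortPartition\n")
  cat(sprintf("  cohort 1 (interaction):    %d samples, r = %.4f\n",
              length(object@cohort1), tail(object@trace, 1L)))
  cat(sprintf("  cohort 2 (no interaction): %d samples (removal order)\n",
              length(object@cohort2)))
  cat(sprintf("  full-sample r = %.4f, %d removals accepted\n",
              object@trace[1L], length(object@cohort2)))
  cat(sprintf("  minCohort1 = %s, tol = %g, method = %s\n",
              object@params$minCohort1, object@params$tol,
              object@params$method))
  invisible(NULL)
})

#' KMCurve: a Kaplan--Meier (product-limit) survival curve
#'
#' Produced by [kmEstimate()]. Only distinct event times are tabulated;
#' censored observations enter through the risk sets.
#'
#' @slot time ascending distinct event times.
#' @slot surv product-limit survival estimate just after each event time;
#'   values in `[0, 1]`, non-increasing.
#' @slot nRisk number at risk just before each event time; strictly
#'   decreasing.
#' @slot nEvent number of events at each event time.
#' @slot n total number of subjects the curve was estimated from.
#'
#' @seealso [kmEstimate()], [as.data.frame()][KMCurve-class]
#' @exportClass KMCurve
setClass("KMCurve",
  representation(
    time = "numeric",
    surv = "numeric",
    nRisk = "integer",
    nEvent = "integer",
    n = "integer"
  )
)

setValidity("KMCurve", function(object) {
  k <- length(object@time)
  msg <- character(0)
  if (length(object@surv) != k || length(object@nRisk) != k ||
      length(object@nEvent) != k)
    msg <- c(msg, "time, surv, nRisk and nEvent must have equal length")
  if (k > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "event times must be strictly increasing")
  if (k > 0L && (any(object@surv < 0) || any(object@surv > 1)))
    msg <- c(msg, "survival estimates must lie in [0, 1]")
  if (k > 1L && any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival estimates must be non-increasing")
  if (k > 1L && any(diff(object@nRisk) >= 0L))
    msg <- c(msg, "numbers at risk must be strictly decreasing across event times")
  if (k > 0L && any(object@nEvent < 1L))
    msg <- c(msg, "each tabulated time must carry at least one event")
  if (length(msg)) msg else TRUE
})

#' @describeIn KMCurve-class compact display
#' @param object a `KMCurve`
#' @export
setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve: %d subjects, %d event times\n",
              object@n, length(object@time)))
  if (length(object@time)) {
    cat(sprintf("  final S(t) = %.4f at t = %g\n",
                tail(object@surv, 1L), tail(object@time, 1L)))
  } else {
    cat("  no events observed: S(t) = 1 throughout\n")
  }
  invisible(NULL)
})

#' @describeIn KMCurve-class coerce to a data.frame with columns `time`,
#'   `surv`, `n_risk`, `n_event`
#' @param x a `KMCurve`
#' @param ... ignored
#' @export
setMethod("as.data.frame", "KMCurve", function(x, ...) {
  data.frame(time = x@time, surv = x@surv,
             n_risk = x@nRisk, n_event = x@nEvent)
})

#' LogRankResult: two-group log-rank (Mantel--Cox) test
#'
#' Produced by [logRank()] and [comparePartitionSurvival()]. The statistic is
#' the chi-square form \eqn{(O_1 - E_1)^2 / V} on 1 degree of freedom, where
#' \eqn{O_1}, \eqn{E_1} and \eqn{V} are the observed events, expected events
#' and hypergeometric variance for group 1 summed over pooled distinct event
#' times.
#'
#' @slot statistic non-negative chi-square statistic.
#' @slot df degrees of freedom (always 1).
#' @slot pValue two-sided p-value from the chi-square reference distribution.
#' @slot nPerGroup integer vector, subjects per group.
#' @slot eventsPerGroup integer vector, observed events per group.
#'
#' @exportClass LogRankResult
setClass("LogRankResult",
  representation(
    statistic = "numeric",
    df = "integer",
    pValue = "numeric",
    nPerGroup = "integer",
    eventsPerGroup = "integer"
  )
)

setValidity("LogRankResult", function(object) {
  msg <- character(0)
  if (length(object@statistic) != 1L || is.na(object@statistic) ||
      object@statistic < 0)
    msg <- c(msg, "statistic must be a single non-negative number")
  if (!identical(object@df, 1L))
    msg <- c(msg, "df must be 1")
  if (length(object@pValue) != 1L || is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn LogRankResult-class compact display
#' @param object a `LogRankResult`
#' @export
setMethod("show", "LogRankResult", function(object) {
  cat("Two-group log-rank test\n")
  cat(sprintf("  n = %d vs %d, events = %d vs %d\n",
              object@nPerGroup[1L], object@nPerGroup[2L],
              object@eventsPerGroup[1L], object@eventsPerGroup[2L]))
  cat(sprintf("  chi-square = %.4f on %d df, p = %.4g\n",
              object@statistic, object@df, object@pValue))
  invisible(NULL)
})
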