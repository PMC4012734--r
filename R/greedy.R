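## The greedy cohort split. Starting from the full cohort, repeatedly remove
## the single sample whose removal yields the largest increase in the Pearson
## correlation between the two gene profiles, until no removal increases the
## correlation by more than `tol` or the cohort has shrunk to `minCohort1`
## samples. The retained samples form cohort 1 ("interaction"), the removed
## ones cohort 2 ("no interaction", in removal order).

# leave-one-out correlations for every member of a value vector pair.
# method "recompute": each candidate correlation from scratch.
# method "downdate": O(1) per candidate from the cohort's sufficient
# statistics (sums of x, y, x^2, y^2, xy), subtracting the candidate.
# Undefined correlations (zero variance after removal) come back as NA.
.looCors <- function(xv, yv, method) {
  k <- length(xv)
  if (method == "recompute") {
    out <- vapply(seq_len(k), function(i) {
      xs <- xv[-i]; ys <- yv[-i]
      if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
      cor(xs, ys)
    }, numeric(1L))
  } else {
    Sx <- sum(xv); Sy <- sum(yv)
    Sxx <- sum(xv^2); Syy <- sum(yv^2); Sxy <- sum(xv * yv)
    km1 <- k - 1
    ssx <- Sxx - xv^2 - (Sx - xv)^2 / km1
    ssy <- Syy - yv^2 - (Sy - yv)^2 / km1
    sxy <- Sxy - xv * yv - (Sx - xv) * (Sy - yv) / km1
    denom <- sqrt(pmax(ssx, 0) * pmax(ssy, 0))
    out <- ifelse(denom > 0, sxy / denom, NA_real_)
  }
  pmin(1, pmax(-1, out))
}

#' Leave-one-out correlation deltas for a cohort
#'
#' For every member of the cohort, the correlation the pair of profiles would
#' have if that one sample were removed, and the change relative to the
#' current cohort correlation. This is the quantity the greedy split scans at
#' each step.
#'
#' @param x,y named numeric profiles over the same samples (see
#'   [extractProfile()]).
#' @param cohort character vector of sample ids forming the current cohort 1;
#'   defaults to all samples. Must have at least 4 members so that every
#'   leave-one-out correlation is defined on >= 3 samples.
#' @param method `"recompute"` (default) or `"downdate"`; see [greedySplit()].
#' @return a data.frame with one row per cohort member: `sample_id`,
#'   `r_without` (the leave-one-out correlation, `NA` when undefined because
#'   of zero variance) and `delta` (`r_without` minus the current cohort
#'   correlation).
#' @export
looDeltas <- function(x, y, cohort = names(x),
                      method = c("recompute", "downdate")) {
  method <- match.arg(method)
  if (length(cohort) < 4L)
    stop("leave-one-out deltas need a cohort of at least 4 samples")
  rCur <- pearsonCor(x, y, subset = cohort)
  xv <- x[cohort]
  yv <- y[cohort]
  rw <- .looCors(xv, yv, method)
  if (anyNA(rw))
    message("looDeltas: ", sum(is.na(rw)),
            " member(s) with undefined leave-one-out correlation excluded ",
            "from candidacy")
  data.frame(sample_id = cohort,
             r_without = rw,
             delta = rw - rCur,
             stringsAsFactors = FALSE)
}

#' Greedily split a cohort to maximise a gene pair's correlation
#'
#' Starts with every sample in cohort 1. At each step the leave-one-out
#' correlation is evaluated for every current member; the member whose
#' removal maximally increases the correlation is moved to cohort 2, provided
#' the increase exceeds `tol`. The procedure stops when no removal increases
#' the correlation by more than `tol`, or when cohort 1 has shrunk to
#' `minCohort1` samples. Ties on the maximal increase are broken by the
#' lexicographically smallest sample id, so the procedure is deterministic.
#'
#' @param x,y named numeric profiles over the same samples, normally rank
#'   values from [rankTransform()].
#' @param minCohort1 smallest admissible cohort-1 size; default
#'   `max(10, ceiling(0.05 * n))`. Must be at least 3.
#' @param tol smallest correlation increase that counts as an improvement
#'   (default `1e-12`, a float-noise guard).
#' @param method `"recompute"` (default) re-derives every candidate
#'   correlation from scratch; `"downdate"` is an algebraically equivalent
#'   fast path using sufficient-statistic downdating, O(1) per candidate.
#' @return a [CohortPartition-class] object.
#' @examples
#' sim <- simulateDataset(simConfig(nSamples = 40, nBackgroundProbes = 50,
#'                                  seed = 7))
#' rk <- rankTransform(sim$exprs)
#' part <- greedySplit(extractProfile(rk, "TP63"),
#'                     extractProfile(rk, "MMP13"))
#' part
#' @export
greedySplit <- function(x, y, minCohort1 = NULL, tol = 1e-12,
                        method = c("recompute", "downdate")) {
  method <- match.arg(method)
  if (is.null(names(x)) || !identical(names(x), names(y)))
    stop("profiles must share sample ids and order")
  n <- length(x)
  if (is.null(minCohort1)) minCohort1 <- max(10L, ceiling(0.05 * n))
  minCohort1 <- as.integer(minCohort1)
  if (minCohort1 < 3L)
    stop("minCohort1 must be at least 3")
  if (n < max(minCohort1, 4L))
    stop("need at least max(minCohort1, 4) = ", max(minCohort1, 4L),
         " samples; got ", n)
  if (!(tol > 0)) stop("tol must be positive")
  if (sd(x) == 0 || sd(y) == 0)
    stop("initial correlation undefined: zero variance in a profile")

  members <- names(x)
  removed <- character(0)
  rCur <- pearsonCor(x, y)
  trace <- rCur
  while (length(members) > minCohort1 && length(members) >= 4L) {
    rw <- .looCors(x[members], y[members], method)
    if (all(is.na(rw))) break
    best <- max(rw, na.rm = TRUE)
    if (!(best - rCur > tol)) break
    # deterministic tie-break: smallest sample id among the maximisers
    cand <- members[!is.na(rw) & rw == best]
    pick <- min(cand)
    removed <- c(removed, pick)
    members <- setdiff(members, pick)
    rCur <- best
    trace <- c(trace, rCur)
  }
  methods::new("CohortPartition",
               cohort1 = members,
               cohort2 = removed,
               trace = trace,
               params = list(minCohort1 = minCohort1, tol = tol,
                             method = method, n = n))
}

#' Tabulate a partition for serialisation
#'
#' @param partition a [CohortPartition-class].
#' @return a data.frame with columns `sample_id`, `cohort` (1 or 2) and
#'   `removal_order` (`NA` for cohort-1 members).
#' @export
partitionTable <- function(partition) {
  stopifnot(methods::is(partition, "CohortPartition"))
  data.frame(
    sample_id = c(cohort1(partition), cohort2(partition)),
    cohort = rep(c(1L, 2L),
                 c(length(cohort1(partition)), length(cohort2(partition)))),
    removal_order = c(rep(NA_integer_, length(cohort1(partition))),
                      seq_along(cohort2(partition))),
    stringsAsFactors = FALSE)
}

#' Tabulate a partition's correlation trace
#'
#' @param partition a [CohortPartition-class].
#' @return a data.frame with columns `step` (0 = no removal yet),
#'   `n_cohort1` and `r`.
#' @export
traceTable <- function(partition) {
  stopifnot(methods::is(partition, "CohortPartition"))
  tr <- correlationTrace(partition)
  n <- splitParams(partition)$n
  data.frame(step = seq_along(tr) - 1L,
             n_cohort1 = n - (seq_along(tr) - 1L),
             r = tr)
}
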