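## Kaplan-Meier estimation and the two-group log-rank (Mantel-Cox) test,
## computed through the survival package behind a thin validated surface.
## Used both for the single-gene high/low marker analysis and for comparing
## the greedy split's two cohorts.

#' Kaplan--Meier (product-limit) survival estimate
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct event times
#' \eqn{t_i} with \eqn{d_i} events and \eqn{n_i} subjects at risk; censored
#' observations reduce later risk sets only. An event and a censoring tied at
#' the same time are resolved event-first (the standard convention).
#'
#' @param s a survival data.frame with columns `sample_id`, `time`, `event`.
#' @return a [KMCurve-class]; with no events the curve has no event times and
#'   \eqn{S(t) = 1} throughout.
#' @examples
#' s <- data.frame(sample_id = paste0("S", 1:5),
#'                 time = c(1, 2, 3, 4, 5),
#'                 event = c(0, 1, 1, 0, 1))
#' as.data.frame(kmEstimate(s))
#' @export
kmEstimate <- function(s) {
  s <- validateSurvivalTable(s)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = s)
  keep <- fit$n.event > 0
  methods::new("KMCurve",
               time = fit$time[keep],
               surv = fit$surv[keep],
               nRisk = as.integer(fit$n.risk[keep]),
               nEvent = as.integer(fit$n.event[keep]),
               n = nrow(s))
}

#' Two-group log-rank (Mantel--Cox) test
#'
#' Over the pooled distinct event times, group 1's observed events
#' \eqn{O_1 = \sum_i d_{1i}}, expected events
#' \eqn{E_1 = \sum_i d_i n_{1i} / n_i} and hypergeometric variance
#' \eqn{V = \sum_i d_i (n_{1i}/n_i)(1 - n_{1i}/n_i)(n_i - d_i)/(n_i - 1)}
#' give the chi-square statistic \eqn{(O_1 - E_1)^2 / V} on 1 degree of
#' freedom. When \eqn{V = 0} with \eqn{O_1 = E_1} (a fully degenerate
#' comparison) the statistic is defined as 0 with p = 1.
#'
#' @param a,b survival data.frames for the two groups.
#' @return a [LogRankResult-class].
#' @export
logRank <- function(a, b) {
  a <- validateSurvivalTable(a)
  b <- validateSurvivalTable(b)
  if (sum(a$event) + sum(b$event) == 0L)
    stop("no events in either group; log-rank test undefined")
  df <- data.frame(time = c(a$time, b$time),
                   event = c(a$event, b$event),
                   group = rep(c(1L, 2L), c(nrow(a), nrow(b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  o1 <- sd$obs[1L]
  e1 <- sd$exp[1L]
  v <- sd$var[1L, 1L]
  if (v <= 0) {
    if (abs(o1 - e1) > 1e-8)
      stop("degenerate log-rank: zero variance with O != E")
    stat <- 0
  } else {
    stat <- (o1 - e1)^2 / v
  }
  methods::new("LogRankResult",
               statistic = stat,
               df = 1L,
               pValue = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
               nPerGroup = c(nrow(a), nrow(b)),
               eventsPerGroup = as.integer(c(sum(a$event), sum(b$event))))
}

#' Split a survival table by a gene's expression level
#'
#' Samples whose profile value exceeds the `cutoff` quantile form the "high"
#' group, the rest the "low" group. The default cutoff is the median, the
#' usual convention for single-marker survival dichotomisation.
#'
#' @param profile named numeric vector of expression (normally rank) values.
#' @param s survival data.frame; only samples present in both inputs are
#'   used, and at least 4 shared samples are required.
#' @param cutoff quantile in (0, 1); default `0.5`.
#' @return a list with survival data.frames `low` and `high` and the numeric
#'   `threshold` used.
#' @export
splitByExpression <- function(profile, s, cutoff = 0.5) {
  s <- validateSurvivalTable(s)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L,
            cutoff > 0, cutoff < 1)
  shared <- intersect(names(profile), s$sample_id)
  if (length(shared) < 4L)
    stop("profile and survival table share fewer than 4 samples")
  p <- profile[shared]
  thr <- unname(quantile(p, probs = cutoff))
  highIds <- shared[p > thr]
  lowIds <- shared[p <= thr]
  if (length(highIds) == 0L || length(lowIds) == 0L)
    stop("cutoff quantile ", cutoff, " leaves the '",
         if (length(highIds) == 0L) "high" else "low",
         "' group empty; choose a different cutoff")
  list(low = s[s$sample_id %in% lowIds, , drop = FALSE],
       high = s[s$sample_id %in% highIds, , drop = FALSE],
       threshold = thr)
}

#' Compare survival between the two cohorts of a greedy split
#'
#' Restricts the survival table to each cohort and runs the two-group
#' log-rank test, returning the Kaplan--Meier curves alongside.
#'
#' @param partition a [CohortPartition-class].
#' @param s survival data.frame; each cohort must intersect it in at least
#'   2 samples.
#' @return a list with elements `logrank` ([LogRankResult-class]), `km` (a
#'   list of two [KMCurve-class] objects named `cohort1`, `cohort2`) and `n`
#'   (integer vector of per-cohort sample counts used).
#' @export
comparePartitionSurvival <- function(partition, s) {
  stopifnot(methods::is(partition, "CohortPartition"))
  s <- validateSurvivalTable(s)
  if (length(cohort2(partition)) == 0L)
    stop("partition has an empty cohort 2; no second group to compare")
  s1 <- s[s$sample_id %in% cohort1(partition), , drop = FALSE]
  s2 <- s[s$sample_id %in% cohort2(partition), , drop = FALSE]
  if (nrow(s1) < 2L || nrow(s2) < 2L)
    stop("each cohort must intersect the survival table in at least 2 samples ",
         "(got ", nrow(s1), " and ", nrow(s2), ")")
  list(logrank = logRank(s1, s2),
       km = list(cohort1 = kmEstimate(s1), cohort2 = kmEstimate(s2)),
       n = c(cohort1 = nrow(s1), cohort2 = nrow(s2)))
}
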