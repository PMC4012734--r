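# Independent oracles and fixture builders. Each oracle is a deliberately
# naive, formula-level computation kept separate from the package's code
# paths.

# percentile rank by brute-force pairwise counting of strictly smaller values
bruteRank <- function(v) {
  unname(vapply(v, function(x) sum(v < x), numeric(1L))) * 100 / length(v)
}

# two-pass textbook Pearson: explicit sums of squares / cross-products
brutePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# reference greedy split: exhaustive scan at every step, brutePearson
# throughout, tie broken by smallest sample id; returns removal order and the
# correlation trace
bruteGreedy <- function(x, y, minCohort1, tol = 1e-12) {
  members <- names(x)
  removed <- character(0)
  rCur <- brutePearson(x[members], y[members])
  trace <- rCur
  while (length(members) > minCohort1 && length(members) >= 4L) {
    rw <- vapply(members, function(id) {
      keep <- setdiff(members, id)
      if (sd(x[keep]) == 0 || sd(y[keep]) == 0) return(NA_real_)
      brutePearson(x[keep], y[keep])
    }, numeric(1L))
    if (all(is.na(rw))) break
    best <- max(rw, na.rm = TRUE)
    if (!(best - rCur > tol)) break
    pick <- min(members[!is.na(rw) & rw == best])
    removed <- c(removed, pick)
    members <- setdiff(members, pick)
    rCur <- best
    trace <- c(trace, rCur)
  }
  list(cohort1 = members, cohort2 = removed, trace = trace)
}

# explicit per-event-time 2x2-table log-rank arithmetic (O1, E1, V sums)
bruteLogRank <- function(a, b) {
  times <- c(a$time, b$time)
  event <- c(a$event, b$event)
  group <- rep(c(1L, 2L), c(nrow(a), nrow(b)))
  ts <- sort(unique(times[event == 1L]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == 1L)
    d <- sum(event == 1L & times == t)
    d1 <- sum(event == 1L & times == t & group == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  list(O1 = O1, E1 = E1, V = V, stat = stat)
}

# random survival table
randomSurvTable <- function(n, hazard = log(2) / 12, censorRate = NULL,
                            prefix = "S") {
  et <- rexp(n, hazard)
  if (is.null(censorRate)) {
    time <- et
    event <- rep(1L, n)
  } else {
    ct <- rexp(n, censorRate)
    time <- pmin(et, ct)
    event <- as.integer(et <= ct)
  }
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             time = time, event = event, stringsAsFactors = FALSE)
}

# small named expression matrix fixture
toyMatrix <- function(nProbes = 5, nSamples = 4, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nProbes * nSamples),
         nrow = nProbes, ncol = nSamples,
         dimnames = list(sprintf("p%02d", seq_len(nProbes)),
                         sprintf("S%02d", seq_len(nSamples))))
}

# named profile helper
asProfile <- function(v, ids = sprintf("S%03d", seq_along(v))) {
  names(v) <- ids
  v
}
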