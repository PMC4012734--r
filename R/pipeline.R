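## End-to-end orchestration of the three analyses: coexpression of a gene
## pair, single-marker high/low survival, and the greedy interaction /
## no-interaction cohort comparison. Each run logs its stages, writes TSV
## reports plus a JSON manifest sufficient to replay it, and returns its
## results invisibly.

#' Pipeline run configuration
#'
#' Inputs come either from files (`matrix`, `survival`, `probeMap`) or from a
#' simulation (`sim`); flags select the analysis mode and stage parameters.
#'
#' @param mode one of `"coexpr"`, `"marker_survival"`,
#'   `"interaction_survival"`.
#' @param matrix,survival,probeMap input file paths, or `NULL`.
#' @param sim a [simConfig()] object to generate inputs instead of reading
#'   files.
#' @param geneA,geneB gene (row) names; `geneB` is not used by
#'   `marker_survival`.
#' @param ties tie policy for [rankTransform()].
#' @param collapsePolicy,namedProbes probe-collapsing controls (see
#'   [collapseProbes()]); collapsing only runs when `probeMap` is given.
#' @param minCohort1,tol greedy-split controls (see [greedySplit()]).
#' @param cutoff quantile for the high/low marker split.
#' @param rawCorrelation if `TRUE`, correlate raw instead of rank values
#'   (non-default; the pipeline's convention is rank-based correlation).
#' @param outDir output directory, created if absent.
#' @param seed integer seed recorded in the manifest (drives `sim` when the
#'   simulation carries no seed of its own).
#' @return a validated list of class `"RunConfig"`.
#' @export
runConfig <- function(mode = c("coexpr", "marker_survival",
                               "interaction_survival"),
                      matrix = NULL, survival = NULL, probeMap = NULL,
                      sim = NULL,
                      geneA = NULL, geneB = NULL,
                      ties = "strict_lower",
                      collapsePolicy = "max_variance",
                      namedProbes = NULL,
                      minCohort1 = NULL, tol = 1e-12,
                      cutoff = 0.5,
                      rawCorrelation = FALSE,
                      outDir = tempfile("coexsplit_run_"),
                      seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, matrix = matrix, survival = survival,
              probeMap = probeMap, sim = sim, geneA = geneA, geneB = geneB,
              ties = ties, collapsePolicy = collapsePolicy,
              namedProbes = namedProbes, minCohort1 = minCohort1, tol = tol,
              cutoff = cutoff, rawCorrelation = rawCorrelation,
              outDir = outDir, seed = as.integer(seed))
  if (is.null(cfg$matrix) && is.null(cfg$sim))
    stop("provide either an expression matrix path or a simulation config")
  if (is.null(cfg$geneA))
    stop("geneA is required")
  if (mode != "marker_survival" && is.null(cfg$geneB))
    stop("geneB is required for mode '", mode, "'")
  if (mode != "coexpr" && is.null(cfg$survival) && is.null(cfg$sim))
    stop("a survival table is required for mode '", mode, "'")
  class(cfg) <- "RunConfig"
  cfg
}

# run `expr`, prefixing any error with the pipeline stage name
.stage <- function(name, expr) {
  message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.loadInputs <- function(cfg) {
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    if (!inherits(sim, "SimConfig"))
      stop("'sim' must be a simConfig() object")
    dat <- .stage("simulate", simulateDataset(sim))
    writeDataset(dat, file.path(cfg$outDir, "simulated_input"))
    list(exprs = dat$exprs, surv = dat$surv, truth = dat$truth)
  } else {
    exprs <- .stage("read_matrix", readExpressionMatrix(cfg$matrix))
    surv <- if (!is.null(cfg$survival))
      .stage("read_survival", readSurvivalTable(cfg$survival)) else NULL
    list(exprs = exprs, surv = surv, truth = NULL)
  }
}

.prepareRanks <- function(cfg, exprs) {
  ranks <- .stage("rank_transform", rankTransform(exprs, ties = cfg$ties))
  if (!is.null(cfg$probeMap)) {
    map <- .stage("read_probe_map", readProbeGeneMap(cfg$probeMap))
    ranks <- .stage("collapse_probes",
                    collapseProbes(ranks, map, policy = cfg$collapsePolicy,
                                   probes = cfg$namedProbes))
  }
  ranks
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writeManifest <- function(cfg, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    config = lapply(unclass(cfg), function(v)
      if (inherits(v, "SimConfig")) unclass(v) else v),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("coexSplit")),
    r_version = R.version.string,
    outputs = as.list(tools::md5sum(files))
  )
  path <- file.path(cfg$outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Run the coexpression analysis
#'
#' Rank-transforms the matrix, collapses probes when a map is supplied,
#' and reports the Pearson correlation of the two genes' rank profiles over
#' all samples. Writes `coexpr.tsv` and `manifest.json` to the output
#' directory.
#'
#' @param cfg a [runConfig()] with `mode = "coexpr"`.
#' @return invisibly, a list with the report data.frame (`gene_a`, `gene_b`,
#'   `cohort`, `n`, `r`) and the output directory.
#' @export
runCoexpr <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"), cfg$mode == "coexpr")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  dat <- .loadInputs(cfg)
  vals <- if (cfg$rawCorrelation) dat$exprs else .prepareRanks(cfg, dat$exprs)
  a <- .stage("extract_profiles", extractProfile(vals, cfg$geneA))
  b <- .stage("extract_profiles", extractProfile(vals, cfg$geneB))
  r <- .stage("pearson", pearsonCor(a, b))
  report <- data.frame(gene_a = cfg$geneA, gene_b = cfg$geneB,
                       cohort = "all", n = length(a), r = r,
                       stringsAsFactors = FALSE)
  f <- .writeTSV(report, file.path(cfg$outDir, "coexpr.tsv"))
  .writeManifest(cfg, f)
  message(sprintf("coexpr: r(%s, %s) = %.4f over n = %d samples",
                  cfg$geneA, cfg$geneB, r, length(a)))
  invisible(list(report = report, outDir = cfg$outDir))
}

#' Run the single-marker high/low survival analysis
#'
#' Rank-transforms, splits samples into high and low expressers of `geneA` at
#' the configured quantile, estimates a Kaplan--Meier curve per group and
#' compares them by the log-rank test. Writes `km_low.tsv`, `km_high.tsv`,
#' `logrank.tsv` and `manifest.json`.
#'
#' @param cfg a [runConfig()] with `mode = "marker_survival"`.
#' @return invisibly, a list with `logrank` ([LogRankResult-class]), `km`
#'   (list of curves), `groups` (the two survival tables and threshold) and
#'   the output directory.
#' @export
runMarkerSurvival <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"), cfg$mode == "marker_survival")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  dat <- .loadInputs(cfg)
  al <- .stage("align_samples", alignSamples(dat$exprs, dat$surv))
  ranks <- .prepareRanks(cfg, al$exprs)
  prof <- .stage("extract_profiles", extractProfile(ranks, cfg$geneA))
  grp <- .stage("split_by_expression",
                splitByExpression(prof, al$surv, cutoff = cfg$cutoff))
  kmLow <- .stage("km_estimate", kmEstimate(grp$low))
  kmHigh <- .stage("km_estimate", kmEstimate(grp$high))
  lr <- .stage("log_rank", logRank(grp$high, grp$low))
  files <- c(
    .writeTSV(as.data.frame(kmLow), file.path(cfg$outDir, "km_low.tsv")),
    .writeTSV(as.data.frame(kmHigh), file.path(cfg$outDir, "km_high.tsv")),
    .writeTSV(data.frame(gene = cfg$geneA, cutoff = cfg$cutoff,
                         threshold = grp$threshold,
                         n_high = nrow(grp$high), n_low = nrow(grp$low),
                         events_high = sum(grp$high$event),
                         events_low = sum(grp$low$event),
                         chisq = chisqStatistic(lr), p_value = pValue(lr)),
              file.path(cfg$outDir, "logrank.tsv")))
  .writeManifest(cfg, files)
  message(sprintf(
    "marker_survival: %s high (n=%d) vs low (n=%d), log-rank p = %.4g",
    cfg$geneA, nrow(grp$high), nrow(grp$low), pValue(lr)))
  invisible(list(logrank = lr, km = list(low = kmLow, high = kmHigh),
                 groups = grp, outDir = cfg$outDir))
}

#' Run the interaction / no-interaction cohort survival analysis
#'
#' Rank-transforms, greedily splits the cohort to maximise the two genes'
#' correlation in cohort 1, reports per-cohort correlations, and compares the
#' cohorts' survival by Kaplan--Meier and log-rank. If the split leaves
#' cohort 2 with fewer than 2 samples the survival comparison is skipped with
#' a note rather than an error. Writes `partition.tsv`, `trace.tsv`,
#' `correlations.tsv`, per-cohort KM curves, `logrank.tsv` and
#' `manifest.json`.
#'
#' @param cfg a [runConfig()] with `mode = "interaction_survival"`.
#' @return invisibly, a list with `partition` ([CohortPartition-class]),
#'   `correlations` (data.frame), `survival` (the
#'   [comparePartitionSurvival()] result, or `NULL` when skipped), `note`
#'   and the output directory.
#' @export
runInteractionSurvival <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"), cfg$mode == "interaction_survival")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  dat <- .loadInputs(cfg)
  al <- .stage("align_samples", alignSamples(dat$exprs, dat$surv))
  ranks <- .prepareRanks(cfg, al$exprs)
  a <- .stage("extract_profiles", extractProfile(ranks, cfg$geneA))
  b <- .stage("extract_profiles", extractProfile(ranks, cfg$geneB))
  part <- .stage("greedy_split",
                 greedySplit(a, b, minCohort1 = cfg$minCohort1,
                             tol = cfg$tol))
  r2 <- tryCatch(pearsonCor(a, b, subset = cohort2(part)),
                 error = function(e) NA_real_)
  correlations <- data.frame(
    gene_a = cfg$geneA, gene_b = cfg$geneB,
    cohort = c("all", "cohort1", "cohort2"),
    n = c(length(a), length(cohort1(part)), length(cohort2(part))),
    r = c(correlationTrace(part)[1L], tail(correlationTrace(part), 1L), r2),
    stringsAsFactors = FALSE)
  files <- c(
    .writeTSV(partitionTable(part), file.path(cfg$outDir, "partition.tsv")),
    .writeTSV(traceTable(part), file.path(cfg$outDir, "trace.tsv")),
    .writeTSV(correlations, file.path(cfg$outDir, "correlations.tsv")))
  note <- NA_character_
  cmp <- NULL
  if (length(cohort2(part)) < 2L) {
    note <- "no second cohort; survival comparison skipped"
    message("interaction_survival: ", note)
  } else {
    cmp <- .stage("compare_partition_survival",
                  comparePartitionSurvival(part, al$surv))
    files <- c(files,
      .writeTSV(as.data.frame(cmp$km$cohort1),
                file.path(cfg$outDir, "km_cohort1.tsv")),
      .writeTSV(as.data.frame(cmp$km$cohort2),
                file.path(cfg$outDir, "km_cohort2.tsv")),
      .writeTSV(data.frame(n_cohort1 = cmp$n[["cohort1"]],
                           n_cohort2 = cmp$n[["cohort2"]],
                           chisq = chisqStatistic(cmp$logrank),
                           p_value = pValue(cmp$logrank)),
                file.path(cfg$outDir, "logrank.tsv")))
    message(sprintf(
      "interaction_survival: r %.3f -> %.3f, cohorts %d/%d, log-rank p = %.4g",
      correlationTrace(part)[1L], tail(correlationTrace(part), 1L),
      cmp$n[["cohort1"]], cmp$n[["cohort2"]], pValue(cmp$logrank)))
  }
  .writeManifest(cfg, files)
  invisible(list(partition = part, correlations = correlations,
                 survival = cmp, note = note, outDir = cfg$outDir))
}
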