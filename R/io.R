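## Reading, writing and validating the tabular inputs: expression matrices
## (probes x samples, TSV, GEO series-matrix orientation), survival tables
## and probe -> gene maps.

#' Read a tab-separated expression matrix
#'
#' Expects the GEO series-matrix text convention: first row holds sample ids
#' (the first cell is empty or `"probe_id"`), first column holds probe ids,
#' remaining cells are numeric intensities. Probes are rows, samples columns;
#' set `transpose = TRUE` for files stored the other way around.
#'
#' @param path path to the TSV file.
#' @param strict logical; if `TRUE` (default) any missing or non-numeric cell
#'   is a hard error reported with its probe/sample coordinates. If `FALSE`,
#'   missing cells are imputed by the per-probe mean of the observed values.
#' @param transpose logical; transpose the matrix after reading.
#' @return a numeric matrix with unique rownames (probes) and colnames
#'   (samples), all values finite.
#' @examples
#' sim <- simulateDataset(simConfig(nSamples = 6, nBackgroundProbes = 4,
#'                                  seed = 1))
#' tf <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(sim$exprs, tf)
#' m <- readExpressionMatrix(tf)
#' dim(m)
#' @export
readExpressionMatrix <- function(path, strict = TRUE, transpose = FALSE) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path))
    stop("expression matrix file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    quote = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty expression matrix: need at least one probe and one sample")
  probes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  .checkUniqueIds(probes, "probe")
  .checkUniqueIds(samples, "sample")
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw), ncol = length(samples),
                 dimnames = list(probes, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    if (strict) {
      loc <- sprintf("probe '%s' / sample '%s'",
                     probes[bad[1L, 1L]], samples[bad[1L, 2L]])
      stop("non-numeric or missing value at ", loc,
           " (", nrow(bad), " offending cell(s) in total); ",
           "set strict = FALSE to impute by per-probe means")
    }
    for (i in unique(bad[, 1L])) {
      row <- vals[i, ]
      if (all(!is.finite(row)))
        stop("probe '", probes[i], "' has no finite values; cannot impute")
      row[!is.finite(row)] <- mean(row[is.finite(row)])
      vals[i, ] <- row
    }
    message("imputed ", nrow(bad), " missing cell(s) by per-probe means")
  }
  if (transpose) vals <- t(vals)
  message(sprintf("read expression matrix: %d probes x %d samples",
                  nrow(vals), ncol(vals)))
  vals
}

#' Write an expression (or rank) matrix as TSV
#'
#' Values are serialised with 17 significant digits so that a
#' write/read round-trip reproduces finite doubles bit-exactly.
#'
#' @param x numeric matrix with row and column names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x),
            !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c("probe_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a survival table
#'
#' Expects a TSV with header columns `sample_id`, `time`, `event`:
#' follow-up time (positive, one unit throughout the table) and the event
#' indicator (1 = event observed, 0 = right-censored).
#'
#' @param path path to the TSV file.
#' @return a data.frame with columns `sample_id` (character, unique), `time`
#'   (positive numeric) and `event` (integer 0/1).
#' @export
readSurvivalTable <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path))
    stop("survival table file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  validateSurvivalTable(
    data.frame(sample_id = as.character(df$sample_id),
               time = suppressWarnings(as.numeric(df$time)),
               event = suppressWarnings(as.numeric(df$event)),
               stringsAsFactors = FALSE),
    required = c("sample_id", "time", "event") %in% colnames(df)
  )
}

#' Validate a survival table held in memory
#'
#' @param s a data.frame with columns `sample_id`, `time`, `event`.
#' @param required internal; logical vector flagging column presence.
#' @return the validated data.frame, `event` coerced to integer.
#' @export
validateSurvivalTable <- function(s, required = rep(TRUE, 3L)) {
  if (!all(required))
    stop("survival table must have header columns sample_id, time, event")
  if (!all(c("sample_id", "time", "event") %in% colnames(s)))
    stop("survival table must have columns sample_id, time, event")
  if (nrow(s) == 0L)
    stop("empty survival table")
  .checkUniqueIds(s$sample_id, "sample")
  if (any(!is.finite(s$time)) || any(s$time <= 0))
    stop("non-positive time for sample(s): ",
         paste(head(s$sample_id[!is.finite(s$time) | s$time <= 0], 5L),
               collapse = ", "))
  if (any(!s$event %in% c(0, 1)))
    stop("event indicator outside {0,1} for sample(s): ",
         paste(head(s$sample_id[!s$event %in% c(0, 1)], 5L),
               collapse = ", "))
  s$event <- as.integer(s$event)
  s
}

#' Write a survival table as TSV
#'
#' @param s validated survival data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSurvivalTable <- function(s, path) {
  s <- validateSurvivalTable(s)
  lines <- c("sample_id\ttime\tevent",
             sprintf("%s\t%.17g\t%d", s$sample_id, s$time, s$event))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV `probe_id<TAB>gene_symbol`; every probe maps to exactly one
#' gene symbol, a symbol may own several probes.
#'
#' @param path path to the TSV file.
#' @return a data.frame with character columns `probe_id` (unique) and
#'   `gene_symbol`.
#' @export
readProbeGeneMap <- function(path) {
  if (!file.exists(path))
    stop("probe map file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (!all(c("probe_id", "gene_symbol") %in% colnames(df)))
    stop("probe map must have columns probe_id, gene_symbol")
  .checkUniqueIds(df$probe_id, "probe")
  data.frame(probe_id = as.character(df$probe_id),
             gene_symbol = as.character(df$gene_symbol),
             stringsAsFactors = FALSE)
}

#' Restrict an expression matrix and a survival table to shared samples
#'
#' Both outputs are ordered by the matrix's column order. The number of
#' samples dropped from each input is reported via `message()`.
#'
#' @param exprs numeric matrix, samples in columns.
#' @param surv survival data.frame (see [readSurvivalTable()]).
#' @return a list with elements `exprs` and `surv` restricted to the shared
#'   sample ids.
#' @export
alignSamples <- function(exprs, surv) {
  surv <- validateSurvivalTable(surv)
  shared <- intersect(colnames(exprs), surv$sample_id)
  if (length(shared) < 2L)
    stop("fewer than 2 samples shared between expression matrix and ",
         "survival table (", length(shared), " shared)")
  shared <- colnames(exprs)[colnames(exprs) %in% shared]
  dropM <- ncol(exprs) - length(shared)
  dropS <- nrow(surv) - length(shared)
  if (dropM + dropS > 0L)
    message(sprintf("alignSamples: dropped %d matrix sample(s), %d survival record(s)",
                    dropM, dropS))
  list(exprs = exprs[, shared, drop = FALSE],
       surv = surv[match(shared, surv$sample_id), , drop = FALSE])
}

#' Collapse probe rows to one row per gene
#'
#' @param exprs numeric matrix, probes in rows.
#' @param map probe-to-gene data.frame (see [readProbeGeneMap()]). Probes
#'   absent from the map are dropped with a message.
#' @param policy `"max_variance"` (default) keeps, per gene, the probe with
#'   the largest variance across samples (ties broken by lexicographically
#'   smallest probe id); `"mean"` averages the gene's probes per sample;
#'   `"named_probe"` keeps exactly the probes listed in `probes`.
#' @param probes for `policy = "named_probe"`: named character vector mapping
#'   gene symbol to the probe id to keep.
#' @return numeric matrix with one row per gene; sample ids and column order
#'   unchanged.
#' @export
collapseProbes <- function(exprs,
                           map,
                           policy = c("max_variance", "mean", "named_probe"),
                           probes = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.matrix(exprs), !is.null(rownames(exprs)))
  known <- rownames(exprs) %in% map$probe_id
  if (!all(known))
    message("collapseProbes: dropping ", sum(!known),
            " probe(s) absent from the map")
  if (!any(known))
    stop("no probe of the matrix appears in the map")
  exprs <- exprs[known, , drop = FALSE]
  gene <- map$gene_symbol[match(rownames(exprs), map$probe_id)]
  if (policy == "named_probe") {
    if (is.null(probes) || is.null(names(probes)))
      stop("policy 'named_probe' requires a named 'probes' vector (gene -> probe)")
    missing <- setdiff(probes, rownames(exprs))
    if (length(missing))
      stop("named probe(s) absent from the matrix: ",
           paste(missing, collapse = ", "))
    out <- exprs[probes, , drop = FALSE]
    rownames(out) <- names(probes)
    return(out)
  }
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(exprs),
                dimnames = list(genes, colnames(exprs)))
  for (g in genes) {
    rows <- which(gene == g)
    if (policy == "mean") {
      out[g, ] <- colMeans(exprs[rows, , drop = FALSE])
    } else {  # max_variance; tie -> smallest probe id
      v <- apply(exprs[rows, , drop = FALSE], 1L, var)
      best <- rows[order(-v, rownames(exprs)[rows])[1L]]
      out[g, ] <- exprs[best, ]
    }
  }
  out
}

#' Bundle expression and survival data into a SummarizedExperiment
#'
#' Samples are aligned with [alignSamples()]; follow-up time and event
#' indicator land in `colData` as `time` and `event`, the matrix in the
#' `"exprs"` assay.
#'
#' @param exprs numeric matrix, probes in rows, samples in columns.
#' @param surv survival data.frame, or `NULL` to bundle expression only.
#' @return a [SummarizedExperiment::SummarizedExperiment-class].
#' @export
makeCoexExperiment <- function(exprs, surv = NULL) {
  if (!is.null(surv)) {
    al <- alignSamples(exprs, surv)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = al$exprs),
      colData = S4Vectors::DataFrame(time = al$surv$time,
                                     event = al$surv$event,
                                     row.names = al$surv$sample_id))
  } else {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = exprs))
  }
  se
}

# shared id validation: non-empty, non-missing, unique
.checkUniqueIds <- function(ids, what) {
  if (any(is.na(ids) | !nzchar(ids)))
    stop("missing or empty ", what, " identifier")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated ", what, " id(s): ", paste(head(dup, 5L), collapse = ", "))
  invisible(TRUE)
}
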