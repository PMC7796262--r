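# Expression-matrix summarization: complete-linkage clustering, the
# differential-expression threshold filter, expression banding, and report
# assembly.

#' Validate a log2 expression matrix
#'
#' @param mat numeric matrix, genes in rows, samples in columns, log2
#'   scale. Must be complete; `na_action = "drop_rows"` removes rows with
#'   missing values instead of failing.
#' @param na_action `"fail"` (default) or `"drop_rows"`.
#' @return the validated (possibly row-filtered) matrix.
#' @export
expression_matrix <- function(mat, na_action = c("fail", "drop_rows")) {
  na_action <- match.arg(na_action)
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (anyNA(mat)) {
    if (na_action == "fail") {
      stop("expression matrix contains missing values")
    }
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  }
  mat
}

#' Hierarchical clustering with complete linkage
#'
#' Agglomerative clustering of genes (rows) or samples (columns) using
#' Euclidean distance and complete linkage -- the combination under which
#' merge heights are monotone non-decreasing.
#'
#' @param mat expression matrix (genes x samples).
#' @param axis cluster `"genes"` (rows, default) or `"samples"` (columns).
#' @return an object of class `hclust` (merge list, heights, leaf order).
#' @export
hcluster <- function(mat, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  mat <- expression_matrix(mat)
  if (axis == "samples") mat <- t(mat)
  if (nrow(mat) < 2L) stop("need at least two items on the '", axis, "' axis")
  stats::hclust(stats::dist(mat, method = "euclidean"), method = "complete")
}

#' Differential-expression threshold filter
#'
#' Splits a DE table into up- and down-regulated sets using inclusive
#' thresholds: up when `log2fc >= lfc` and `padj <= alpha`, down when
#' `log2fc <= -lfc` and `padj <= alpha`. Boundary values pass.
#'
#' @param records data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @param lfc absolute log2 fold-change threshold (default 1.2).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @return list with data.frames `up` and `down` (disjoint).
#' @export
de_filter <- function(records, lfc = 1.2, alpha = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "log2fc", "padj") %in% names(records)))
  if (any(records$padj < 0 | records$padj > 1, na.rm = TRUE)) {
    stop("padj values must lie in [0, 1]")
  }
  sig <- !is.na(records$padj) & records$padj <= alpha
  list(up = records[sig & records$log2fc >= lfc, , drop = FALSE],
       down = records[sig & records$log2fc <= -lfc, , drop = FALSE])
}

#' Default expression band table
#'
#' Named log2 expression bands: low below 2.0, moderate 4.0-6.0 and high
#' above 6.0, with the 2.0-4.0 gap between the named bands mapped
#' explicitly to a `moderate_low` band. Each band is lower-inclusive and
#' upper-exclusive except where `upper_inclusive` says otherwise (6.0
#' falls in `moderate`; the assignment at that shared endpoint is a
#' configuration choice).
#'
#' @return data.frame with columns `name`, `upper`, `upper_inclusive`,
#'   evaluated in order.
#' @export
default_expression_bands <- function() {
  data.frame(
    name = c("low", "moderate_low", "moderate", "high"),
    upper = c(2, 4, 6, Inf),
    upper_inclusive = c(FALSE, FALSE, TRUE, TRUE))
}

#' Band a log2 expression value
#'
#' @param value numeric vector of log2 expression values.
#' @param bands band table as from [default_expression_bands()].
#' @return character vector of band names.
#' @examples
#' expression_band(c(1.9, 5.0, 8.0))  # low, moderate, high
#' @export
expression_band <- function(value, bands = default_expression_bands()) {
  stopifnot(is.numeric(value), is.data.frame(bands))
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    for (i in seq_len(nrow(bands))) {
      hit <- if (bands$upper_inclusive[i]) v <= bands$upper[i] else v < bands$upper[i]
      if (hit) return(bands$name[i])
    }
    bands$name[nrow(bands)]
  }, character(1))
}

#' Assemble a reproducible report directory
#'
#' Writes one file per analysis stage: data.frames and matrices as TSV,
#' anything else as JSON, plus a `run_info.json` with the seed,
#' configuration and package version. Stages passed as `NULL` are recorded
#' as skipped rather than failing the run. Output is deterministic: the
#' same inputs yield byte-identical TSVs.
#'
#' @param stages named list of stage outputs (`NULL` entries are skipped).
#' @param dir output directory (created if needed).
#' @param seed optional seed to record.
#' @param config optional configuration list to record.
#' @return invisibly, a character vector of the files written.
#' @export
build_report <- function(stages, dir, seed = NULL, config = list()) {
  stopifnot(is.list(stages), length(names(stages)) == length(stages))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  skipped <- character(0)
  for (nm in names(stages)) {
    x <- stages[[nm]]
    if (is.null(x)) {
      skipped <- c(skipped, nm)
      next
    }
    if (is.matrix(x)) x <- as.data.frame(x)
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE,
                           pretty = TRUE)
    }
    written <- c(written, f)
  }
  info <- list(package = "zipperscan",
               version = as.character(utils::packageVersion("zipperscan")),
               seed = seed, config = config,
               stages_written = names(stages)[!names(stages) %in% skipped],
               stages_skipped = skipped)
  f <- file.path(dir, "run_info.json")
  jsonlite::write_json(info, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(written, f))
}
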