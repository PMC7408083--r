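#' Read a gene x sample expression table
#'
#' Reads a tab-delimited matrix with gene symbols in the first column and
#' sample identifiers in the header row. GEO series-matrix-style files are
#' supported: metadata lines starting with `!` or `#` are skipped, and an
#' `ID_REF`-style header is accepted. The scale (log2 vs linear) is taken
#' from `scale_hint` when given, otherwise inferred: a maximum value below
#' 30 is read as log2 (microarray/log-TPM values never exceed ~25), else
#' linear. Linear matrices are never silently transformed; use [to_log2()].
#'
#' @param path path to a tab-delimited file.
#' @param scale_hint optional `"log2"` or `"linear"` overriding inference.
#' @param pseudocount declared pseudocount floor for log2 data.
#' @return an [expr_matrix].
#' @export
read_expression <- function(path, scale_hint = NULL, pseudocount = 1) {
  if (!file.exists(path))
    stop("expression file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[!#]", lines) & nzchar(lines)]
  if (length(lines) < 2L)
    stop("unparseable expression file (need a header plus >=1 gene row): ",
         path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(text = lines, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\""),
    error = function(e) stop("unparseable expression file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  if (ncol(df) < 2L)
    stop("expression file has zero samples: ", path, call. = FALSE)
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
    if (all(is.na(vals)))
      stop("unparseable expression file (non-numeric body): ", path,
           call. = FALSE)
  }
  rownames(vals) <- genes

  if (is.null(scale_hint)) {
    mx <- max(vals, na.rm = TRUE)
    scale <- if (mx < 30) "log2" else "linear"
    message("read_expression: inferred scale = ", scale,
            " (max value ", signif(mx, 4), ")")
  } else {
    scale <- match.arg(scale_hint, c("log2", "linear"))
  }
  expr_matrix(vals, scale = scale, pseudocount = pseudocount)
}

#' Write an expression matrix as TSV
#'
#' Tab-delimited, UTF-8, `.` decimal; gene symbols in the first column
#' (header `gene`), samples across the header. Round-trips through
#' [read_expression()] to at least 6 significant digits.
#'
#' @param m an [expr_matrix]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression <- function(m, path) {
  assert_expr(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     utf8, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a linear-scale matrix
#'
#' `values' = log2(values + pseudocount)`. Calling this on a matrix that is
#' already log2 is an error, not a silent no-op: double transformation is a
#' classic silent corruption of signature scores.
#'
#' @param m a linear-scale [expr_matrix]
#' @param pseudocount positive offset; the default 1 maps zero to zero.
#' @return a log2-scale [expr_matrix]
#' @export
to_log2 <- function(m, pseudocount = 1) {
  assert_expr(m)
  if (identical(expr_scale(m), "log2"))
    stop("matrix is already on the log2 scale; refusing to transform twice",
         call. = FALSE)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  if (min(m) < 0)
    stop("linear matrix contains negative values; cannot log-transform",
         call. = FALSE)
  out <- log2(unclass(m) + pseudocount)
  expr_matrix(out, scale = "log2", pseudocount = pseudocount)
}

#' Subset an expression matrix to a gene panel
#'
#' Returns the rows matching `wanted`, in `wanted` order, together with the
#' list of genes that were not found. Matching is case-insensitive with
#' exact-case preference (GEO platforms mix symbol cases). Missing
#' signature genes are reported, never fatal, unless *none* match.
#'
#' @param m an [expr_matrix]
#' @param wanted character vector of gene symbols
#' @return list with elements `matrix` (an [expr_matrix] whose rows are the
#'   found genes in `wanted` order) and `missing` (character vector).
#' @export
subset_genes <- function(m, wanted) {
  assert_expr(m)
  if (length(wanted) == 0L)
    stop("`wanted` gene list is empty", call. = FALSE)
  rn <- rownames(m)
  idx <- match(wanted, rn)                      # exact-case first
  lower_hit <- match(tolower(wanted), tolower(rn))
  idx[is.na(idx)] <- lower_hit[is.na(idx)]
  missing <- wanted[is.na(idx)]
  if (all(is.na(idx)))
    stop("none of the requested genes are present: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  found <- idx[!is.na(idx)]
  out <- unclass(m)[found, , drop = FALSE]
  rownames(out) <- wanted[!is.na(idx)]
  list(matrix = expr_matrix(out, scale = expr_scale(m),
                            pseudocount = attr(m, "pseudocount")),
       missing = missing)
}

#' Read a clinical table with survival endpoints
#'
#' Reads a TSV/CSV table and maps its columns onto the survival data model
#' (`sample_id`, `time`, `event`, covariates). The mapping can be given
#' directly or in a YAML/JSON config with a `columns:` block naming
#' `sample`, `time`, `event` and optionally `covariates:`.
#'
#' @param path clinical table (TSV or CSV; delimiter sniffed from header).
#' @param columns named list/character: which input columns hold `sample`,
#'   `time`, `event`; optional `covariates` character vector.
#' @param config optional YAML/JSON file supplying `columns` instead.
#' @return a `survival_table`: data.frame with `sample_id`, `time`
#'   (non-negative), logical `event`, plus covariate columns.
#' @export
read_clinical <- function(path, columns = NULL, config = NULL) {
  if (!is.null(config)) {
    cfg <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
           else yaml::read_yaml(config)
    columns <- cfg$columns
  }
  if (is.null(columns))
    columns <- list(sample = "sample", time = "time", event = "event")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (f in c("sample", "time", "event"))
    if (!columns[[f]] %in% names(df))
      stop("clinical table lacks mapped column '", columns[[f]],
           "' for field '", f, "'", call. = FALSE)
  covs <- setdiff(unlist(columns[["covariates"]]), NA)
  miss <- setdiff(covs, names(df))
  if (length(miss))
    stop("clinical table lacks covariate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  survival_table(
    sample_id = as.character(df[[columns$sample]]),
    time = as.numeric(df[[columns$time]]),
    event = df[[columns$event]],
    covariates = if (length(covs)) df[covs] else NULL)
}

#' Construct a survival table
#'
#' @param sample_id character ids
#' @param time non-negative follow-up times (one unit per table, e.g. months)
#' @param event event indicator (TRUE/1 = death observed)
#' @param covariates optional data.frame of numeric/binary covariates
#' @return data.frame of class `survival_table`
#' @export
survival_table <- function(sample_id, time, event, covariates = NULL) {
  sample_id <- as.character(sample_id)
  time <- as.numeric(time)
  event <- as.logical(event)
  n <- length(sample_id)
  if (length(time) != n || length(event) != n)
    stop("sample_id, time and event must have equal length", call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicated sample ids in survival table", call. = FALSE)
  if (anyNA(time) || any(time < 0))
    stop("survival times must be non-negative and non-missing", call. = FALSE)
  if (anyNA(event))
    stop("event indicator contains missing values", call. = FALSE)
  df <- data.frame(sample_id = sample_id, time = time, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per sample", call. = FALSE)
    df <- cbind(df, covariates)
  }
  class(df) <- c("survival_table", "data.frame")
  df
}
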