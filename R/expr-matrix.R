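#' Construct an expression matrix
#'
#' The shared substrate of every score in the package: a numeric genes x
#' samples matrix with a declared scale (`"log2"` or `"linear"`). On
#' construction duplicate gene symbols are collapsed to their per-sample
#' mean, rows containing any missing value are dropped (with a warning),
#' and sample identifiers must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row
#'   names are gene symbols; column names are sample identifiers.
#' @param scale `"log2"` or `"linear"`. Microarray and log-TPM data are
#'   `"log2"`; raw counts/TPM are `"linear"`.
#' @param pseudocount the pseudocount under which a log2 matrix was (or
#'   will be) transformed; `log2(pseudocount)` is the smallest value a
#'   log2 matrix may legally contain.
#' @return an object of class `expr_matrix`: a numeric matrix with
#'   attributes `scale` and `pseudocount`.
#' @export
expr_matrix <- function(values, scale = c("log2", "linear"), pseudocount = 1) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix has zero genes or zero samples", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)

  # duplicate gene symbols -> per-sample mean of the duplicate rows
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    warning("collapsed ", length(dups), " duplicated gene symbol(s) ",
            "by per-sample mean: ", paste(dups, collapse = ", "),
            call. = FALSE)
    values <- rowsum(values, group = rownames(values), reorder = FALSE) /
      as.vector(table(rownames(values))[unique(rownames(values))])
  }

  # rows with any missing value are dropped, never imputed
  bad <- rowSums(!is.finite(values)) > 0L
  if (any(bad)) {
    warning("dropped ", sum(bad), " gene row(s) with missing values: ",
            paste(utils::head(rownames(values)[bad], 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", call. = FALSE)
    values <- values[!bad, , drop = FALSE]
  }
  if (nrow(values) == 0L)
    stop("no gene rows left after dropping rows with missing values",
         call. = FALSE)

  if (scale == "log2") {
    floor_val <- log2(pseudocount)
    if (min(values) < floor_val - 1e-8)
      stop("log2 matrix contains values below log2(pseudocount) = ",
           signif(floor_val, 6), call. = FALSE)
  } else if (min(values) < 0) {
    stop("linear-scale matrix contains negative values", call. = FALSE)
  }

  structure(values, scale = scale, pseudocount = pseudocount,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' Scale of an expression matrix
#' @param m an [expr_matrix]
#' @return `"log2"` or `"linear"`
#' @export
expr_scale <- function(m) attr(m, "scale", exact = TRUE)

#' Gene and sample identifiers
#' @param m an [expr_matrix]
#' @return character vector of gene symbols / sample ids
#' @export
gene_ids <- function(m) rownames(m)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m)

assert_expr <- function(m, scale = NULL) {
  if (!inherits(m, "expr_matrix"))
    stop("expected an `expr_matrix` (see read_expression()/expr_matrix())",
         call. = FALSE)
  if (!is.null(scale) && !identical(expr_scale(m), scale))
    stop("expression matrix must be on the ", scale, " scale; it is ",
         expr_scale(m),
         if (scale == "log2") " (use to_log2() first)" else "",
         call. = FALSE)
  invisible(m)
}
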