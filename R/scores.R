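#' Per-sample signature score vector
#'
#' A named numeric vector (names = sample ids) carrying the score name and
#' the panel genes that were used / missing in the cohort.
#'
#' @param values numeric, one score per sample
#' @param sample_ids character ids (same length)
#' @param score_name label, e.g. `"caf_index"`
#' @param genes_used,genes_missing partition of the panel's genes
#' @return object of class `score_vector`
#' @export
score_vector <- function(values, sample_ids, score_name,
                         genes_used = character(), genes_missing = character()) {
  if (length(values) != length(sample_ids))
    stop("one score per sample required", call. = FALSE)
  structure(stats::setNames(as.numeric(values), sample_ids),
            score_name = score_name,
            genes_used = genes_used, genes_missing = genes_missing,
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %s: %d samples (%d genes used, %d missing)\n",
              attr(x, "score_name"), length(x),
              length(attr(x, "genes_used")), length(attr(x, "genes_missing"))))
  print(unclass(stats::setNames(as.numeric(x), names(x))))
  invisible(x)
}

# Shared plumbing: match one role's genes, warn about the missing ones,
# and return their per-sample log2 column sums (0 if no gene matches).
role_sum <- function(m, genes) {
  sub <- tryCatch(subset_genes(m, genes), error = function(e) NULL)
  if (is.null(sub))
    return(list(sums = rep(0, ncol(m)), used = character(), missing = genes))
  vals <- unclass(sub$matrix)
  list(sums = colSums(vals), used = rownames(vals), missing = sub$missing)
}

#' 14-gene EMT score
#'
#' Per sample, the sum of the log2 expression of the panel's mesenchymal
#' genes minus the sum of its epithelial genes. Higher scores indicate a
#' more mesenchymal phenotype. Panel genes absent from the cohort are
#' omitted from their sum and reported in `genes_missing` — mirroring how
#' cohorts that lack a probe (e.g. TWIST2 on some arrays) are handled in
#' practice.
#'
#' @param m a log2-scale [expr_matrix]
#' @param panel a [gene_panel] with mesenchymal and epithelial roles;
#'   default the built-in 14-gene panel.
#' @return a [score_vector]
#' @export
score_emt_salt <- function(m, panel = default_panel("emt_salt14")) {
  assert_expr(m, "log2")
  mes_genes <- panel_genes(panel, "mesenchymal")
  epi_genes <- panel_genes(panel, "epithelial")
  if (!length(mes_genes) || !length(epi_genes))
    stop("EMT panel needs both mesenchymal and epithelial genes",
         call. = FALSE)
  mes <- role_sum(m, mes_genes)
  epi <- role_sum(m, epi_genes)
  used <- c(mes$used, epi$used)
  missing <- c(mes$missing, epi$missing)
  if (!length(used))
    stop("no EMT panel gene present in the expression matrix", call. = FALSE)
  if (length(missing))
    warning("EMT panel gene(s) absent, omitted from the score: ",
            paste(missing, collapse = ", "), call. = FALSE)
  score_vector(mes$sums - epi$sums, sample_ids(m), "emt_salt",
               genes_used = used, genes_missing = missing)
}

#' 4-gene CAF index
#'
#' Per sample, the summed log2 expression of FN1, TGFB2, TGFBR2 and TGFBI
#' — a proxy for the abundance of cancer-associated fibroblasts in a bulk
#' sample. Missing panel genes are omitted with a warning; at least one of
#' the four must be present.
#'
#' @param m a log2-scale [expr_matrix]
#' @param panel a [gene_panel]; default the built-in `caf4` panel
#' @return a [score_vector]
#' @export
score_caf_index <- function(m, panel = default_panel("caf4")) {
  assert_expr(m, "log2")
  genes <- panel_genes(panel)
  r <- role_sum(m, genes)
  if (!length(r$used))
    stop("none of the CAF index genes (", paste(genes, collapse = ", "),
         ") are present in the expression matrix", call. = FALSE)
  if (length(r$missing))
    warning("CAF index gene(s) absent, omitted from the sum: ",
            paste(r$missing, collapse = ", "), call. = FALSE)
  score_vector(r$sums, sample_ids(m), "caf_index",
               genes_used = r$used, genes_missing = r$missing)
}

#' 76-gene CDH1-correlation-weighted EMT score
#'
#' For each panel gene present in the cohort, the weight is its Pearson
#' correlation with CDH1 across the cohort's samples; the score of a
#' sample is the weighted sum of the gene's mean-centered (per gene,
#' across samples) log2 expression. Because CDH1 anchors the weights,
#' positive scores indicate an epithelial and negative scores a
#' mesenchymal phenotype — the opposite sign convention to
#' [score_emt_salt()]. A gene with zero variance across samples has an
#' undefined correlation and receives weight 0 (logged).
#'
#' @param m a log2-scale [expr_matrix] with CDH1 present and >= 2 samples
#' @param panel a [gene_panel]; default the built-in 76-gene panel
#' @return a [score_vector]; attribute `weights` carries the per-gene
#'   weights actually applied.
#' @export
score_76gs <- function(m, panel = default_panel("emt76gs")) {
  assert_expr(m, "log2")
  if (ncol(m) < 2L)
    stop("76GS weights are correlations; need >= 2 samples", call. = FALSE)
  cdh1 <- tryCatch(subset_genes(m, "CDH1"), error = function(e) NULL)
  if (is.null(cdh1))
    stop("CDH1 is absent from the expression matrix; the 76GS weights ",
         "are undefined without it", call. = FALSE)
  cdh1_expr <- as.numeric(unclass(cdh1$matrix)[1L, ])

  sub <- subset_genes(m, panel_genes(panel))
  vals <- unclass(sub$matrix)
  sds <- apply(vals, 1L, stats::sd)
  w <- rep(0, nrow(vals))
  ok <- sds > 0 & stats::sd(cdh1_expr) > 0
  if (any(!ok))
    message("score_76gs: ", sum(!ok), " gene(s) with zero variance got ",
            "weight 0: ", paste(rownames(vals)[!ok], collapse = ", "))
  if (any(ok))
    w[ok] <- apply(vals[ok, , drop = FALSE], 1L, stats::cor, y = cdh1_expr)
  centered <- vals - rowMeans(vals)
  scores <- as.numeric(crossprod(centered, w))
  out <- score_vector(scores, sample_ids(m), "emt_76gs",
                      genes_used = rownames(vals), genes_missing = sub$missing)
  attr(out, "weights") <- stats::setNames(w, rownames(vals))
  out
}

#' Write one or more score vectors as TSV
#'
#' Columns: `sample_id`, then one column per score (named by its
#' `score_name`). All scores must cover the same samples.
#'
#' @param scores a [score_vector] or list of them
#' @param path output file
#' @return `path`, invisibly
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "score_vector")) scores <- list(scores)
  ids <- names(scores[[1L]])
  df <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (s in scores) {
    if (!identical(names(s), ids))
      stop("score vectors cover different samples", call. = FALSE)
    df[[attr(s, "score_name")]] <- as.numeric(s)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
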