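# Small in-code fixtures shared across test files.

# genes x samples matrix with named rows/columns
toy_matrix <- function(genes, samples, values) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples))
}

# write a gene x sample TSV the way read_expression() expects it
write_expr_tsv <- function(values, path, gene_col = "gene") {
  df <- data.frame(g = rownames(values), values, check.names = FALSE)
  names(df)[1] <- gene_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random log2-scale expr_matrix over the default signature genes plus
# background, for score-oracle tests
random_log2_matrix <- function(genes, n_samples, seed) {
  set.seed(seed)
  vals <- toy_matrix(genes, sprintf("smp%02d", seq_len(n_samples)),
                     round(runif(length(genes) * n_samples, 0, 14), 3))
  expr_matrix(vals, scale = "log2")
}

all14 <- function() {
  p <- default_panel("emt_salt14")
  list(mes = panel_genes(p, "mesenchymal"), epi = panel_genes(p, "epithelial"))
}

# independent naive Cox partial log-likelihood (no ties expected):
# the brute-force oracle used against the Newton-Raphson fit
naive_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
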