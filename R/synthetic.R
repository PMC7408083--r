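#' Configuration for the synthetic tumor/stroma-mixture cohort
#'
#' The generator emulates the statistical structure the scoring analysis
#' assumes: each bulk sample is a mixture of one tumor profile and one
#' CAF-like stromal profile with latent stromal fraction `f ~ Beta(a, b)`;
#' CAF-index genes are strongly stroma-enriched, mesenchymal EMT genes
#' moderately so, epithelial genes stroma-depleted, background genes
#' indifferent; the hazard of death increases with `f`; and an exome-style
#' "tumor content" equals `1 - f` plus noise. A tumor-intrinsic EMT latent
#' state (independent of survival) shifts the EMT-panel genes of the tumor
#' compartment, reproducing the confounding that makes a bulk EMT score an
#' imperfect stand-in for stromal abundance.
#'
#' @param n_samples cohort size
#' @param n_background_genes genes with no tumor/stroma differential
#' @param f_alpha,f_beta Beta prior of the stromal fraction (defaults
#'   loosely anchored to xenograft stromal fractions of roughly 10-35%)
#' @param baseline_expr linear-scale mean expression of every gene's
#'   tumor profile
#' @param caf_enrichment stroma/tumor expression ratio of CAF-index genes
#' @param mes_enrichment same for (non-CAF) mesenchymal EMT genes
#' @param epi_factor stroma/tumor ratio of epithelial genes (< 1)
#' @param tumor_emt_sd sd (log2 units) of the tumor-intrinsic EMT latent
#'   state, anchored to the 2-22x fold-change scale EMT genes show across
#'   cell lines; 0 switches the confounder off
#' @param noise_sd sdlog of the multiplicative lognormal noise (additive
#'   Gaussian on the log2 scale, microarray-like)
#' @param lambda0 baseline hazard (events per time unit, e.g. per month)
#' @param beta_f log-hazard coefficient on the stromal fraction
#' @param weibull_shape shape of the proportional-hazards Weibull
#'   baseline; 1 = exponential
#' @param admin_time administrative censoring time
#' @param dropout_rate probability of uniform early dropout
#' @param purity_noise_sd sd of the Gaussian noise on `1 - f`
#' @param seed integer seed; the cohort is fully reproducible from it
#' @return object of class `synthetic_cohort_config`
#' @export
synthetic_cohort_config <- function(n_samples = 200L,
                                    n_background_genes = 200L,
                                    f_alpha = 2, f_beta = 6,
                                    baseline_expr = 100,
                                    caf_enrichment = 8,
                                    mes_enrichment = 3,
                                    epi_factor = 0.2,
                                    tumor_emt_sd = 1,
                                    noise_sd = 0.3,
                                    lambda0 = 0.01,
                                    beta_f = 3,
                                    weibull_shape = 1,
                                    admin_time = 60,
                                    dropout_rate = 0.1,
                                    purity_noise_sd = 0.05,
                                    seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_background_genes = as.integer(n_background_genes),
              f_alpha = f_alpha, f_beta = f_beta,
              baseline_expr = baseline_expr,
              caf_enrichment = caf_enrichment,
              mes_enrichment = mes_enrichment,
              epi_factor = epi_factor,
              tumor_emt_sd = tumor_emt_sd,
              noise_sd = noise_sd,
              lambda0 = lambda0, beta_f = beta_f,
              weibull_shape = weibull_shape,
              admin_time = admin_time, dropout_rate = dropout_rate,
              purity_noise_sd = purity_noise_sd,
              seed = as.integer(seed))
  problems <- character()
  if (cfg$n_samples < 2L) problems <- c(problems, "n_samples must be >= 2")
  if (cfg$n_background_genes < 0L)
    problems <- c(problems, "n_background_genes must be >= 0")
  if (cfg$f_alpha <= 0 || cfg$f_beta <= 0)
    problems <- c(problems, "Beta parameters f_alpha, f_beta must be > 0")
  if (cfg$baseline_expr <= 0)
    problems <- c(problems, "baseline_expr must be > 0")
  if (cfg$caf_enrichment <= 0 || cfg$mes_enrichment <= 0 ||
      cfg$epi_factor <= 0)
    problems <- c(problems, "enrichment factors must be > 0")
  if (cfg$noise_sd < 0) problems <- c(problems, "noise_sd must be >= 0")
  if (cfg$tumor_emt_sd < 0)
    problems <- c(problems, "tumor_emt_sd must be >= 0")
  if (cfg$lambda0 <= 0) problems <- c(problems, "lambda0 must be > 0")
  if (cfg$weibull_shape <= 0)
    problems <- c(problems, "weibull_shape must be > 0")
  if (cfg$admin_time <= 0) problems <- c(problems, "admin_time must be > 0")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    problems <- c(problems, "dropout_rate must be in [0, 1]")
  if (cfg$purity_noise_sd < 0)
    problems <- c(problems, "purity_noise_sd must be >= 0")
  if (length(problems))
    stop("invalid synthetic cohort config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "synthetic_cohort_config")
}

#' Generate a synthetic tumor/stroma-mixture cohort
#'
#' For sample `i`: stromal fraction `f_i ~ Beta(a, b)` (or the hand-set
#' `f` override); for gene `g` the linear expression is
#' `x_gi = ((1 - f_i) * T_gi + f_i * S_g) * eps`, with `eps` lognormal;
#' the tumor profile `T_gi` of EMT-panel genes is modulated by the
#' sample's tumor-intrinsic EMT state; event times follow a
#' proportional-hazards Weibull (default exponential) with log-hazard
#' `beta_f * f_i`; censoring is administrative plus uniform dropout;
#' purity is `1 - f_i` plus Gaussian noise, clipped to [0, 1]. Draws are
#' ordered deterministically (f, tumor EMT state, expression noise,
#' survival, censoring, purity) from the single seed.
#'
#' @param config a [synthetic_cohort_config]
#' @param f optional hand-set stromal fractions (length `n_samples`),
#'   bypassing the Beta draw — useful for closed-form checks
#' @return object of class `synthetic_cohort`: `expression` (linear-scale
#'   [expr_matrix]), `clinical` ([survival_table]), `truth` (data.frame
#'   with `sample_id`, `f`, `event_time_true`, `purity`), `config`
#' @export
generate_cohort <- function(config = synthetic_cohort_config(), f = NULL) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  n <- config$n_samples
  set.seed(config$seed)

  ids <- sprintf("S%04d", seq_len(n))
  mes_genes <- panel_genes(default_panel("emt_salt14"), "mesenchymal")
  epi_genes <- panel_genes(default_panel("emt_salt14"), "epithelial")
  caf_genes <- panel_genes(default_panel("caf4"))
  sig_genes <- union(union(mes_genes, epi_genes), caf_genes)
  bg_genes <- if (config$n_background_genes > 0L)
    sprintf("BG%04d", seq_len(config$n_background_genes)) else character()
  genes <- c(sig_genes, bg_genes)

  # stroma/tumor ratio per gene; CAF membership wins for FN1
  ratio <- stats::setNames(rep(1, length(genes)), genes)
  ratio[mes_genes] <- config$mes_enrichment
  ratio[epi_genes] <- config$epi_factor
  ratio[caf_genes] <- config$caf_enrichment

  # draw order is part of the reproducibility contract
  if (is.null(f)) {
    f <- stats::rbeta(n, config$f_alpha, config$f_beta)
    # keep f strictly inside (0,1); Beta draws of 0/1 only occur at
    # degenerate parameters but the invariant is explicit
    f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
  } else {
    if (length(f) != n) stop("hand-set f must have length n_samples",
                             call. = FALSE)
    f <- pmin(pmax(as.numeric(f), 0), 1)
  }
  u <- stats::rnorm(n, 0, config$tumor_emt_sd)    # tumor-intrinsic EMT state
  noise <- matrix(stats::rlnorm(length(genes) * n, 0, config$noise_sd),
                  nrow = length(genes))

  T0 <- config$baseline_expr
  S <- ratio * T0
  vals <- matrix(0, nrow = length(genes), ncol = n,
                 dimnames = list(genes, ids))
  emt_dir <- stats::setNames(rep(0, length(genes)), genes)
  emt_dir[mes_genes] <- 1
  emt_dir[epi_genes] <- -1
  for (i in seq_len(n)) {
    Tg <- T0 * 2^(emt_dir * u[i])               # EMT state shifts tumor profile
    vals[, i] <- ((1 - f[i]) * Tg + f[i] * S) * noise[, i]
  }

  # proportional-hazards Weibull: H(t) = (lambda0 t)^k * exp(beta_f f)
  uu <- stats::runif(n)
  k <- config$weibull_shape
  event_time <- (-log(uu) / exp(config$beta_f * f))^(1 / k) / config$lambda0
  drop_out <- stats::runif(n) < config$dropout_rate
  drop_time <- stats::runif(n, 0, config$admin_time)
  cens_time <- ifelse(drop_out, pmin(drop_time, config$admin_time),
                      config$admin_time)
  obs_time <- pmin(event_time, cens_time)
  event <- event_time <= cens_time
  purity <- pmin(pmax(1 - f + stats::rnorm(n, 0, config$purity_noise_sd),
                      0), 1)

  structure(list(
    expression = expr_matrix(vals, scale = "linear"),
    clinical = survival_table(ids, obs_time, event),
    truth = data.frame(sample_id = ids, f = f, tumor_emt_state = u,
                       event_time_true = event_time, purity = purity,
                       stringsAsFactors = FALSE),
    config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> n = %d, %d genes, %d events, ",
                     "mean stromal fraction %.3f (seed %d)\n"),
              x$config$n_samples, nrow(x$expression),
              sum(x$clinical$event), mean(x$truth$f), x$config$seed))
  invisible(x)
}

#' Ground-truth recovery metrics for a synthetic cohort
#'
#' Computes (i) the Spearman correlation between the CAF index (on log2
#' data) and the true stromal fraction, (ii) the Cox hazard ratio of the
#' median-dichotomized CAF index next to the truth-implied hazard ratio
#' `exp(beta_f * (mean f in high - mean f in low))`, and (iii) the sign
#' of the Pearson correlation between the CAF index and the noisy purity.
#'
#' @param cohort a [synthetic_cohort][generate_cohort]
#' @return list: `spearman_caf_f`, `hr_caf_dichotomized`,
#'   `hr_truth_implied`, `purity_cor`, `purity_cor_sign`
#' @export
recovery_check <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort") || is.null(cohort$truth))
    stop("cohort does not carry ground truth", call. = FALSE)
  logm <- to_log2(cohort$expression)
  caf <- score_caf_index(logm)
  f <- stats::setNames(cohort$truth$f, cohort$truth$sample_id)

  sp <- stats::cor(as.numeric(caf), f[names(caf)], method = "spearman")

  d <- dichotomize(caf)
  hi <- d$labels == "high"
  st <- cohort$clinical
  st$caf_high <- as.numeric(hi[match(st$sample_id, names(d$labels))])
  fit <- cox_fit(st, "caf_high")
  hr_truth <- exp(cohort$config$beta_f *
                    (mean(f[names(d$labels)[hi]]) -
                     mean(f[names(d$labels)[!hi]])))

  pc <- correlate_purity(caf, stats::setNames(cohort$truth$purity,
                                              cohort$truth$sample_id))
  list(spearman_caf_f = sp,
       hr_caf_dichotomized = fit$terms$hr[1L],
       hr_truth_implied = hr_truth,
       purity_cor = pc$r,
       purity_cor_sign = sign(pc$r))
}

#' Write a synthetic cohort to disk
#'
#' Writes `expression.tsv` (linear scale), `clinical.tsv` and `truth.tsv`
#' into `dir`.
#'
#' @param cohort a [synthetic_cohort][generate_cohort]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(as.data.frame(cohort$clinical),
                     file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
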