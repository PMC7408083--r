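#' Dichotomize a score vector at the cohort median
#'
#' `high` means strictly above the threshold; ties at the threshold go to
#' `low`. With the median rule the threshold is the sample median of the
#' scores. Degenerate splits (all scores equal, or a split leaving one
#' group empty) are errors: a dichotomized survival analysis is undefined
#' without two groups.
#'
#' @param scores a [score_vector] (>= 2 samples)
#' @param rule splitting rule; only `"median"` is defined
#' @return object of class `dichotomy`: `threshold`, `labels` (named
#'   factor high/low), `rule`, `n_high`, `n_low`
#' @export
dichotomize <- function(scores, rule = c("median")) {
  rule <- match.arg(rule)
  if (length(scores) < 2L)
    stop("need >= 2 samples to dichotomize", call. = FALSE)
  threshold <- stats::median(as.numeric(scores))
  labels <- factor(ifelse(as.numeric(scores) > threshold, "high", "low"),
                   levels = c("low", "high"))
  names(labels) <- names(scores)
  if (length(unique(labels)) < 2L)
    stop("degenerate split: all samples fall on one side of the median",
         call. = FALSE)
  structure(list(threshold = threshold, labels = labels, rule = rule,
                 n_high = sum(labels == "high"),
                 n_low = sum(labels == "low")),
            class = "dichotomy")
}

#' @export
print.dichotomy <- function(x, ...) {
  cat(sprintf("<dichotomy> rule = %s, threshold = %.4g: %d high / %d low\n",
              x$rule, x$threshold, x$n_high, x$n_low))
  invisible(x)
}

#' Pearson correlation of a score with tumor content
#'
#' Pairs samples by id, drops pairs with missing purity (counted in
#' `n_dropped`), and returns the Pearson correlation with its two-sided
#' t-test p-value. Bulk scores that track stromal abundance are expected
#' to correlate negatively with tumor content (purity), which is the
#' complement of the stromal fraction.
#'
#' @param scores a [score_vector]
#' @param purity named numeric vector of per-sample tumor-content values
#' @return list: `r`, `p_value`, `n`, `n_dropped`
#' @export
correlate_purity <- function(scores, purity) {
  common <- intersect(names(scores), names(purity))
  s <- as.numeric(scores[common])
  p <- as.numeric(purity[common])
  keep <- is.finite(s) & is.finite(p)
  n_dropped <- (length(scores) - sum(keep))
  s <- s[keep]; p <- p[keep]
  if (length(s) < 3L)
    stop("need >= 3 paired, non-missing observations", call. = FALSE)
  if (stats::sd(s) == 0 || stats::sd(p) == 0)
    stop("zero variance in scores or purity; correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(s, p, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(s),
       n_dropped = n_dropped)
}

#' Per-group five-number summary of a score
#'
#' Summaries (n, min, q1, median, q3, max) per group, sorted by median
#' descending — the ranking view behind "which primary site has the
#' highest index" comparisons. Samples without a score are dropped from
#' their group with a warning; groups left empty are dropped.
#'
#' @param scores a [score_vector]
#' @param group named character/factor of per-sample group labels
#' @return data.frame sorted by median descending
#' @export
groupwise_index_summary <- function(scores, group) {
  if (is.null(names(group)))
    stop("`group` must be named by sample id", call. = FALSE)
  common <- intersect(names(scores), names(group))
  if (length(common) < length(group))
    warning("dropped ", length(group) - length(common),
            " sample(s) without a score", call. = FALSE)
  g <- as.character(group[common])
  s <- as.numeric(scores[common])
  rows <- lapply(split(s, g), function(v)
    data.frame(n = length(v), min = min(v),
               q1 = unname(stats::quantile(v, 0.25)),
               median = stats::median(v),
               q3 = unname(stats::quantile(v, 0.75)), max = max(v)))
  out <- do.call(rbind, rows)
  out <- data.frame(group = names(rows), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$median), , drop = FALSE]
}

#' End-to-end EMT-score vs CAF-index prognostic comparison
#'
#' The package's headline analysis: on one cohort, compute the 14-gene
#' EMT score and the 4-gene CAF index (optionally also the 76-gene
#' CDH1-weighted score), dichotomize each at the cohort median, run
#' Kaplan-Meier and log-rank per score, fit a univariate Cox model per
#' clinical covariate and per dichotomized score, and fit one
#' multivariate Cox model containing all of them jointly. Exclusions
#' (e.g. treatment-related deaths) are applied once, up front, so the
#' same sample set underlies every sub-analysis. The result is
#' deterministic given its inputs.
#'
#' @param m a log2-scale [expr_matrix]
#' @param surv a [survival_table]; joined to `m` by sample id
#' @param clinical_covariates character: covariate columns of `surv` to
#'   carry into the Cox models (may be empty)
#' @param exclusions sample ids to drop before any analysis
#' @param with_76gs also compute the 76-gene score
#' @param continuous_scores enter scores into the Cox models as
#'   continuous values instead of the default high/low indicator
#' @param panels named list overriding the default gene panels; entries
#'   `emt_salt`, `caf`, `gs76`
#' @return object of class `comparison_report`: per-score blocks
#'   (`scores`, `dichotomy`, `km_high`, `km_low`, `logrank`), the
#'   univariate Cox table, the multivariate [cox_fit], `n`, `n_events`,
#'   `exclusions`
#' @export
run_comparison <- function(m, surv, clinical_covariates = character(),
                           exclusions = character(), with_76gs = FALSE,
                           continuous_scores = FALSE, panels = list()) {
  assert_expr(m, "log2")
  if (!inherits(surv, "survival_table"))
    stop("`surv` must be a survival_table", call. = FALSE)
  bad_excl <- setdiff(exclusions, c(sample_ids(m), surv$sample_id))
  if (length(bad_excl))
    stop("exclusions not found in the cohort: ",
         paste(bad_excl, collapse = ", "), call. = FALSE)
  miss_cov <- setdiff(clinical_covariates, names(surv))
  if (length(miss_cov))
    stop("clinical covariate column(s) missing: ",
         paste(miss_cov, collapse = ", "), call. = FALSE)

  keep <- setdiff(intersect(sample_ids(m), surv$sample_id), exclusions)
  if (length(keep) < 4L)
    stop("fewer than 4 joinable samples after exclusions", call. = FALSE)
  mm <- expr_matrix(unclass(m)[, keep, drop = FALSE], scale = "log2",
                    pseudocount = attr(m, "pseudocount"))
  st <- surv[match(keep, surv$sample_id), , drop = FALSE]
  if (sum(st$event) < 2L)
    stop("fewer than 2 events after exclusions", call. = FALSE)

  score_fns <- list(
    emt_salt = function() score_emt_salt(mm, panel = panels$emt_salt %||%
                                           default_panel("emt_salt14")),
    caf_index = function() score_caf_index(mm, panel = panels$caf %||%
                                             default_panel("caf4")))
  if (with_76gs)
    score_fns$emt_76gs <- function() score_76gs(mm, panel = panels$gs76 %||%
                                                  default_panel("emt76gs"))

  per_score <- lapply(score_fns, function(f) {
    sc <- f()
    d <- dichotomize(sc)
    hi <- d$labels == "high"
    list(scores = sc,
         dichotomy = d,
         km_high = km_estimate(st$time[hi], st$event[hi]),
         km_low = km_estimate(st$time[!hi], st$event[!hi]),
         logrank = logrank_test(st$time, st$event, d$labels))
  })

  # Cox covariates: clinical columns plus one column per score
  st_cox <- st
  for (nm in names(per_score)) {
    st_cox[[nm]] <- if (continuous_scores)
      as.numeric(per_score[[nm]]$scores)
    else
      as.numeric(per_score[[nm]]$dichotomy$labels == "high")
  }
  cox_terms <- c(clinical_covariates, names(per_score))
  uni <- do.call(rbind, lapply(cox_terms, function(tm) {
    fit <- cox_fit(st_cox, tm)
    cbind(fit$terms, data.frame(n = fit$n, n_events = fit$n_events))
  }))
  multi <- cox_fit(st_cox, cox_terms)

  structure(list(per_score = per_score, univariate = uni,
                 multivariate = multi, n = length(keep),
                 n_events = sum(st$event), exclusions = exclusions,
                 continuous_scores = continuous_scores),
            class = "comparison_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> n = %d (%d events), %d exclusion(s)\n",
              x$n, x$n_events, length(x$exclusions)))
  for (nm in names(x$per_score)) {
    lr <- x$per_score[[nm]]$logrank
    cat(sprintf("  %-10s log-rank chi-square = %.4g, p = %.4g\n",
                nm, lr$statistic, lr$p_value))
  }
  cat("multivariate Cox:\n")
  print(x$multivariate)
  invisible(x)
}

#' Write a comparison report bundle
#'
#' Writes `report.json` (machine-readable summary), `forest.tsv`
#' (univariate and multivariate Cox terms: the data behind a forest
#' plot), `logrank.tsv`, and one `km_<score>_<arm>.tsv` per score arm.
#'
#' @param report a [comparison_report][run_comparison]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  forest <- rbind(
    cbind(model = "univariate",
          report$univariate[, c("term", "beta", "hr", "ci_low", "ci_high",
                                "p_wald")],
          n = report$univariate$n, events = report$univariate$n_events),
    cbind(model = "multivariate",
          report$multivariate$terms[, c("term", "beta", "hr", "ci_low",
                                        "ci_high", "p_wald")],
          n = report$multivariate$n, events = report$multivariate$n_events))
  utils::write.table(forest, file.path(dir, "forest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  lr <- do.call(rbind, lapply(names(report$per_score), function(nm) {
    l <- report$per_score[[nm]]$logrank
    data.frame(score = nm, statistic = l$statistic, p_value = l$p_value,
               n_high = l$n_per_group[["high"]],
               n_low = l$n_per_group[["low"]])
  }))
  utils::write.table(lr, file.path(dir, "logrank.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  for (nm in names(report$per_score)) {
    write_km(report$per_score[[nm]]$km_high,
             file.path(dir, paste0("km_", nm, "_high.tsv")))
    write_km(report$per_score[[nm]]$km_low,
             file.path(dir, paste0("km_", nm, "_low.tsv")))
  }
  summary <- list(
    n = report$n, n_events = report$n_events,
    exclusions = report$exclusions,
    logrank = stats::setNames(lapply(report$per_score, function(b)
      list(statistic = b$logrank$statistic, p = b$logrank$p_value)),
      names(report$per_score)),
    multivariate = report$multivariate$terms)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
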