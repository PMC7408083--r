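# Partial log-likelihood, gradient and observed information for the Cox
# model, with Efron or Breslow handling of tied event times. Dimensions
# are small (a handful of covariates), so the dense loop over distinct
# event times is the clearest correct implementation.
cox_loglik_parts <- function(beta, X, time, event,
                             ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  et <- sort(unique(time[event]))

  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in et) {
    risk <- time >= t
    dead <- time == t & event
    d <- sum(dead)
    sR <- sum(w[risk])
    xR <- colSums(X[risk, , drop = FALSE] * w[risk])
    xxR <- crossprod(X[risk, , drop = FALSE] * sqrt(w[risk]))
    ll <- ll + sum(eta[dead])
    grad <- grad + colSums(X[dead, , drop = FALSE])
    if (ties == "breslow") {
      frac <- rep(0, d)
    } else {
      frac <- (seq_len(d) - 1) / d
    }
    sD <- sum(w[dead])
    xD <- colSums(X[dead, , drop = FALSE] * w[dead])
    xxD <- crossprod(X[dead, , drop = FALSE] * sqrt(w[dead]))
    for (r in seq_len(d)) {
      f <- frac[r]
      denom <- sR - f * sD
      mu <- (xR - f * xD) / denom
      ll <- ll - log(denom)
      grad <- grad - mu
      info <- info + (xxR - f * xxD) / denom - tcrossprod(mu)
    }
  }
  list(loglik = ll, gradient = grad, information = info)
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the partial likelihood by Newton-Raphson from \eqn{\beta = 0}
#' with step-halving, using the Efron approximation for tied event times
#' (the convention of mainstream survival software; Breslow available).
#' Standard errors come from the inverse observed information; confidence
#' intervals and p-values are Wald, reported on the hazard-ratio scale.
#'
#' @param surv a [survival_table] (needs >= 1 event)
#' @param covariates character: covariate column names in `surv`
#' @param ties `"efron"` (default) or `"breslow"`
#' @param max_iter maximum Newton iterations
#' @param tol convergence tolerance on the gradient max-norm
#' @return object of class `cox_fit`: `terms` data.frame (term, beta, se,
#'   hr, ci_low, ci_high, p_wald), `loglik`, `loglik_null`, `n`,
#'   `n_events`, `converged`, `iterations`.
#' @export
cox_fit <- function(surv, covariates, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  if (!inherits(surv, "survival_table"))
    stop("`surv` must be a survival_table", call. = FALSE)
  if (!any(surv$event))
    stop("no events in the survival table; Cox model undefined",
         call. = FALSE)
  miss <- setdiff(covariates, names(surv))
  if (length(miss))
    stop("covariate column(s) absent from the survival table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(as.data.frame(lapply(surv[covariates], as.numeric)))
  colnames(X) <- covariates
  if (anyNA(X))
    stop("covariates contain missing values", call. = FALSE)
  const <- apply(X, 2L, function(col) stats::sd(col) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(covariates[const], collapse = ", "),
         call. = FALSE)

  time <- surv$time
  event <- surv$event
  p <- ncol(X)
  beta <- numeric(p)
  parts <- cox_loglik_parts(beta, X, time, event, ties)
  loglik_null <- parts$loglik
  converged <- FALSE
  iter <- 0L
  separation <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$information, parts$gradient),
                     error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: never accept a decrease in the partial likelihood
    halve <- 0L
    repeat {
      cand <- beta + step / 2^halve
      cand_parts <- cox_loglik_parts(cand, X, time, event, ties)
      if (is.finite(cand_parts$loglik) &&
          cand_parts$loglik >= parts$loglik - 1e-12) break
      halve <- halve + 1L
      if (halve > 30L) break
    }
    beta <- cand
    parts <- cand_parts
    if (max(abs(beta)) > 15) { separation <- TRUE; break }
    if (max(abs(parts$gradient)) < tol) { converged <- TRUE; break }
  }
  if (separation)
    warning("diverging coefficient (|beta| > 15): monotone partial ",
            "likelihood, likely perfect separation", call. = FALSE)
  if (!converged && !separation)
    warning("Cox Newton-Raphson did not converge in ", max_iter,
            " iterations", call. = FALSE)

  vcov <- tryCatch(solve(parts$information), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- beta / se
  terms <- data.frame(
    term = covariates,
    beta = beta,
    se = se,
    hr = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_wald = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE)
  structure(list(terms = terms, loglik = parts$loglik,
                 loglik_null = loglik_null, vcov = vcov,
                 n = nrow(surv), n_events = sum(event),
                 converged = converged, separation = separation,
                 iterations = iter, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, %s (%d iter)\n",
              x$n, x$n_events, x$ties,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  t <- x$terms
  t[-1L] <- lapply(t[-1L], signif, digits = 4)
  print(t, row.names = FALSE)
  invisible(x)
}

#' Cox score test at beta = 0
#'
#' The score statistic \eqn{U(0)^\top I(0)^{-1} U(0)}. For a single
#' binary covariate with Breslow tie handling this equals the two-group
#' log-rank chi-square — the classical equivalence used here as an
#' internal consistency check between the two procedures.
#'
#' @inheritParams cox_fit
#' @return list with `statistic` (chi-square, df = #covariates) and
#'   `p_value`
#' @export
cox_score_test <- function(surv, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(as.data.frame(lapply(surv[covariates], as.numeric)))
  parts <- cox_loglik_parts(numeric(ncol(X)), X, surv$time, surv$event, ties)
  stat <- drop(crossprod(parts$gradient,
                         solve(parts$information, parts$gradient)))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = ncol(X), lower.tail = FALSE))
}

#' Gene-wise univariate Cox screen
#'
#' For each gene, dichotomizes its expression at the cohort median
#' (high = above the median; see [dichotomize()]) and fits a univariate
#' Cox model of overall survival on the high/low indicator. Genes absent
#' from the matrix, or whose expression is constant, yield an NA row with
#' a warning instead of failing the screen. Rows are sorted by p-value,
#' and an `hr_gt_1` flag supports selection rules that require an adverse
#' direction of effect.
#'
#' @param m a log2-scale [expr_matrix]
#' @param surv a [survival_table]; joined to `m` by sample id
#' @param genes character vector of gene symbols to screen
#' @param dichotomized fit on the median-split indicator (default) or on
#'   the continuous log2 expression
#' @return data.frame: gene, n, n_events, beta, se, hr, ci_low, ci_high,
#'   p_wald, hr_gt_1; sorted by p-value (NA rows last)
#' @export
cox_univariate_screen <- function(m, surv, genes, dichotomized = TRUE) {
  assert_expr(m, "log2")
  common <- intersect(sample_ids(m), surv$sample_id)
  if (length(common) < 2L)
    stop("expression matrix and survival table share < 2 samples",
         call. = FALSE)
  surv <- surv[match(common, surv$sample_id), , drop = FALSE]

  na_row <- function(g) data.frame(
    gene = g, n = NA_integer_, n_events = NA_integer_, beta = NA_real_,
    se = NA_real_, hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_wald = NA_real_, hr_gt_1 = NA, stringsAsFactors = FALSE)

  rows <- lapply(genes, function(g) {
    sub <- tryCatch(subset_genes(m, g), error = function(e) NULL)
    if (is.null(sub)) {
      warning("gene absent from expression matrix, screen row is NA: ", g,
              call. = FALSE)
      return(na_row(g))
    }
    x <- as.numeric(unclass(sub$matrix)[1L, match(common, sample_ids(m))])
    cov_val <- if (dichotomized) {
      d <- tryCatch(dichotomize(score_vector(x, common, g)),
                    error = function(e) NULL)
      if (is.null(d)) NULL else as.numeric(d$labels == "high")
    } else x
    if (is.null(cov_val) || stats::sd(cov_val) == 0) {
      warning("constant (or degenerate split) expression, screen row is ",
              "NA: ", g, call. = FALSE)
      return(na_row(g))
    }
    st <- surv
    st[[g]] <- cov_val
    fit <- cox_fit(st, g)
    cbind(data.frame(gene = g, n = fit$n, n_events = fit$n_events,
                     stringsAsFactors = FALSE),
          fit$terms[, c("beta", "se", "hr", "ci_low", "ci_high", "p_wald")],
          data.frame(hr_gt_1 = fit$terms$hr > 1))
  })
  out <- do.call(rbind, rows)
  out[order(out$p_wald, na.last = TRUE), , drop = FALSE]
}
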