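#' Kaplan-Meier product-limit estimator
#'
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct
#' observed event times \eqn{t_i}, with \eqn{d_i} deaths and \eqn{n_i}
#' subjects at risk at \eqn{t_i}. A subject censored exactly at an event
#' time is counted at risk for that event (standard convention); censored
#' subjects leave the risk set immediately after their time. With no
#' events the curve is identically 1.
#'
#' @param time non-negative follow-up times
#' @param event event flags (TRUE/1 = death observed)
#' @return object of class `km_curve`: list with `event_times`, `survival`
#'   (\eqn{\hat S} at each event time), `at_risk`, `events`, `n`.
#' @export
km_estimate <- function(time, event) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) == 0L)
    stop("empty survival input", call. = FALSE)
  if (length(time) != length(event))
    stop("time and event lengths differ", call. = FALSE)
  if (anyNA(time) || any(time < 0))
    stop("times must be non-negative and non-missing", call. = FALSE)

  et <- sort(unique(time[event]))
  n_at_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  d <- vapply(et, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - d / n_at_risk)
  structure(list(event_times = et, survival = surv, at_risk = n_at_risk,
                 events = d, n = length(time)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Step-function evaluation: \eqn{\hat S(t)} is 1 before the first event
#' time and right-continuous thereafter.
#'
#' @param curve a [km_curve][km_estimate]
#' @param t times at which to evaluate
#' @return numeric vector of survival probabilities
#' @export
km_survival <- function(curve, t) {
  if (length(curve$event_times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$event_times)
  c(1, curve$survival)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d events at %d distinct times\n",
              x$n, sum(x$events), length(x$event_times)))
  if (length(x$event_times))
    print(data.frame(time = x$event_times, n_risk = x$at_risk,
                     events = x$events, survival = signif(x$survival, 4)))
  invisible(x)
}

#' Write a Kaplan-Meier curve as TSV
#' @param curve a [km_curve][km_estimate]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_km <- function(curve, path) {
  df <- data.frame(time = curve$event_times, n_risk = curve$at_risk,
                   events = curve$events, survival = curve$survival)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Two-group log-rank test
#'
#' At each distinct pooled event time \eqn{t_i} with \eqn{d_i} total
#' deaths, \eqn{n_i} at risk and \eqn{n_{1i}} at risk in group 1, the
#' observed group-1 deaths \eqn{d_{1i}} are compared with their
#' hypergeometric expectation \eqn{E_{1i} = d_i n_{1i}/n_i}; the statistic
#' \deqn{\chi^2 = \left(\sum_i (d_{1i} - E_{1i})\right)^2 / \sum_i V_i,
#'   \quad V_i = d_i \frac{n_{1i}}{n_i}\left(1-\frac{n_{1i}}{n_i}\right)
#'   \frac{n_i - d_i}{n_i - 1}}
#' is chi-square with 1 df under the null of equal hazards.
#'
#' @param time non-negative follow-up times
#' @param event event flags
#' @param group binary labels (exactly two levels, both non-empty)
#' @return object of class `logrank_result`: `statistic`, `p_value`,
#'   `n_per_group`, `events_per_group`, `observed_minus_expected`.
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.logical(event)
  group <- as.factor(group)
  lv <- levels(droplevels(group))
  if (length(lv) != 2L)
    stop("log-rank test needs exactly two non-empty groups; got ",
         length(lv), call. = FALSE)
  g1 <- group == lv[1L]

  if (!any(event)) {
    warning("no events in either group; log-rank statistic is 0",
            call. = FALSE)
    stat <- 0
  } else {
    et <- sort(unique(time[event]))
    o_minus_e <- 0
    v <- 0
    for (t in et) {
      at_risk <- time >= t
      n_i <- sum(at_risk)
      n1_i <- sum(at_risk & g1)
      d_i <- sum(time == t & event)
      d1_i <- sum(time == t & event & g1)
      o_minus_e <- o_minus_e + (d1_i - d_i * n1_i / n_i)
      if (n_i > 1L)
        v <- v + d_i * (n1_i / n_i) * (1 - n1_i / n_i) * (n_i - d_i) / (n_i - 1)
    }
    stat <- if (v > 0) o_minus_e^2 / v else 0
  }
  structure(list(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    n_per_group = stats::setNames(c(sum(g1), sum(!g1)), lv),
    events_per_group = stats::setNames(c(sum(event & g1), sum(event & !g1)), lv)),
    class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  n = %s; events = %s\n",
              paste(sprintf("%s:%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", "),
              paste(sprintf("%s:%d", names(x$events_per_group),
                            x$events_per_group), collapse = ", ")))
  invisible(x)
}
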