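# Kaplan-Meier product-limit estimator ---------------------------------------

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood standard errors. At tied times,
#' deaths are processed before censorings (both leave the risk set after
#' that time). The standard error is set to 0 once the estimate reaches 0,
#' where the Greenwood sum degenerates.
#'
#' @param time follow-up times (non-negative, finite).
#' @param event logical or 0/1 event indicator.
#' @return object of class `km_curve`: a data.frame with one row per
#'   distinct observed time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `se`), plus attribute `n`.
#' @examples
#' kaplan_meier(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' @export
kaplan_meier <- function(time, event) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) < 1) stop("need at least one observation", call. = FALSE)
  if (length(event) != length(time)) {
    stop("time and event lengths differ", call. = FALSE)
  }
  if (anyNA(time) || anyNA(event) || any(time < 0) || any(!is.finite(time))) {
    stop("times must be non-negative and finite, indicators non-missing",
         call. = FALSE)
  }
  n <- length(time)
  tt <- sort(unique(time))
  d <- vapply(tt, function(t) sum(time == t & event), numeric(1))
  cns <- vapply(tt, function(t) sum(time == t & !event), numeric(1))
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  gw_terms <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), 0)
  se <- surv * sqrt(cumsum(gw_terms))
  se[surv == 0] <- 0
  out <- data.frame(time = tt, n_risk = n_risk, n_event = d, n_censor = cns,
                    surv = surv, se = se)
  structure(out, class = c("km_curve", "data.frame"), n = n)
}

step_value <- function(times, values, t, before = 1) {
  idx <- findInterval(t, times)
  if (idx == 0) before else values[idx]
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step-function evaluation (default 60 months = 5 years)
#' with a plain-scale Greenwood confidence interval. Evaluation beyond the
#' last observed time returns the last value with an extrapolation warning.
#'
#' @param curve a `km_curve`.
#' @param t evaluation time in months (default 60).
#' @param level confidence level.
#' @param clamp clamp the interval to \[0, 1\] (default TRUE).
#' @return list with `time`, `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
survival_at <- function(curve, t = 60, level = 0.95, clamp = TRUE) {
  stopifnot(inherits(curve, "km_curve"), is.numeric(t), length(t) == 1, t >= 0)
  if (t > max(curve$time)) {
    warning("evaluation time ", t, " beyond last observed time ",
            max(curve$time), "; returning last value", call. = FALSE)
  }
  est <- step_value(curve$time, curve$surv, t, before = 1)
  se <- step_value(curve$time, curve$se, t, before = 0)
  half <- z_quantile(level) * se
  lo <- est - half
  hi <- est + half
  if (clamp) {
    lo <- max(0, lo)
    hi <- min(1, hi)
  }
  list(time = t, estimate = est, se = se, ci_low = lo, ci_high = hi)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", attr(x, "n"), "subjects,",
      sum(x$n_event), "events\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
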