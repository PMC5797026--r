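# Cox regression on start-stop data ------------------------------------------
#
# Partial-likelihood Newton-Raphson with Breslow handling of tied event
# times, on counting-process (start, stop] intervals. A subject is at risk
# for an event at time t on an interval iff start < t <= stop. Time-fixed
# data are the special case start = 0.

#' Cox proportional hazards fit with time-dependent covariates
#'
#' Maximises the Breslow partial likelihood over start-stop risk intervals
#' by Newton-Raphson (convergence when the gradient's largest component
#' falls below `tol`). Built for the transplant-as-time-dependent-covariate
#' analysis (see [make_sct_intervals()]) but accepts any interval data.
#' Monotone likelihoods (perfect separation) are detected by coefficient
#' blow-up, flagged with a warning, and the bounded estimate of the final
#' iteration is returned.
#'
#' @param data data.frame holding the interval and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param start,stop,event names of the interval columns; if the `start`
#'   column is absent all intervals begin at 0.
#' @param tol gradient convergence tolerance (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return object of class `coxtd_fit`: list with `coefficients` (log
#'   hazard ratios), `se`, `z`, `p_value`, `loglik`, `iter`, `converged`,
#'   `flagged` (monotone-likelihood flag), `vcov`.
#' @export
cox_time_dependent <- function(data, covariates, start = "start",
                               stop = "stop", event = "event",
                               tol = 1e-8, max_iter = 50) {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  missing_cols <- setdiff(c(covariates, stop, event), names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  t0 <- if (start %in% names(data)) as.numeric(data[[start]]) else {
    rep(0, nrow(data))
  }
  t1 <- as.numeric(data[[stop]])
  ev <- as.logical(data[[event]])
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(t1 <= t0)) stop("intervals must satisfy start < stop", call. = FALSE)
  if (anyNA(t0) || anyNA(t1) || anyNA(ev) || anyNA(X)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  p <- ncol(X)
  times <- sort(unique(t1[ev]))
  risk_idx <- lapply(times, function(t) which(t0 < t & t1 >= t))
  death_idx <- lapply(times, function(t) which(ev & t1 == t))

  pl <- function(beta) {
    eta <- drop(X %*% beta)
    ll <- 0
    grad <- numeric(p)
    hess <- matrix(0, p, p)
    for (j in seq_along(times)) {
      R <- risk_idx[[j]]
      D <- death_idx[[j]]
      w <- exp(eta[R])
      sw <- sum(w)
      xbar <- drop(crossprod(X[R, , drop = FALSE], w)) / sw
      xxbar <- crossprod(X[R, , drop = FALSE] * w, X[R, , drop = FALSE]) / sw
      d <- length(D)
      ll <- ll + sum(eta[D]) - d * log(sw)
      grad <- grad + colSums(X[D, , drop = FALSE]) - d * xbar
      hess <- hess + d * (xxbar - outer(xbar, xbar))
    }
    list(ll = ll, grad = grad, hess = hess)
  }

  beta <- numeric(p)
  flagged <- FALSE
  converged <- FALSE
  cur <- pl(beta)
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(cur$grad)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(cur$hess, cur$grad), error = function(e) {
      cur$grad / (diag(cur$hess) + 1e-12)
    })
    new_beta <- beta + step
    new <- pl(new_beta)
    halvings <- 0
    while ((!is.finite(new$ll) || new$ll < cur$ll - 1e-12) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new <- pl(new_beta)
      halvings <- halvings + 1
    }
    beta <- new_beta
    cur <- new
    if (any(abs(beta) > 15)) {
      flagged <- TRUE
      warning("possible monotone partial likelihood (coefficient beyond ",
              "+/-15); estimate is bounded, not a maximum", call. = FALSE)
      break
    }
  }
  if (!converged && max(abs(cur$grad)) < tol) converged <- TRUE
  vcov <- tryCatch(solve(cur$hess), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  names(beta) <- names(se) <- names(z) <- covariates
  structure(
    list(coefficients = beta, se = se, z = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         loglik = cur$ll, iter = iter, converged = converged,
         flagged = flagged, vcov = vcov, n = nrow(data),
         n_event = sum(ev)),
    class = "coxtd_fit"
  )
}

#' @export
print.coxtd_fit <- function(x, ...) {
  cat("Cox fit (Breslow ties, counting-process intervals):",
      x$n, "intervals,", x$n_event, "events\n")
  print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                   se = x$se, z = x$z, p = x$p_value, check.names = FALSE))
  if (!x$converged) cat("NOTE: Newton iterations did not converge\n")
  if (x$flagged) cat("NOTE: monotone likelihood flagged\n")
  invisible(x)
}
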