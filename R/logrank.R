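# Log-rank test --------------------------------------------------------------

#' K-sample log-rank test
#'
#' Score/variance construction over the pooled event times with the
#' hypergeometric tie correction; the statistic is U' V^-1 U over the first
#' k-1 groups and is referred to a chi-square distribution with k-1 degrees
#' of freedom.
#'
#' @param time follow-up times.
#' @param event logical or 0/1 event indicator.
#' @param group group membership (coerced to factor); every level must be
#'   non-empty and there must be at least two.
#' @return list with `statistic`, `df`, `p_value`, `observed`, `expected`
#'   (named by group).
#' @export
logrank <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.logical(event)
  group <- factor(group)
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (anyNA(time) || anyNA(event) || anyNA(group)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  k <- nlevels(group)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(group) == 0)) {
    stop("every group must contain at least one subject", call. = FALSE)
  }
  tt <- sort(unique(time[event]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in tt) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(event & time == t)
    if (n_j == 0 || d_j == 0) next
    n_ij <- vapply(levels(group), function(g) sum(at_risk & group == g),
                   numeric(1))
    d_ij <- vapply(levels(group), function(g) {
      sum(event & time == t & group == g)
    }, numeric(1))
    O <- O + d_ij
    E <- E + d_j * n_ij / n_j
    if (n_j > 1) {
      mult <- d_j * (n_j - d_j) / (n_j - 1)
      p_i <- n_ij / n_j
      V <- V + mult * (diag(p_i, nrow = k) - outer(p_i, p_i))
    }
  }
  U <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- if (length(tt) == 0 || all(abs(U) < 1e-12) && all(abs(Vk) < 1e-12)) {
    0
  } else {
    drop(crossprod(U, solve(Vk, U)))
  }
  names(O) <- names(E) <- levels(group)
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}
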