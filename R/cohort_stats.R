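# Subgroup-vs-rest categorical statistics ------------------------------------

z_quantile <- function(level) stats::qnorm(1 - (1 - level) / 2)

#' Proportion with a Wald confidence interval (percent scale)
#'
#' Point estimate 100 k/n with the normal-approximation interval
#' point +/- z * 100 * sqrt(p(1-p)/n), clamped to \[0, 100\].
#'
#' @param k number of events.
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95; z = 1.959964...).
#' @return object of class `ratio_estimate` with elements `point`,
#'   `ci_low`, `ci_high`, `level`, `method = "wald_prop"`, `k`, `n`.
#' @examples
#' proportion_with_ci(118, 136)
#' @export
proportion_with_ci <- function(k, n, level = 0.95) {
  if (!(is.numeric(n) && length(n) == 1 && n > 0)) {
    stop("n must be a positive count", call. = FALSE)
  }
  if (!(is.numeric(k) && length(k) == 1 && k >= 0 && k <= n)) {
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  }
  p <- k / n
  point <- 100 * p
  half <- z_quantile(level) * 100 * sqrt(p * (1 - p) / n)
  structure(
    list(point = point,
         ci_low = max(0, point - half),
         ci_high = min(100, point + half),
         p_value = NA_real_,
         level = level, method = "wald_prop", k = k, n = n),
    class = "ratio_estimate"
  )
}

#' Odds ratio with a Woolf (log-normal) confidence interval
#'
#' For the 2x2 table `a` (event in group), `b` (no event in group), `c`
#' (event in rest), `d` (no event in rest): point (a d)/(b c), interval
#' exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)), and a Pearson chi-square
#' p-value on the (uncorrected) table. If any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied to the
#' estimate and interval, and the result is tagged `corrected`.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param level confidence level.
#' @return object of class `ratio_estimate` with elements `point`,
#'   `ci_low`, `ci_high`, `p_value`, `method = "woolf_or"`, `corrected`.
#' @examples
#' odds_ratio(50, 3, 275, 65)  # OR 3.939, CI approximately 1.191-13.03
#' @export
odds_ratio <- function(a, b, c, d, level = 0.95) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0) {
    stop("both rows of the 2x2 table must be non-empty", call. = FALSE)
  }
  corrected <- any(counts == 0)
  cc <- if (corrected) counts + 0.5 else counts
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  half <- z_quantile(level) * se
  p <- tryCatch(chi_square(a, b, c, d)$p_value, warning = function(w) {
    suppressWarnings(chi_square(a, b, c, d)$p_value)
  })
  structure(
    list(point = or,
         ci_low = exp(log(or) - half),
         ci_high = exp(log(or) + half),
         p_value = p,
         level = level, method = "woolf_or", corrected = corrected,
         counts = counts),
    class = "ratio_estimate"
  )
}

#' Pearson chi-square test for a 2x2 table
#'
#' One degree of freedom, no continuity correction. A warning recommending
#' the exact test is emitted when any expected cell count falls below 1.
#'
#' @param a,b,c,d cell counts, or a 2x2 matrix as `a` with `b`, `c`, `d`
#'   missing.
#' @return list with `statistic`, `df` (1) and `p_value`.
#' @export
chi_square <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), nrow = 2)
  if (!all(dim(tab) == c(2, 2)) || anyNA(tab) || any(tab < 0)) {
    stop("chi_square needs a complete non-negative 2x2 table", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: chi-square statistic undefined", call. = FALSE)
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_))
  }
  if (any(expected < 1)) {
    warning("expected cell count below 1; an exact test is recommended",
            call. = FALSE)
  }
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' @export
print.ratio_estimate <- function(x, digits = 3, ...) {
  lab <- switch(x$method, wald_prop = "proportion (%)", woolf_or = "odds ratio",
                x$method)
  cat(sprintf("%s: %.*f (%d%% CI %.*f-%.*f)", lab, digits, x$point,
              round(100 * x$level), digits, x$ci_low, digits, x$ci_high))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  if (isTRUE(x$corrected)) cat(" [Haldane-Anscombe corrected]")
  cat("\n")
  invisible(x)
}

#' Subgroup-versus-rest association table
#'
#' For each genomic class, forms the 2x2 table of a binary outcome in the
#' class versus the rest of the cohort and reports the class rate (Wald CI)
#' and the Woolf odds ratio with its chi-square p-value.
#'
#' @param labels factor/character of class labels, one per patient.
#' @param outcome logical vector, same length (e.g. CR achieved, SCT done).
#' @param level confidence level.
#' @return data.frame with one row per class present in [GENOMIC_CLASSES]:
#'   `label`, `k`, `n`, `rate_pct`, `rate_low`, `rate_high`, `or`,
#'   `or_low`, `or_high`, `p_value`, `or_corrected`.
#' @export
subgroup_vs_rest <- function(labels, outcome, level = 0.95) {
  stopifnot(length(labels) == length(outcome))
  labels <- factor(as.character(labels), levels = GENOMIC_CLASSES)
  keep <- !is.na(outcome) & !is.na(labels)
  labels <- labels[keep]; outcome <- as.logical(outcome[keep])
  rows <- lapply(GENOMIC_CLASSES, function(cl) {
    incl <- labels == cl
    a <- sum(outcome & incl); b <- sum(!outcome & incl)
    cc <- sum(outcome & !incl); dd <- sum(!outcome & !incl)
    n <- a + b
    if (n == 0) {
      return(data.frame(label = cl, k = 0L, n = 0L, rate_pct = NA_real_,
                        rate_low = NA_real_, rate_high = NA_real_,
                        or = NA_real_, or_low = NA_real_, or_high = NA_real_,
                        p_value = NA_real_, or_corrected = NA,
                        stringsAsFactors = FALSE))
    }
    pr <- proportion_with_ci(a, n, level)
    orr <- suppressWarnings(odds_ratio(a, b, cc, dd, level))
    data.frame(label = cl, k = a, n = n, rate_pct = pr$point,
               rate_low = pr$ci_low, rate_high = pr$ci_high,
               or = orr$point, or_low = orr$ci_low, or_high = orr$ci_high,
               p_value = orr$p_value, or_corrected = orr$corrected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
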