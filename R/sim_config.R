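# Synthetic-cohort configuration ---------------------------------------------
#
# Defaults reproduce the published Table-1 structure of a 393-patient
# normal-karyotype AML cohort: subgroup prevalences, per-class CR and
# transplant rates, 5-year OS and 5-year relapse incidence, and the class
# medians/ranges of age, WBC and marrow blasts.

TABLE1_CLASS_COUNTS <- c(
  NPM1 = 136, CHROMATIN_SPLICE = 42, TP53 = 6, BIALLELIC_CEBPA = 53,
  IDH2_R172 = 8, DRIVER_NO_CLASS = 116, NO_DRIVER = 17, MULTI_CLASS = 15
)

default_class_params <- function() {
  data.frame(
    label = GENOMIC_CLASSES,
    cr_prob = c(118 / 136, 26 / 42, 5 / 6, 50 / 53, 7 / 8, 91 / 116,
                16 / 17, 12 / 15),
    sct_prob = c(46 / 136, 6 / 42, 3 / 6, 30 / 53, 3 / 8, 33 / 116,
                 6 / 17, 2 / 15),
    five_year_os = c(0.493, 0.116, 0.500, 0.584, 0.563, 0.243, 0.294, 0.400),
    five_year_relapse = c(0.403, 0.714, 0.200, 0.213, 0.214, 0.539, 0.438,
                          0.333),
    male_frac = c(58 / 136, 32 / 42, 3 / 6, 22 / 53, 6 / 8, 62 / 116,
                  8 / 17, 10 / 15),
    age_median = c(54, 59, 39, 40, 58, 50, 41, 59),
    age_lo = c(15, 19, 22, 15, 51, 17, 23, 16),
    age_hi = c(84, 76, 54, 72, 64, 83, 69, 75),
    wbc_median = c(41.7, 12.6, 8.8, 28.5, 1.6, 23.7, 2.5, 13.9),
    wbc_lo = c(0.9, 0.5, 2.0, 4.5, 0.5, 0.5, 0.3, 1.2),
    wbc_hi = c(384.0, 397.2, 120.7, 333.2, 8.6, 279.0, 121.0, 142.0),
    blast_median = c(79, 60, 48, 70, 72, 68, 79, 69),
    blast_lo = c(3, 10, 16, 16, 56, 2, 12, 23),
    blast_hi = c(100, 100, 100, 100, 100, 100, 100, 100),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic NK-AML cohort generator
#'
#' All defaults encode the published cohort structure; override any piece
#' for sensitivity experiments. Probabilities are validated; outcome
#' calibration must be solvable (`five_year_relapse` in \[0, 1) whenever
#' the class has deaths, `five_year_os` in (0, 1\]).
#'
#' @param n_patients cohort size (default 393).
#' @param seed RNG seed used by [generate_cohort()].
#' @param class_probs named 8-vector of subgroup probabilities in
#'   [GENOMIC_CLASSES] order; must sum to 1 (tolerance 1e-9). Default: the
#'   published counts 136/42/6/53/8/116/17/15 over 393.
#' @param class_params data.frame of per-class parameters (`label`,
#'   `cr_prob`, `sct_prob` (class-level transplant fraction),
#'   `five_year_os`, `five_year_relapse`, `male_frac`, and the
#'   age/WBC/blast medians and ranges).
#' @param co_mutation_freqs named vector of marginal frequencies for
#'   non-class-defining co-mutations (default FLT3 0.349, DNMT3A 0.316,
#'   NRAS 0.183, TET2 0.102).
#' @param prob_control probability that a patient has a matched control
#'   sample; without one, planted variants carry the control-free caller
#'   flag (default 0.8).
#' @param followup_horizon administrative follow-up ceiling in months
#'   (default 120); censoring times are uniform on
#'   (`followup_min`, `followup_horizon`).
#' @param followup_min earliest administrative censoring time (default 72,
#'   so 60-month estimates are never censoring-limited).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 393,
                       seed = 1,
                       class_probs = TABLE1_CLASS_COUNTS / sum(TABLE1_CLASS_COUNTS),
                       class_params = default_class_params(),
                       co_mutation_freqs = c(FLT3 = 0.349, DNMT3A = 0.316,
                                             NRAS = 0.183, TET2 = 0.102),
                       prob_control = 0.8,
                       followup_horizon = 120,
                       followup_min = 72) {
  if (!(is.numeric(n_patients) && length(n_patients) == 1 &&
        n_patients >= 0 && n_patients == round(n_patients))) {
    stop("n_patients must be a non-negative integer", call. = FALSE)
  }
  class_probs <- class_probs[GENOMIC_CLASSES]
  if (anyNA(class_probs)) {
    stop("class_probs must be named by GENOMIC_CLASSES", call. = FALSE)
  }
  if (abs(sum(class_probs) - 1) > 1e-9) {
    stop("class_probs must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(class_probs < 0)) stop("class_probs must be non-negative",
                                 call. = FALSE)
  stopifnot(is.data.frame(class_params),
            identical(class_params$label, GENOMIC_CLASSES))
  probs <- c(class_params$cr_prob, class_params$sct_prob,
             class_params$five_year_os, class_params$five_year_relapse,
             class_params$male_frac, prob_control, co_mutation_freqs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(class_params$five_year_os <= 0)) {
    stop("five_year_os must be positive (exponential calibration ",
         "-log(five_year_os)/60 must be finite)", call. = FALSE)
  }
  # infeasible outcome calibration: a relapse incidence of 1 (or more) at 60
  # months cannot coexist with any survivors among CR patients
  infeasible <- class_params$five_year_relapse >= 1 &
    class_params$five_year_os < 1
  if (any(class_params$five_year_relapse >= 1)) {
    stop("infeasible calibration: five_year_relapse must be below 1 for ",
         "class(es) ", paste(class_params$label[class_params$five_year_relapse
                                                >= 1 | infeasible],
                             collapse = ", "), call. = FALSE)
  }
  if (!(followup_horizon > 60 && followup_min > 60 &&
        followup_min <= followup_horizon)) {
    stop("follow-up window must satisfy 60 < followup_min <= followup_horizon",
         call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         class_probs = class_probs, class_params = class_params,
         co_mutation_freqs = co_mutation_freqs, prob_control = prob_control,
         followup_horizon = followup_horizon, followup_min = followup_min),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic NK-AML cohort config:", x$n_patients, "patients, seed",
      x$seed, "\n")
  cat("class probabilities:\n")
  print(round(x$class_probs, 4))
  invisible(x)
}

# Outcome-model rates per class: all-cause death hazard from the 5-year OS
# point; relapse hazard solved so the exponential competing-risks CIF at 60
# months equals the 5-year relapse target.
class_rates <- function(cfg) {
  cp <- cfg$class_params
  lam_os <- -log(cp$five_year_os) / 60
  lam_rel <- vapply(seq_len(nrow(cp)), function(i) {
    target <- cp$five_year_relapse[i]
    if (target <= 0) return(0)
    lo <- lam_os[i]
    f <- function(lr) {
      tot <- lr + lo
      lr / tot * (1 - exp(-60 * tot)) - target
    }
    upper <- 1
    while (f(upper) < 0 && upper < 1e6) upper <- upper * 10
    stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
  }, numeric(1))
  data.frame(label = cp$label, lam_os = lam_os, lam_rel = lam_rel,
             stringsAsFactors = FALSE)
}
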