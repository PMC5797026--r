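test_that("endpoint derivation follows the OS/EFS/relapse definitions", {
  cl <- rbind(
    # CR at 1.5, relapse at 10, death at 14
    make_clinical_row("P1", cr_time = 1.5, relapse_time = 10, death_time = 14,
                      last_followup_time = 14),
    # CR, never relapsed, alive at 70
    make_clinical_row("P2", cr_time = 1.5, last_followup_time = 70),
    # no CR, death at 3
    make_clinical_row("P3", cr_achieved = FALSE, cr_time = NA_real_,
                      death_time = 3, last_followup_time = 3),
    # no CR, alive at 24: EFS event at the failure-assessment default
    make_clinical_row("P4", cr_achieved = FALSE, cr_time = NA_real_,
                      last_followup_time = 24),
    # transplanted in CR, alive: SCT must not censor anything
    make_clinical_row("P5", cr_time = 2, sct_time = 5,
                      last_followup_time = 80)
  )
  ep <- derive_endpoints(cl)
  expect_equal(ep$os_time, c(14, 70, 3, 24, 80))
  expect_equal(ep$os_event, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ep$relapse_time[1], 8.5)
  expect_equal(ep$relapse_code[1], 1L)
  expect_equal(ep$efs_time[1], 10)
  expect_true(ep$efs_event[1])
  expect_equal(ep$relapse_time[2], 68.5)
  expect_equal(ep$relapse_code[2], 0L)
  expect_equal(ep$efs_time[2], 70)
  expect_false(ep$efs_event[2])
  # non-CR: EFS event at min(default 1, death/lfu)
  expect_equal(ep$efs_time[3], 1)
  expect_true(ep$efs_event[3])
  expect_equal(ep$efs_time[4], 1)
  expect_true(ep$efs_event[4])
  expect_true(is.na(ep$relapse_code[3]))
  # SCT patient: censored at last follow-up, relapse clock from CR
  expect_equal(ep$os_time[5], 80)
  expect_equal(ep$relapse_time[5], 78)
  # death before the non-CR assessment default moves the EFS event earlier
  cl2 <- make_clinical_row("P6", cr_achieved = FALSE, cr_time = NA_real_,
                           death_time = 0.4, last_followup_time = 0.4)
  expect_equal(derive_endpoints(cl2)$efs_time, 0.4)
})

test_that("Kaplan-Meier matches the hand product-limit on 3 subjects", {
  km <- kaplan_meier(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # Greenwood at t=1: S * sqrt(d/(n(n-d))) = 2/3 * sqrt(1/6)
  expect_equal(km$se[1], 2 / 3 * sqrt(1 / 6))
  all_cens <- kaplan_meier(c(5, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(all_cens$surv == 1))
  expect_error(kaplan_meier(c(-1, 2), c(TRUE, TRUE)), "non-negative")
})

test_that("Kaplan-Meier and Greenwood match the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(12)
  for (i in 1:5) {
    n <- 150
    tm <- round(rexp(n, 0.1), 1)  # rounding forces ties
    ev <- runif(n) < 0.65
    km <- kaplan_meier(tm, ev)
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    expect_equal(km$surv, sf$surv, tolerance = 1e-12)
    # survfit reports NaN once S reaches 0, where this package uses 0
    pos <- km$surv > 0
    expect_equal(km$se[pos], (sf$std.err * sf$surv)[pos], tolerance = 1e-12)
    expect_equal(km$n_risk, sf$n.risk)
  }
})

test_that("KM approaches the exponential survivor function at large n", {
  set.seed(500)
  lam <- 0.05
  tm <- rexp(4000, lam)
  cens <- runif(4000, 0, 80)
  obs <- pmin(tm, cens)
  km <- kaplan_meier(obs, tm <= cens)
  grid <- seq(1, 50, by = 1)
  shat <- vapply(grid, function(t) survival_at(km, t)$estimate, numeric(1))
  expect_lt(max(abs(shat - exp(-lam * grid))), 0.03)
})

test_that("survival_at evaluates right-continuously and warns beyond support", {
  km <- kaplan_meier(c(10, 20, 50), c(TRUE, TRUE, FALSE))
  expect_equal(survival_at(km, 5)$estimate, 1)
  expect_equal(survival_at(km, 10)$estimate, 2 / 3)
  expect_equal(survival_at(km, 45)$estimate, 1 / 3)
  expect_warning(s <- survival_at(km, 61), "beyond last observed")
  expect_equal(s$estimate, 1 / 3)
  expect_gte(s$ci_low, 0)
  expect_lte(s$ci_high, 1)
  # unclamped plain-scale Wald interval may leave [0, 1]
  raw <- survival_at(kaplan_meier(c(5, 9), c(TRUE, FALSE)), 7, clamp = FALSE)
  expect_lt(raw$ci_low, 0)
})

test_that("log-rank matches the hand 6-subject tabulation", {
  tm <- c(1, 3, 5, 2, 4, 6)
  ev <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  gr <- rep(c("A", "B"), each = 3)
  lr <- logrank(tm, ev, gr)
  # hand tabulation: O_A = 2, E_A = 0.5 + 0.4 + 0.5 = 1.4, V = 0.74
  expect_equal(unname(lr$observed["A"] - lr$expected["A"]), 0.6,
               tolerance = 1e-12)
  expect_equal(lr$statistic, 0.6^2 / 0.74, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
})

test_that("log-rank is zero for identical groups and matches survdiff", {
  tm <- c(2, 4, 6, 8, 2, 4, 6, 8)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  gr <- rep(c("A", "B"), each = 4)
  lr <- logrank(tm, ev, gr)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  skip_if_not_installed("survival")
  set.seed(21)
  for (i in 1:5) {
    n <- 90
    tm <- round(rexp(n, 0.2), 1)
    ev <- runif(n) < 0.7
    gr <- sample(c("a", "b", "c"), n, replace = TRUE)
    lr <- logrank(tm, ev, gr)
    sd <- survival::survdiff(survival::Surv(tm, ev) ~ gr)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
    expect_equal(lr$df, 2L)
  }
  expect_error(logrank(c(1, 2), c(TRUE, TRUE), c("a", "a")), "two groups")
})

test_that("Aalen-Johansen matches the hand 5-subject tabulation", {
  aj <- aalen_johansen(time = 1:5, code = c(1, 2, 1, 0, 1))
  expect_equal(aj$cif.1, c(0.2, 0.2, 0.4, 0.4, 0.8))
  expect_equal(aj$cif.2, c(0, 0.2, 0.2, 0.2, 0.2))
  expect_equal(aj$km, c(0.8, 0.6, 0.4, 0.4, 0))
  expect_error(aalen_johansen(1:3, c(1, -1, 0)), "unknown event code")
})

test_that("with a single cause the CIF is the KM complement", {
  set.seed(77)
  tm <- rexp(100)
  code <- ifelse(runif(100) < 0.7, 1L, 0L)
  aj <- aalen_johansen(tm, code)
  km <- kaplan_meier(tm, code == 1)
  expect_equal(aj$cif.1, 1 - km$surv, tolerance = 1e-12)
})

test_that("CIFs and all-cause KM conserve probability at machine precision", {
  set.seed(88)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    tm <- round(rexp(n, 0.3), 2)
    code <- sample(0:2, n, replace = TRUE)
    aj <- aalen_johansen(tm, code)
    if (!all(c("cif.1", "cif.2") %in% names(aj))) next
    expect_lt(max(abs(aj$km + aj$cif.1 + aj$cif.2 - 1)), 1e-12)
  }
})

test_that("AJ estimates and variance match the reference implementations", {
  skip_if_not_installed("survival")
  set.seed(90)
  n <- 250
  tm <- round(rexp(n, 0.2), 1) + 0.1  # ties, but no zero times
  code <- ifelse(runif(n) < 0.3, 0L, 1L + (runif(n) < 0.4))
  aj <- aalen_johansen(tm, code)
  states <- factor(code, 0:2, c("censor", "relapse", "death"))
  sf <- survival::survfit(survival::Surv(tm, states) ~ 1)
  i <- match(aj$time, sf$time)
  rel_col <- match("relapse", colnames(sf$pstate))
  dth_col <- match("death", colnames(sf$pstate))
  expect_equal(aj$cif.1, sf$pstate[i, rel_col], tolerance = 1e-12)
  expect_equal(aj$cif.2, sf$pstate[i, dth_col], tolerance = 1e-12)
  expect_equal(sqrt(aj$var.1), sf$std.err[i, rel_col], tolerance = 1e-10)
  # cmprsk point estimates agree too (its variance is Gray's finite-sample
  # variant, close but not identical)
  ci <- cmprsk::cuminc(tm, code, cencode = 0)
  tp <- cmprsk::timepoints(ci, aj$time)
  expect_equal(aj$cif.1, unname(tp$est["1 1", ]), tolerance = 1e-12)
  rel <- abs(aj$var.1 - tp$var["1 1", ]) / pmax(tp$var["1 1", ], 1e-8)
  expect_lt(stats::median(rel, na.rm = TRUE), 0.1)
})

test_that("left truncation shrinks early risk sets", {
  aj <- aalen_johansen(time = c(2, 3, 4), code = c(1, 1, 1),
                       entry = c(0, 2.5, 0))
  expect_equal(aj$n_risk, c(2, 2, 1))
  expect_error(aalen_johansen(1, 1, entry = 2), "entry")
})

test_that("Gray's test is degenerate for identical groups and without events", {
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4)
  cd <- c(1, 2, 0, 1, 1, 2, 0, 1)
  gr <- rep(c("x", "y"), each = 4)
  g <- grays_test(tm, cd, gr)
  expect_equal(g$statistic, 0, tolerance = 1e-12)
  expect_equal(g$p_value, 1, tolerance = 1e-12)
  expect_warning(g0 <- grays_test(c(1, 2, 3, 4), c(0, 2, 0, 2),
                                  c("x", "x", "y", "y")),
                 "degenerate")
  expect_equal(g0$p_value, 1)
})

test_that("Gray's test p agrees with a permutation-null oracle", {
  set.seed(314)
  n <- 40
  tm <- round(rexp(n, 0.3), 2)
  cd <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  gr <- rep(c("A", "B"), each = n / 2)
  obs <- grays_test(tm, cd, gr)
  nperm <- 2000
  perm_stats <- vapply(seq_len(nperm), function(i) {
    grays_test(tm, cd, sample(gr))$statistic
  }, numeric(1))
  p_perm <- mean(perm_stats >= obs$statistic - 1e-12)
  # the chi-square p and the permutation p estimate the same null tail
  expect_lt(abs(obs$p_value - p_perm),
            3 * sqrt(p_perm * (1 - p_perm) / nperm) + 0.02)
})

test_that("Cox with a zero covariate returns log-HR 0 and start-stop
           representation is invariant for time-fixed covariates", {
  d <- data.frame(start = 0, stop = c(3, 5, 7, 9), event = c(1, 1, 0, 1),
                  x = 0)
  fit <- cox_time_dependent(d, "x")
  expect_equal(unname(fit$coefficients), 0)
  skip_if_not_installed("survival")
  set.seed(44)
  n <- 60
  d2 <- data.frame(stop = rexp(n) + 0.1, event = runif(n) < 0.6,
                   x = rnorm(n), z = rbinom(n, 1, 0.4))
  fit_plain <- cox_time_dependent(d2, c("x", "z"))
  d3 <- cbind(start = 0, d2)
  fit_ss <- cox_time_dependent(d3, c("x", "z"))
  expect_equal(fit_plain$coefficients, fit_ss$coefficients, tolerance = 1e-10)
  ref <- survival::coxph(survival::Surv(stop, event) ~ x + z, data = d2,
                         ties = "breslow")
  expect_equal(unname(fit_plain$coefficients), unname(coef(ref)),
               tolerance = 1e-7)
  expect_equal(unname(fit_plain$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-7)
})

test_that("Cox matches a brute-force partial-likelihood grid on 5 subjects", {
  d <- data.frame(start = c(0, 0, 0, 2, 1),
                  stop = c(4, 6, 8, 9, 3),
                  event = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                  x = c(1, 0, 1, 0, 1))
  fit <- cox_time_dependent(d, "x")
  # independent brute-force Breslow partial log-likelihood
  pl <- function(b) {
    out <- 0
    for (t in sort(unique(d$stop[d$event]))) {
      risk <- d$start < t & d$stop >= t
      dead <- d$event & d$stop == t
      out <- out + sum(b * d$x[dead]) -
        sum(dead) * log(sum(exp(b * d$x[risk])))
    }
    out
  }
  opt <- stats::optimize(pl, c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("time-dependent SCT covariate matches the reference start-stop fit", {
  skip_if_not_installed("survival")
  co <- generate_cohort(sim_config(n_patients = 300, seed = 17))
  ep <- derive_endpoints(co$clinical)
  iv <- make_sct_intervals(co$clinical, ep, "os")
  fit <- cox_time_dependent(iv, "sct")
  ref <- survival::coxph(survival::Surv(start, stop, event) ~ sct, data = iv,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
  # exposure intervals only exist for transplanted patients
  expect_true(all(iv$sct[iv$start > 0] == 1))
})

test_that("monotone likelihood is flagged with a bounded estimate", {
  d <- data.frame(start = 0, stop = c(1, 2, 3, 4, 5, 6),
                  event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                  x = c(1, 1, 1, 0, 0, 0))
  expect_warning(fit <- cox_time_dependent(d, "x"), "monotone")
  expect_true(fit$flagged)
  expect_true(all(is.finite(fit$coefficients)))
})
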