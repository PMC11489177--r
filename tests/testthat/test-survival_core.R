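test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(5, 10, 15), c(1, 1, 1))
  expect_equal(km$time, c(5, 10, 15))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))

  # censoring before the first event shrinks the risk set: S(5) = 1 - 1/3
  km2 <- km_estimate(c(1, 5, 10, 15), c(0, 1, 1, 1))
  expect_equal(km2$survival, c(2/3, 1/3, 0))
  expect_equal(km2$at_risk, c(3, 2, 1))

  # all censored: survival identically 1 (no event times)
  km3 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_length(km3$time, 0)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier agrees with survival::survfit and is non-increasing", {
  for (seed in 1:5) {
    d <- make_surv(60, seed)
    km <- km_estimate(d$times, d$events)
    sf <- survival::survfit(survival::Surv(d$times, d$events) ~ 1)
    expect_equal(km$survival, sf$surv[sf$n.event > 0], tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 0))
    expect_true(all(km$survival <= 1))
  }
})

test_that("log-rank statistic matches the hand-computed O/E/V table", {
  res <- logrank_test(1:6, rep(1, 6), rep(c("A", "B"), each = 3))
  # six risk sets: U_A = 3 - (0.5 + 0.4 + 0.25), V = 0.25 + 0.24 + 0.1875
  expect_equal(res$chi_square, 1.85^2 / 0.6775, tolerance = 1e-12)
  expect_equal(res$observed, c(3, 3))
  expect_equal(res$expected[1], 1.15, tolerance = 1e-12)

  # identical groups: statistic 0, p 1
  same <- logrank_test(rep(c(2, 4, 8), 2), rep(c(1, 0, 1), 2),
                       rep(c("A", "B"), each = 3))
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
})

test_that("log-rank agrees with survival::survdiff and is label-symmetric", {
  for (seed in 1:5) {
    d <- make_surv(80, seed)
    g <- rep(c("x", "y"), 40)
    r1 <- logrank_test(d$times, d$events, g)
    r2 <- logrank_test(d$times, d$events, rev(g))
    sd_ <- survival::survdiff(survival::Surv(d$times, d$events) ~ g)
    expect_equal(r1$chi_square, sd_$chisq, tolerance = 1e-10)
    expect_equal(r1$chi_square, r2$chi_square, tolerance = 1e-12)
    expect_equal(r1$p, r2$p)
  }
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2")
  expect_message(r0 <- logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
  expect_equal(r0$p, 1)
})

test_that("Cox fit reproduces survival::coxph under both tie policies", {
  set.seed(11)
  n <- 150
  x <- cbind(age = rnorm(n), grp = rbinom(n, 1, 0.5))
  tm <- ceiling(rexp(n, 0.05 * exp(0.5 * x[, 2])))   # heavy ties
  ev <- rbinom(n, 1, 0.7)
  for (ties in c("efron", "breslow")) {
    f <- cox_fit(x, tm, ev, ties = ties)
    ref <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = ties)
    expect_equal(f$coefficients$coef, unname(coef(ref)), tolerance = 1e-7)
    expect_equal(f$coefficients$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(unname(f$loglik["final"]), unname(ref$loglik[2]), tolerance = 1e-8)
  }
})

test_that("Cox respects reparameterization and rejects degenerate input", {
  d <- make_surv(100, 3)
  set.seed(3); x <- rnorm(100)
  f1 <- cox_fit(cbind(x = x), d$times, d$events)
  f2 <- cox_fit(cbind(x = -x), d$times, d$events)
  expect_equal(f1$coefficients$coef, -f2$coefficients$coef, tolerance = 1e-8)
  expect_equal(f1$coefficients$hr, 1 / f2$coefficients$hr, tolerance = 1e-8)
  expect_true(f1$coefficients$ci_low <= f1$coefficients$hr)
  expect_true(f1$coefficients$hr <= f1$coefficients$ci_high)
  expect_error(cox_fit(cbind(k = rep(1, 100)), d$times, d$events), "constant.*k")
  expect_error(cox_fit(cbind(x = x), d$times, rep(0, 100)), "no events")
})

test_that("Cox recovers null and planted hazard ratios on exponential data", {
  set.seed(21)
  n <- 2000
  grp <- rep(0:1, n / 2)
  t_null <- rexp(n, 0.05)
  f0 <- cox_fit(cbind(grp = grp), pmax(t_null, 1e-3), rep(1, n))
  expect_gt(f0$coefficients$hr, 0.9)
  expect_lt(f0$coefficients$hr, 1.1)

  t_eff <- rexp(n, 0.05 * ifelse(grp == 1, 2, 1))
  f2 <- cox_fit(cbind(grp = grp), pmax(t_eff, 1e-3), rep(1, n))
  # asymptotic SE of beta for a balanced binary covariate is sqrt(4/n)
  expect_lt(abs(f2$coefficients$coef - log(2)), 3 * sqrt(4 / n))
})

test_that("Cox score test at zero equals the log-rank chi-square", {
  set.seed(5)
  tm <- sample(seq(1, 4000), 90)                     # distinct times: no ties
  ev <- rbinom(90, 1, 0.7)
  grp <- rbinom(90, 1, 0.5)
  sc <- natrecur:::.cox_score_chisq(cbind(g = grp), tm, ev)
  lr <- logrank_test(tm, ev, grp)
  expect_equal(sc, lr$chi_square, tolerance = 1e-6)
})

test_that("best cut-point equals the brute-force survdiff scan", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(30:200, 1)
    marker <- rnorm(n)
    d <- make_surv(n, seed + 100)
    got <- best_cutpoint(marker, d$times, d$events)
    ref <- oracle_cutpoint(marker, d$times, d$events)
    expect_equal(got$threshold, ref$thr, tolerance = 1e-12)
    expect_equal(got$chi_square, ref$chi, tolerance = 1e-9)
    expect_equal(got$n_low, ref$n_low)
    expect_gte(min(got$n_low, got$n_high), ceiling(0.1 * n))
  }
})

test_that("cut-point selection is invariant to monotone marker transforms", {
  set.seed(17)
  n <- 80
  marker <- rnorm(n)
  d <- make_surv(n, 18)
  a <- best_cutpoint(marker, d$times, d$events)
  b <- best_cutpoint(exp(marker), d$times, d$events)
  expect_equal(marker <= a$threshold, exp(marker) <= b$threshold)
  expect_equal(a$chi_square, b$chi_square, tolerance = 1e-10)
})

test_that("degenerate cut-point inputs are rejected", {
  d <- make_surv(10, 1)
  expect_error(best_cutpoint(rep(1, 10), d$times, d$events), "constant")
  expect_error(best_cutpoint(rnorm(10), d$times, d$events, minprop = 0.5),
               "minprop")
  expect_error(best_cutpoint(c(rep(0, 9), 1), d$times, d$events, minprop = 0.2),
               "admissible")
})

test_that("permutation p-value is computable and selection-aware", {
  set.seed(30)
  n <- 60
  marker <- rnorm(n)                                  # null marker
  d <- make_surv(n, 31)
  cp <- best_cutpoint(marker, d$times, d$events, n_perm = 99, seed = 7)
  expect_true(cp$perm_p >= cp$logrank_p)              # naive p is optimistic
  cp2 <- best_cutpoint(marker, d$times, d$events, n_perm = 99, seed = 7)
  expect_identical(cp$perm_p, cp2$perm_p)
})
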