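# Kaplan-Meier, pairwise log-rank, and the Breslow Cox fit against
# closed-form and brute-force oracles.

test_that("Kaplan-Meier matches hand-computed product-limit values", {
  # no events -> S stays at 1
  rec <- data.frame(time_months = 1:5, event = 0)
  km <- km_estimate(rec)
  expect_true(all(km$surv == 1))
  # all events at distinct times, n = 4
  rec2 <- data.frame(time_months = c(1, 2, 3, 4), event = 1)
  km2 <- km_estimate(rec2)
  expect_equal(km2$surv, c(0.75, 0.5, 0.25, 0))
  # mixed toy: events at 1 and 3, censored at 2
  rec3 <- data.frame(time_months = c(1, 2, 3), event = c(1, 0, 1))
  km3 <- km_estimate(rec3)
  expect_equal(km3$surv[km3$time == 1], 2 / 3)
  expect_equal(km3$surv[km3$time == 3], 2 / 3 * (1 - 1 / 1))
  # without censoring KM equals the empirical survival function
  set.seed(14)
  t4 <- round(rexp(40, 0.1), 3)
  km4 <- km_estimate(data.frame(time_months = t4, event = 1))
  emp <- sapply(km4$time, function(t) mean(t4 > t))
  expect_equal(km4$surv, emp)
})

test_that("input validation catches malformed survival records", {
  expect_error(km_estimate(data.frame(time_months = c(0, 1), event = c(1, 1))),
               "> 0")
  expect_error(km_estimate(data.frame(time_months = 1, event = 2)), "0/1")
})

test_that("pairwise log-rank matches the hypergeometric oracle", {
  # identical groups: statistic 0, p = 1
  base <- data.frame(time_months = c(2, 4, 6, 8), event = c(1, 1, 0, 1))
  rec <- rbind(base, base)
  lab <- rep(1:2, each = 4)
  lr <- logrank_pairwise(rec, lab)
  expect_equal(lr$chisq[1, 2], 0, tolerance = 1e-12)
  expect_equal(lr$p_value[1, 2], 1, tolerance = 1e-9)
  # separated groups: compare with direct accumulation
  set.seed(15)
  rec2 <- data.frame(time_months = c(rexp(30, 0.5), rexp(30, 0.1)) + 0.01,
                     event = rbinom(60, 1, 0.8))
  lab2 <- rep(1:2, each = 30)
  lr2 <- logrank_pairwise(rec2, lab2)
  oracle <- logrank_oracle(rec2$time_months, rec2$event, lab2)
  expect_equal(lr2$chisq[1, 2], oracle$chisq, tolerance = 1e-6)
  expect_equal(lr2$p_value[1, 2], oracle$p, tolerance = 1e-6)
  # statistic is invariant to swapping group labels
  lr2b <- logrank_pairwise(rec2, 3 - lab2)
  expect_equal(lr2b$chisq[1, 2], lr2$chisq[1, 2])
  # k groups -> k(k-1)/2 filled entries above the diagonal
  lab4 <- rep(1:4, 15)
  lr4 <- logrank_pairwise(rec2, lab4)
  expect_equal(sum(!is.na(lr4$p_value[upper.tri(lr4$p_value)])), 6)
  expect_equal(lr4$p_value, t(lr4$p_value))
})

test_that("a null covariate stays within 3 SE of zero", {
  set.seed(16)
  n <- 500
  rec <- data.frame(time_months = rexp(n, 0.05) + 1e-3,
                    event = rbinom(n, 1, 0.7),
                    x = rnorm(n))
  fit <- cox_fit(rec, "x")
  expect_lt(abs(fit$table$coef / fit$table$se), 3)
})

test_that("Breslow Cox matches the closed-form exponential log rate ratio", {
  set.seed(18)
  n <- 1000
  g <- rep(0:1, each = n / 2)
  lam <- 0.05 * exp(log(2) * g)
  rec <- data.frame(time_months = rexp(n, lam), event = 1, g = g)
  fit <- cox_fit(rec, "g")
  d1 <- sum(rec$event[g == 1]); t1 <- sum(rec$time_months[g == 1])
  d0 <- sum(rec$event[g == 0]); t0 <- sum(rec$time_months[g == 0])
  mle <- log((d1 / t1) / (d0 / t0))
  expect_lt(abs(fit$table$coef - mle) / abs(mle), 0.05)
  # tie-free data: Breslow and exact partial likelihoods agree
  exact <- survival::coxph(survival::Surv(time_months, event) ~ g,
                           data = rec, ties = "exact")
  expect_equal(unname(fit$table$coef), unname(coef(exact)), tolerance = 1e-6)
})

test_that("covariate scaling behaves like a reparameterization", {
  set.seed(19)
  n <- 300
  rec <- data.frame(time_months = rexp(n, 0.05) + 1e-3,
                    event = rbinom(n, 1, 0.6),
                    x = rnorm(n, 10, 2))
  f1 <- cox_fit(rec, "x", scaling = "unit")
  rec10 <- transform(rec, x = x * 10)
  f10 <- cox_fit(rec10, "x", scaling = "unit")
  expect_equal(f10$table$coef, f1$table$coef / 10, tolerance = 1e-6)
  expect_equal(f10$loglik, f1$loglik, tolerance = 1e-8)
  # per-SD scaling: HR refers to a 1-SD increment
  fsd <- cox_fit(rec, "x", scaling = "sd")
  expect_equal(fsd$table$coef,
               f1$table$coef * lvmech:::.sd_pop(rec$x), tolerance = 1e-6)
})

test_that("degenerate Cox inputs are rejected or flagged", {
  rec <- data.frame(time_months = 1:6, event = 0, x = rnorm(6))
  expect_error(cox_fit(rec, "x"), "no events")
  rec2 <- data.frame(time_months = 1:6 + 0.5, event = 1,
                     x = 1:6, y = 2 * (1:6))
  expect_error(cox_fit(rec2, c("x", "y"), scaling = "unit"), "collinear")
  expect_error(cox_fit(rec2, c("x", "missing_cov")), "missing_cov")
})

test_that("forest tables order hazard ratios independently of input order", {
  set.seed(20)
  n <- 400
  rec <- data.frame(time_months = rexp(n, 0.05) + 1e-3,
                    event = rbinom(n, 1, 0.7),
                    a = rnorm(n), b = rnorm(n), c = rnorm(n))
  f_abc <- forest_table(cox_fit(rec, c("a", "b", "c")))
  f_cba <- forest_table(cox_fit(rec, c("c", "b", "a")))
  expect_equal(f_abc, f_cba, tolerance = 1e-9)
  expect_true(all(diff(f_abc$hr) <= 0))
  single <- forest_table(cox_fit(rec, "a"))
  expect_equal(nrow(single), 1L)
})
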