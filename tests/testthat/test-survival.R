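test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # censoring at t = 2 only shrinks the risk set
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$event_times, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))

  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km3$event_times, 0)
  expect_equal(km_estimate(c(5), c(0))$max_time, 5)
})

test_that("KM with no censoring equals the empirical survival function", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:50, 1)
    t <- rexp(n)
    km <- km_estimate(t, rep(1, n))
    for (i in seq_along(km$event_times)) {
      expect_equal(km$survival[i], mean(t > km$event_times[i]), tolerance = 1e-12)
    }
  }
})

test_that("log-rank p matches the textbook O-E computation and is invariant", {
  # hand-worked 6-patient example, no ties across groups
  time <- c(1, 3, 4, 2, 5, 7)
  event <- c(1, 1, 0, 1, 1, 1)
  grp <- rep(c("a", "b"), each = 3)
  expect_equal(logrank_p(time, event, grp), hand_logrank(time, event, grp)$p,
               tolerance = 1e-10)

  # exchangeable groups: duplicated data, statistic 0
  t2 <- c(time, time); e2 <- c(event, event)
  g2 <- rep(c("a", "b"), each = 6)
  expect_equal(logrank_p(t2, e2, g2), 1, tolerance = 1e-12)

  # invariance under group relabeling and monotone time transformation
  inst <- rand_surv_instance(5, n = 40)
  g <- factor(inst$x >= 0)
  p1 <- logrank_p(inst$time, inst$event, g)
  expect_equal(logrank_p(inst$time, inst$event, factor(g, levels = rev(levels(g)))),
               p1, tolerance = 1e-12)
  expect_equal(logrank_p(exp(inst$time), inst$event, g), p1, tolerance = 1e-12)

  # power check: strongly separated exponential groups
  set.seed(99)
  ta <- rexp(100, 1); tb <- rexp(100, 0.25)
  expect_lt(logrank_p(c(ta, tb), rep(1, 200), rep(c("a", "b"), each = 100)),
            0.001)
})

test_that("Cox HR is exact on exchangeable groups, reciprocal on swap, and matches a likelihood grid", {
  time <- c(1, 3, 4, 2, 5, 7); event <- c(1, 1, 0, 1, 1, 1)
  t2 <- c(time, time); e2 <- c(event, event)
  g2 <- factor(rep(c("low", "high"), each = 6), levels = c("low", "high"))
  expect_equal(cox_hr(t2, e2, g2)$hr, 1.0, tolerance = 1e-8)

  inst <- rand_surv_instance(11, n = 30)
  g <- factor(ifelse(inst$x >= 0, "high", "low"), levels = c("low", "high"))
  hr1 <- cox_hr(inst$time, inst$event, g)
  swapped <- factor(as.character(g), levels = c("high", "low"))
  expect_equal(cox_hr(inst$time, inst$event, swapped)$hr, 1 / hr1$hr,
               tolerance = 1e-8)

  # 4-patient no-tie example against a brute-force 1-D partial likelihood grid
  t4 <- c(2, 5, 1, 7); e4 <- c(1, 1, 1, 0); z4 <- c(0, 0, 1, 1)
  fit <- cox_hr(t4, e4, factor(ifelse(z4 == 1, "high", "low"),
                               levels = c("low", "high")))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, hand_cox_loglik, numeric(1), time = t4, event = e4, z = z4)
  expect_equal(log(fit$hr), grid[which.max(ll)], tolerance = 1e-3)

  # monotone likelihood: all events in one group is flagged
  mono <- cox_hr(c(1, 2, 3, 4), c(1, 1, 0, 0),
                 factor(c("low", "low", "high", "high"), levels = c("low", "high")))
  expect_true(mono$boundary)
  expect_equal(mono$ci_high, Inf)
})

test_that("Cox recovers a simulated hazard ratio within 3 standard errors", {
  set.seed(17)
  x <- rnorm(500)
  sv <- gen_survival(x, changepoint = 0, hr = 0.5, baseline_rate = 0.2,
                     censoring = 0.3, seed = 170)
  g <- dichotomize(x, 0)
  fit <- survival::coxph(survival::Surv(sv$time, sv$event) ~ g)
  se <- sqrt(fit$var[1, 1])
  hr <- cox_hr(sv$time, sv$event, g)$hr
  expect_equal(log(hr), unname(coef(fit)), tolerance = 1e-8) # same route sanity
  expect_lt(abs(log(hr) - log(0.5)), 3 * se)
})

test_that("RMST reproduces closed forms: sample mean, flat curve, censored hand case", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(as.numeric(rmst(km, 3)), 2.0, tolerance = 1e-12)

  flat <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(as.numeric(suppressWarnings(rmst(flat, 5))), 5.0)
  expect_true(attr(suppressWarnings(rmst(flat, 5)), "extrapolated"))

  # censored case: S = 1 on [0,1), 2/3 on [1,3), 0 at 3
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(as.numeric(rmst(km2, 3)), 1 + 2 * (2 / 3), tolerance = 1e-12)

  # no censoring: RMST at max time equals the arithmetic mean, any n
  for (seed in 1:8) {
    set.seed(seed)
    t <- rexp(sample(5:40, 1))
    km3 <- km_estimate(t, rep(1, length(t)))
    expect_equal(as.numeric(rmst(km3, max(t))), mean(t), tolerance = 1e-12)
  }
})

test_that("RMST difference scan matches the exponential closed form and a bootstrap", {
  set.seed(23)
  n <- 400
  x <- c(rnorm(n / 2, 0), rnorm(n / 2, 4))
  rate <- ifelse(x >= 2, 0.5, 1)
  t <- rexp(n, rate)
  d <- quiet_dataset(x, time = t, event = rep(1L, n))
  scan <- survival_difference_scan(d)
  tau <- attr(scan, "tau")
  i <- which.min(abs(scan$cutoff - 2))
  # exponential RMST: (1 - exp(-rate * tau)) / rate
  truth <- (1 - exp(-0.5 * tau)) / 0.5 - (1 - exp(-1 * tau)) / 1
  se <- (scan$rmst_diff_high[i] - scan$rmst_diff_low[i]) / (2 * qnorm(0.975))
  expect_lt(abs(scan$rmst_diff[i] - truth), 3 * se)

  # identical duplicated groups: difference exactly 0 at every cutoff
  xd <- rep(c(1, 2, 3, 4), each = 4)
  td <- rep(c(2, 5, 3, 7), times = 4)
  dd <- quiet_dataset(xd, time = td, event = rep(1L, 16))
  sc0 <- survival_difference_scan(dd, candidate_cutoffs(dd, min_group = 4))
  expect_equal(sc0$rmst_diff[sc0$cutoff == 3], 0, tolerance = 1e-12)

  # bootstrap SE brackets the asymptotic one at a fixed cutoff
  set.seed(31)
  nb <- 150
  xb <- rnorm(nb); tb <- rexp(nb, ifelse(xb >= 0, 0.5, 1))
  eb <- rbinom(nb, 1, 0.8)
  db <- quiet_dataset(xb, time = tb, event = eb)
  taub <- max(tb)
  at0 <- function(idx) {
    hi <- xb[idx] >= 0
    as.numeric(suppressWarnings(rmst(km_estimate(tb[idx][hi], eb[idx][hi]), taub))) -
      as.numeric(suppressWarnings(rmst(km_estimate(tb[idx][!hi], eb[idx][!hi]), taub)))
  }
  boots <- replicate(300, at0(sample(nb, replace = TRUE)))
  scb <- survival_scan(db)
  ib <- which(scb$cutoff == min(xb[xb >= 0]))
  se_asym <- (scb$rmst_diff_high[ib] - scb$rmst_diff_low[ib]) / (2 * qnorm(0.975))
  expect_lt(abs(sd(boots) - se_asym) / se_asym, 0.5)
})

test_that("survival minimal-p optimizer agrees with the exhaustive scan oracle", {
  for (seed in 1:10) {
    inst <- rand_surv_instance(seed + 300)
    if (sum(inst$event) == 0) next
    d <- quiet_dataset(inst$x, time = inst$time, event = inst$event)
    res <- optimize_survival_significance(d)
    oracle <- oracle_logrank_scan(inst$x, inst$time, inst$event)
    expect_equal(res$statistics$p_logrank, min(oracle$p), tolerance = 1e-10)
    expect_equal(res$cutoff, oracle$cutoff[which(oracle$p == min(oracle$p))[1]])
  }
})

test_that("survival optimizer requires events and survival variables", {
  d <- quiet_dataset(c(1, 2, 3, 4), time = c(1, 2, 3, 4), event = c(0, 0, 0, 0))
  expect_error(optimize_survival_significance(d), "no events")
  d2 <- quiet_dataset(c(1, 2, 3))
  expect_error(survival_scan(d2), "requires survival")
})
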