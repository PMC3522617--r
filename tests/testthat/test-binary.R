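test_that("confusion table handles perfect separation, trivial cutoffs and orientation", {
  d <- quiet_dataset(c(1, 2, 3, 4), outcome = c(0, 0, 1, 1))
  t1 <- confusion_at(d, 3)
  expect_equal(unlist(t1[c("tp", "fn", "tn", "fp")]),
               c(tp = 2L, fn = 0L, tn = 2L, fp = 0L))
  t2 <- confusion_at(d, 0)
  expect_equal(unlist(t2[c("tp", "fp", "tn", "fn")]),
               c(tp = 2L, fp = 2L, tn = 0L, fn = 0L))
  t3 <- confusion_at(d, 3, orientation = "low_positive")
  expect_equal(unlist(t3[c("tp", "fn", "tn", "fp")]),
               c(tp = 0L, fn = 2L, tn = 0L, fp = 2L))
})

test_that("Fisher p matches the hypergeometric closed form and exhaustive enumeration", {
  balanced <- confusion_at(quiet_dataset(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2,
                                           1, 1, 1, 1, 1, 2, 2, 2, 2, 2),
                                         outcome = rep(c(0, 1), each = 10)), 2)
  expect_equal(fisher_p(balanced), 1.0)

  perfect <- list(tp = 10, fp = 0, fn = 0, tn = 10)
  # only the two perfectly separated tables are as extreme: p = 2 / C(20, 10)
  expect_equal(fisher_p(perfect), 2 / choose(20, 10), tolerance = 1e-12)

  # exhaustive oracle: sum hypergeometric probabilities <= observed
  for (seed in 1:10) {
    set.seed(seed)
    tab <- list(tp = sample(0:8, 1), fp = sample(0:8, 1),
                fn = sample(0:8, 1), tn = sample(0:8, 1))
    m <- tab$tp + tab$fn          # column margin (positives)
    n2 <- tab$fp + tab$tn
    k <- tab$tp + tab$fp          # row margin (predicted positive)
    if (m + n2 == 0 || k == 0 || k == m + n2) next
    probs <- dhyper(max(0, k - n2):min(k, m), m, n2, k)
    p_obs <- dhyper(tab$tp, m, n2, k)
    oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    expect_equal(fisher_p(tab), oracle, tolerance = 1e-9)
  }
})

test_that("odds ratio equals the cross-product and the logistic MLE", {
  tab <- list(tp = 10, fp = 2, fn = 3, tn = 15)
  orr <- odds_ratio(tab)
  expect_equal(orr$or, 25.0)
  expect_false(orr$corrected)
  # independent route: logistic regression on the expanded data
  y <- c(rep(1, 10), rep(0, 2), rep(1, 3), rep(0, 15))
  x <- c(rep(1, 12), rep(0, 18))
  fit <- glm(y ~ x, family = binomial())
  expect_equal(log(orr$or), unname(coef(fit)["x"]), tolerance = 1e-6)
  expect_equal(orr$ci_low,
               exp(unname(coef(fit)["x"]) - qnorm(0.975) *
                     sqrt(vcov(fit)["x", "x"])), tolerance = 1e-4)

  flat <- odds_ratio(list(tp = 5, fp = 5, fn = 5, tn = 5))
  expect_equal(flat$or, 1.0)
  expect_true(flat$ci_low < 1 && flat$ci_high > 1)

  zero <- odds_ratio(list(tp = 10, fp = 0, fn = 3, tn = 12))
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or) && zero$or > 1)
})

test_that("Wilson interval matches its closed form at the boundary and center", {
  z <- qnorm(0.975)
  ci0 <- wilson_ci(0, 10)
  expect_equal(ci0[["low"]], 0)
  expect_equal(ci0[["high"]], z^2 / (10 + z^2), tolerance = 1e-12)
  ci1 <- wilson_ci(10, 10)
  expect_equal(ci1[["high"]], 1)
  expect_equal(ci1[["low"]], 10 / (10 + z^2), tolerance = 1e-12)
  # direct formula evaluation at k = 5, n = 10
  p <- 0.5; n <- 10
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(unname(wilson_ci(5, 10)), c(center - half, center + half),
               tolerance = 1e-12)
  expect_error(wilson_ci(1, 0), "trials")
})

test_that("Wilson interval coverage is near nominal in simulation", {
  set.seed(42)
  p <- 0.3; n <- 40
  hits <- replicate(1000, {
    k <- rbinom(1, n, p)
    ci <- wilson_ci(k, n)
    ci[["low"]] <= p && p <= ci[["high"]]
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("minimal-p optimizer finds the perfect split and matches brute force", {
  d <- quiet_dataset(1:10, outcome = rep(c(0, 1), each = 5))
  res <- optimize_binary_significance(d)
  expect_equal(res$cutoff, 6)
  expect_equal(res$statistics$p_fisher, fisher_p(list(tp = 5, fp = 0, fn = 0, tn = 5)))

  for (seed in 1:15) {
    inst <- rand_binary_instance(seed)
    d <- quiet_dataset(inst$x, outcome = inst$y)
    res <- optimize_binary_significance(d, orientation = "high_positive")
    oracle <- oracle_binary_table(inst$x, inst$y == 1)
    expect_equal(res$statistics$p_fisher, min(oracle$p), tolerance = 1e-12)
    expect_equal(res$cutoff, oracle$cutoff[which(oracle$p == min(oracle$p))[1]])
  }
})

test_that("minimal-p ties break toward the lower cutoff", {
  # symmetric data: cutoffs 2 and 3 give mirrored tables with identical p
  d <- quiet_dataset(c(1, 2, 3), outcome = c(0, 1, 0))
  scan <- binary_scan(d, orientation = "high_positive")
  expect_equal(scan$p[scan$cutoff == 2], scan$p[scan$cutoff == 3])
  res <- suppressWarnings(optimize_binary_significance(d, orientation = "high_positive"))
  expect_equal(res$cutoff, 2)
})

test_that("ROC curve has the expected shape, endpoints and orientation symmetry", {
  d <- quiet_dataset(c(1, 2, 3, 4, 5, 6), outcome = c(0, 0, 0, 1, 1, 1))
  roc <- roc_curve(d, orientation = "high_positive")
  expect_true(any(roc$fpr == 0 & roc$sensitivity == 1)) # perfect marker
  expect_equal(attr(roc, "auc"), 1)
  # monotone staircase
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$sensitivity) >= 0))

  flipped <- roc_curve(d, orientation = "low_positive")
  expect_equal(attr(flipped, "auc"), 0, tolerance = 1e-12)

  set.seed(8)
  d0 <- quiet_dataset(rnorm(400), outcome = rbinom(400, 1, 0.5))
  auc <- attr(roc_curve(d0, orientation = "high_positive"), "auc")
  # null AUC ~ 0.5 with SE ~ sqrt(1/(12)) * sqrt(1/n1 + 1/n0)
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / 12) * sqrt(4 / 400))
})

test_that("ROC optimization reproduces hand-computed distances and brute force", {
  # two interior candidates: (sens .9, spec .7) and (sens .8, spec .85)
  pts <- tibble::tibble(cutoff = c(NA, 1, 2, NA),
                        fpr = c(1, 0.3, 0.15, 0),
                        sensitivity = c(1, 0.9, 0.8, 0))
  class(pts) <- c("roc_curve", class(pts))
  # manhattan: J = .6 vs .65 -> cutoff 2; euclidean: .3162 vs .25 -> cutoff 2
  expect_equal(optimize_roc(pts, "manhattan")$cutoff, 2)
  expect_equal(optimize_roc(pts, "euclidean")$cutoff, 2)
  expect_equal(optimize_roc(pts, "euclidean")$statistics$distance, 0.25)

  for (seed in 1:10) {
    inst <- rand_binary_instance(seed + 100)
    d <- quiet_dataset(inst$x, outcome = inst$y)
    scan <- binary_scan(d, orientation = "high_positive")
    oracle <- oracle_binary_table(inst$x, inst$y == 1)
    d_euc <- sqrt((1 - oracle$sens)^2 + (1 - oracle$spec)^2)
    d_man <- (1 - oracle$sens) + (1 - oracle$spec)
    expect_equal(optimize_roc(scan, "euclidean")$cutoff,
                 oracle$cutoff[which(d_euc == min(d_euc))[1]])
    man <- optimize_roc(scan, "manhattan")
    expect_equal(man$cutoff, oracle$cutoff[which(d_man == min(d_man))[1]])
    # the Manhattan winner maximizes Youden's J over the whole grid
    expect_equal(man$statistics$youden, max(oracle$sens + oracle$spec - 1),
                 tolerance = 1e-12)
  }
})

test_that("constrained cutoffs satisfy their guarantee and maximize the complement", {
  d <- quiet_dataset(c(1, 2, 3, 4, 5, 6), outcome = c(0, 0, 0, 1, 1, 1))
  res <- constrained_cutoff(binary_scan(d, orientation = "high_positive"),
                            "sensitivity", 0.9)
  expect_equal(res$cutoff, 4) # the perfectly separating cutoff
  expect_error(constrained_cutoff(binary_scan(d, orientation = "high_positive"),
                                  "sensitivity", 1), "threshold")

  for (seed in 1:10) {
    inst <- rand_binary_instance(seed + 200, n = 50)
    d <- quiet_dataset(inst$x, outcome = inst$y)
    scan <- binary_scan(d, orientation = "high_positive")
    oracle <- oracle_binary_table(inst$x, inst$y == 1)
    ok <- oracle$sens > 0.8
    if (any(ok)) {
      res <- constrained_cutoff(scan, "sensitivity", 0.8)
      expect_gt(res$statistics$sensitivity, 0.8)
      expect_equal(res$statistics$specificity, max(oracle$spec[ok]),
                   tolerance = 1e-12)
    }
    ok2 <- oracle$spec > 0.8
    if (any(ok2)) {
      res2 <- constrained_cutoff(scan, "specificity", 0.8)
      expect_gt(res2$statistics$specificity, 0.8)
      expect_equal(res2$statistics$sensitivity, max(oracle$sens[ok2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("proportion_significant counts sub-alpha candidates", {
  fake <- data.frame(p = c(0.01, 0.2, 0.03, 0.8))
  expect_equal(proportion_significant(fake), 0.5)
  expect_equal(proportion_significant(data.frame(p = rep(1, 5))), 0)
  expect_equal(proportion_significant(data.frame(p = rep(0.001, 5))), 1)
})

test_that("sensitivity/specificity in the scan match an independent recount", {
  inst <- rand_binary_instance(7, n = 60)
  d <- quiet_dataset(inst$x, outcome = inst$y)
  scan <- binary_scan(d, orientation = "high_positive")
  for (i in seq_len(nrow(scan))) {
    hi <- inst$x >= scan$cutoff[i]
    pos <- inst$y == 1
    expect_equal(scan$sensitivity[i], 1 - mean(!hi[pos]))  # 1 - miss rate
    expect_equal(scan$specificity[i], mean(!hi[!pos]))
    expect_true(scan$sens_low[i] <= scan$sensitivity[i])
    expect_true(scan$sens_high[i] >= scan$sensitivity[i])
    expect_true(scan$p[i] >= 0 && scan$p[i] <= 1)
  }
})

test_that("equivocal zone matches a direct recomputation and keeps both guarantees", {
  d <- simulate_marker_dataset(400, seed = 7, surv = FALSE)
  ez <- equivocal_zone(d, sens_threshold = 0.97, spec_threshold = 0.97)
  expect_false(ez$inverted)
  expect_lt(ez$lower, ez$upper)
  expect_gt(ez$fraction_equivocal, 0)

  # independent recomputation on the raw vectors
  x <- d$marker
  pos <- d$outcome == "positive"
  eq <- x >= ez$lower & x < ez$upper
  expect_equal(ez$fraction_equivocal, mean(eq))
  pred <- x[!eq] >= ez$upper
  expect_equal(ez$sensitivity_reliable, mean(pred[pos[!eq]]))
  expect_equal(ez$specificity_reliable, mean(!pred[!pos[!eq]]))
  # on this training sample, both measures exceed the constraint level
  expect_gt(ez$sensitivity_reliable, 0.97)
  expect_gt(ez$specificity_reliable, 0.97)

  # milder constraints shrink the excluded fraction
  ez2 <- suppressWarnings(equivocal_zone(d, sens_threshold = 0.5, spec_threshold = 0.5))
  expect_lte(ez2$fraction_equivocal, ez$fraction_equivocal)
  # over-achieving constraints invert: zone empties with a warning
  expect_warning(ezi <- equivocal_zone(d, sens_threshold = 0.6, spec_threshold = 0.6),
                 "inverted")
  expect_equal(ezi$fraction_equivocal, 0)

  # perfect marker: zone collapses to the separating value
  dp <- quiet_dataset(c(1, 2, 3, 4, 5, 6), outcome = c(0, 0, 0, 1, 1, 1))
  ezp <- equivocal_zone(dp, sens_threshold = 0.9, spec_threshold = 0.9)
  expect_equal(ezp$lower, ezp$upper)
  expect_equal(ezp$fraction_equivocal, 0)
})
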