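test_that("omnibus normality statistic matches an independent implementation", {
  # expected values computed with an independent reference implementation
  # of the same omnibus test (skewness + kurtosis normalization)
  y <- c(1.2, 3.4, -0.5, 2.2, 0.1, 4.5, -1.3, 0.9, 2.8, 5.1, -2.0, 0.3)
  r <- dagostino_pearson(y)
  expect_equal(r$statistic, 0.6982986769, tolerance = 1e-9)
  expect_equal(r$p, 0.7052877958, tolerance = 1e-9)
  expect_equal(r$df, 2)
})

test_that("normality screen is calibrated under the null and powered under skew", {
  pvals <- vapply(1:100, function(s) {
    withr::with_seed(s, dagostino_pearson(rnorm(5000))$p)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
  skewed <- withr::with_seed(7, rexp(5000))
  expect_lt(dagostino_pearson(skewed)$p, 0.001)
})

test_that("small samples are inapplicable, not numbers", {
  r <- dagostino_pearson(c(1, 2, 3, 4, 5))
  expect_true(is.na(r$statistic))
  expect_true(is.na(r$p))
  expect_match(r$note, "inapplicable")
})

test_that("paired t matches the closed form and handles identical samples", {
  x <- c(10, 12, 9); y <- c(11, 15, 10)
  d <- x - y
  t_closed <- mean(d) / (sd(d) / sqrt(3))
  r <- paired_t(x, y)
  expect_equal(r$statistic, t_closed)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-abs(t_closed), 2))
  same <- paired_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
})

test_that("printed cohort contrasts reproduce at the printed precision", {
  ref <- reference_cohort()
  tsi <- paired_t(ref$tsi_baseline, ref$tsi_eut)
  expect_lt(tsi$p, 0.0001)
  map <- paired_t(ref$map_baseline, ref$map_eut)
  expect_lt(map$p, 0.0001)
  po2 <- paired_t(ref$po2_baseline, ref$po2_eut)
  # the published 0.0028 corresponds to the one-tailed value; the two-tailed
  # value is 0.0055, and both are reported
  one_tailed <- po2$p / 2
  expect_equal(round(one_tailed, 4), 0.0028, tolerance = 1e-4)
  expect_equal(round(po2$p, 4), 0.0055, tolerance = 1e-4)
  expect_match(po2$note, "one_tailed_p")
})

test_that("group comparison degrades to inapplicable on all-zero groups", {
  r <- group_t(rep(0, 8), rep(0, 8))
  expect_true(is.na(r$p))
  expect_match(r$note, "inapplicable")
  r2 <- group_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r2$p, t.test(c(1, 2, 3, 4), c(2, 3, 4, 5),
                            var.equal = TRUE)$p.value)
})

test_that("step-down Sidak adjustment is monotone and order-preserving", {
  p <- c(0.04, 0.001, 0.3)
  adj <- holm_sidak(p)
  expect_equal(adj[2], 1 - (1 - 0.001)^3)
  expect_equal(adj[1], max(adj[2], 1 - (1 - 0.04)^2))
  expect_equal(adj[3], max(adj[1], 1 - (1 - 0.3)^1))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p))
})

test_that("repeated-measures ANOVA matches its paired-t special case", {
  withr::with_seed(31, {
    m <- cbind(a = rnorm(8, 10), b = rnorm(8, 12))
  })
  res <- rm_anova(m)
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(res$omnibus$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$omnibus$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$posthoc$p_raw, tt$p.value)
  expect_equal(res$posthoc$adjust_method, "holm-sidak")
})

test_that("identical conditions yield a null ANOVA result", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- rm_anova(m)
  expect_equal(res$omnibus$statistic, 0)
  expect_equal(res$omnibus$p, 1)
  expect_true(all(res$posthoc$p_adj == 1))
  expect_error(rm_anova(cbind(c(1, NA), c(2, 3))), "complete")
})

test_that("a simulated amplitude collapse is significant in both channels", {
  # pulse amplitudes (dB) from the three-window analysis of four animals
  amps <- lapply(1:4, function(s) {
    an <- analyze_animal(simulate_animal(animal_config(seed = 40 + s),
                                         abp_fs = 10), align = FALSE)
    an$pulse
  })
  amps <- dplyr::bind_rows(amps)
  for (ch in c("ABP", "O2Hb")) {
    m <- cbind(
      bsl = amps$amp_db[amps$window == "pre" & amps$channel == ch],
      eut = amps$amp_db[amps$window == "during" & amps$channel == ch])
    res <- rm_anova(m)
    expect_lt(res$posthoc$p_adj, 0.05)
    expect_lt(mean(m[, "eut"]), mean(m[, "bsl"]))
  }
})
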