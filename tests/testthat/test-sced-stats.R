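test_that("kendall_s matches direct pair enumeration", {
  expect_identical(kendall_s(c(1, 2, 3)), 3L)
  expect_identical(kendall_s(c(5, 5, 5)), 0L)
  expect_identical(kendall_s(c(2, 1, 3, 0)), -2L)
  expect_error(kendall_s(1), class = "scedrink_invalid_input")
  set.seed(11)
  for (i in 1:25) {
    x <- sample(0:5, sample(2:9, 1), replace = TRUE)
    expect_identical(kendall_s(x), oracle_kendall_s(x))
  }
})

test_that("pairwise_s_between counts signed nonoverlap", {
  expect_identical(pairwise_s_between(c(1, 1), c(2, 2)), 4L)
  expect_identical(pairwise_s_between(c(1, 2), c(1, 2)), 0L)
  expect_identical(pairwise_s_between(3, 1), -1L)
  expect_error(pairwise_s_between(numeric(0), 1),
               class = "scedrink_invalid_input")
})

test_that("tau_u reproduces worked examples and the oracle on small series", {
  r <- tau_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$s_ab, 9L)
  expect_identical(r$s_trend_a, 3L)
  expect_equal(r$tau_u, 6 / 9)
  expect_equal(tau_u(rep(5, 5), rep(9, 5))$tau_u, 1)
  expect_equal(tau_u(c(1, 2), c(1, 2))$tau_u, -0.25)
  expect_error(tau_u(c(1), c(2, 3)), class = "scedrink_invalid_input")

  set.seed(7)
  for (i in 1:60) {
    n_a <- sample(2:6, 1)
    n_b <- sample(1:(8 - n_a), 1)
    a <- sample(0:4, n_a, replace = TRUE)
    b <- sample(0:4, n_b, replace = TRUE)
    r <- tau_u(a, b, p_method = "normal_approx")
    expect_identical(r$s_ab, oracle_s_between(a, b))
    expect_identical(r$s_trend_a, oracle_kendall_s(a))
    expect_equal(r$tau_u, oracle_tau_u(a, b))
    expect_true(abs(r$tau_ab) <= 1)
    expect_true(abs(r$s_ab) <= n_a * n_b)
    expect_true(abs(r$s_trend_a) <= n_a * (n_a - 1) / 2)
    expect_identical(r$exceeds_unit_range, abs(r$tau_u) > 1)
    # range bound of the corrected index
    expect_lte(abs(r$tau_u), 1 + (n_a - 1) / (2 * n_b))
  }
})

test_that("tau_u is translation invariant and monotone in an A2 shift", {
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    r0 <- tau_u(a, b, p_method = "normal_approx")
    r1 <- tau_u(a + 3.7, b + 3.7, p_method = "normal_approx")
    expect_equal(r1$tau_u, r0$tau_u)
    expect_equal(r1$s_ab, r0$s_ab)
    expect_equal(r1$p_value, r0$p_value)
    prev <- r0$tau_u
    for (shift in c(0.5, 2, 10)) {
      cur <- tau_u(a, b + shift, p_method = "normal_approx")$tau_u
      expect_gte(cur, prev)
      prev <- cur
    }
  }
})

test_that("permutation p agrees with exhaustive enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(tau_u(a, b)$p_value, oracle_perm_p(a, b))
  a <- c(2, 5, 1, 4); b <- c(6, 3, 7)
  expect_equal(tau_u(a, b)$p_value, oracle_perm_p(a, b))
  # Monte-Carlo path approximates the exact answer
  r_mc <- tau_u(a, b, exact_limit = 1L, n_permutations = 20000L, seed = 5)
  expect_lt(abs(r_mc$p_value - oracle_perm_p(a, b)), 0.02)
  # all-tie null
  expect_equal(tau_u(rep(0, 3), rep(0, 3), variant = "AvB")$p_value, 1)
  # full nonoverlap is significant under either method
  expect_lte(tau_u(rep(5, 5), rep(9, 5))$p_value, 0.05)
  expect_lte(tau_u(rep(5, 5), rep(9, 5),
                   p_method = "normal_approx")$p_value, 0.05)
})

test_that("permutation p is reproducible under a fixed seed", {
  a <- rnorm(6, 0, 1); b <- rnorm(6, 1, 1)
  r1 <- tau_u(a, b, exact_limit = 1L, seed = 99, n_permutations = 2000)
  r2 <- tau_u(a, b, exact_limit = 1L, seed = 99, n_permutations = 2000)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("unknown variants and p methods are configuration errors", {
  expect_error(tau_u(1:3, 4:6, variant = "bogus"),
               class = "scedrink_config_error")
  r <- tau_u(1:3, 4:6, p_method = "normal_approx")
  expect_error(tau_p_value(r, method = "bootstrap"),
               class = "scedrink_config_error")
  expect_error(tau_p_value(r, n_permutations = 10),
               class = "scedrink_config_error")
})

test_that("effect-size bands follow the published cut points", {
  expect_identical(classify_effect_size(0.72), "large")
  expect_identical(classify_effect_size(0.68), "moderate")
  expect_identical(classify_effect_size(0), "very_low")
  expect_identical(classify_effect_size(0.25), "very_low")
  expect_identical(classify_effect_size(0.26), "low")
  expect_identical(classify_effect_size(0.5), "moderate")
  expect_identical(classify_effect_size(0.9), "very_large")
  expect_identical(classify_effect_size(-0.95), "very_large")
  expect_identical(classify_effect_size(1.2), "very_large")
  expect_error(classify_effect_size(Inf), class = "scedrink_invalid_input")
})

test_that("assessment series validation enforces the instrument invariants", {
  expect_error(assessment_series("P1", "fma_ue", 1:2, c("A1", "A1"),
                                 c(10, 70)),
               "ceiling 66", class = "scedrink_invalid_input")
  expect_error(assessment_series("P1", "arat", 1:2, c("A1", "A1"),
                                 c(10, 58)),
               class = "scedrink_invalid_input")
  expect_error(assessment_series("P1", "grip_strength", 1:2, c("A1", "A1"),
                                 c(10, -1)),
               class = "scedrink_invalid_input")
  expect_error(assessment_series("P1", "fma_ue", c(1, 1), c("A1", "A1"),
                                 c(10, 10)),
               class = "scedrink_invalid_input")
  expect_error(assessment_series("P1", "fma_ue", 1:2, c("A2", "A1"),
                                 c(10, 10)),
               class = "scedrink_invalid_input")
  s <- make_series(c(15, 15, 14), c(20, 21), outcome = "fma_ue")
  expect_s3_class(s, "assessment_series")
  expect_equal(phase_values(s, "A1"), c(15, 15, 14))
})

test_that("mcid_change scales the median delta against the band", {
  band <- mcid_band("arat", 6, 6, "points", 1)
  s <- make_series(c(10, 10, 10), c(16, 16, 16), outcome = "arat")
  ch <- mcid_change(s, band)
  expect_equal(ch$delta, 6)
  expect_equal(ch$percent_of_mcid, 100)
  expect_true(ch$reached_lower_mcid)
  expect_true(ch$reached_upper_mcid)

  band_f <- default_mcid_bands()$fma_ue
  s2 <- make_series(c(50, 50, 50), c(54, 54, 54), outcome = "fma_ue")
  ch2 <- mcid_change(s2, band_f)
  expect_equal(ch2$percent_of_mcid, 100 * 4 / 4.25, tolerance = 1e-10)
  expect_false(ch2$reached_lower_mcid)

  s3 <- make_series(c(10, 10), c(10, 10), outcome = "arat")
  ch3 <- mcid_change(s3, band)
  expect_equal(ch3$percent_of_mcid, 0)
  expect_false(ch3$reached_lower_mcid)
  expect_false(ch3$reached_upper_mcid)

  # lower-is-better outcomes are signed by improvement direction
  band_mt <- default_mcid_bands()$movement_time
  s4 <- make_series(c(12, 12, 13), c(9, 9.5, 9), outcome = "movement_time")
  ch4 <- mcid_change(s4, band_mt)
  expect_equal(ch4$delta, -3)
  expect_equal(ch4$percent_of_mcid, 100 * 3 / 2.5)
  expect_true(ch4$reached_lower_mcid)
  expect_false(ch4$reached_upper_mcid)

  # even-count medians are midpoints of the central pair
  s5 <- make_series(c(1, 2, 3, 4), c(5, 6, 7, 8), outcome = "grip_strength")
  ch5 <- mcid_change(s5, default_mcid_bands()$grip_strength)
  expect_equal(ch5$median_a1, 2.5)
  expect_equal(ch5$median_a2, 6.5)

  expect_error(mcid_change(s5, band), class = "scedrink_config_error")
  s6 <- assessment_series("P1", "arat", 1:2, c("A1", "A1"), c(1, 2))
  expect_error(mcid_change(s6, band), "A2",
               class = "scedrink_invalid_input")
})

test_that("reached_upper implies reached_lower for any band", {
  set.seed(3)
  band <- default_mcid_bands()$fma_ue
  for (i in 1:20) {
    a1 <- sample(0:30, 3); a2 <- sample(0:66, 3)
    ch <- mcid_change(make_series(a1, a2, outcome = "fma_ue"), band)
    expect_true(!ch$reached_upper_mcid || ch$reached_lower_mcid)
    expect_equal(ch$delta, ch$median_a2 - ch$median_a1)
  }
})

test_that("phase descriptives summarise level, range and trend sign", {
  s <- make_series(c(15, 15, 14, 15, 15), c(20, 21), outcome = "fma_ue")
  d <- phase_descriptives(s, "A1")
  expect_equal(d$median, 15)
  expect_equal(d$trend_sign, 0L) # +2 and -2 pairs cancel
  expect_true(d$trend_defined)

  s2 <- make_series(c(1, 2, 3, 4, 5), c(6, 7))
  expect_equal(phase_descriptives(s2, "A1")$trend_sign, 1L)

  s3 <- make_series(c(4, 3), c(9))
  d3 <- phase_descriptives(s3, "A2")
  expect_equal(d3$n, 1L)
  expect_equal(d3$median, 9)
  expect_equal(d3$trend_sign, 0L)
  expect_false(d3$trend_defined)

  expect_error(phase_descriptives(s3, "FU"), class = "scedrink_invalid_input")
})

test_that("trend-B variants are available and consistent with pair counts", {
  a <- c(3, 1, 4, 1); b <- c(5, 9, 2, 6)
  s_ab <- oracle_s_between(a, b)
  expect_equal(tau_u(a, b, variant = "AvB",
                     p_method = "normal_approx")$tau_u, s_ab / 16)
  expect_equal(tau_u(a, b, variant = "AvB+trendB",
                     p_method = "normal_approx")$tau_u,
               (s_ab + oracle_kendall_s(b)) / 16)
  expect_equal(tau_u(a, b, variant = "AvB+trendB-trendA",
                     p_method = "normal_approx")$tau_u,
               (s_ab + oracle_kendall_s(b) - oracle_kendall_s(a)) / 16)
})
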