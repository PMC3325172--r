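test_that("draw_rates matches the gamma rate law", {
  m <- gamma_rate_model(alpha = 1, R = 10)
  r <- draw_rates(1e5, m, seed = 11)
  # mean R within 3 standard errors (sd of gamma(1) mean = R/sqrt(n))
  expect_lt(abs(mean(r) - 10), 3 * 10 / sqrt(1e5))
  # gamma(1) = exponential: distributional agreement
  expect_gt(ks.test(r, pexp, rate = 1 / 10)$p.value, 1e-3)

  # large alpha: variance R^2/alpha, near-degenerate at R
  r2 <- draw_rates(1e5, gamma_rate_model(1e4, 10), seed = 12)
  expect_lt(abs(var(r2) - 100 / 1e4) / (100 / 1e4), 0.1)
  expect_lt(max(abs(r2 - 10)), 1)

  expect_error(draw_rates(0, m), class = "ss_parameter_error")
  expect_error(draw_rates(10, list(alpha = 1)),
               class = "ss_parameter_error")
  expect_error(gamma_rate_model(-1, 10), class = "ss_parameter_error")
})

test_that("simulate_constant_rate produces i.i.d. gamma ISIs", {
  tr <- simulate_constant_rate(1e5 + 1, kappa = 1, rate = 10, seed = 21)
  isi <- compute_isis(tr)$intervals_ms
  expect_equal(length(isi), 1e5)
  expect_lt(abs(mean(isi) - 100), 3 * 100 / sqrt(1e5))  # mean ISI = 1/rate

  # shape recovery by an independent gamma MLE
  tr2 <- simulate_constant_rate(1e5 + 1, kappa = 3.49, rate = 10, seed = 22)
  khat <- gamma_mle_shape(compute_isis(tr2)$intervals_ms)
  expect_lt(abs(khat - 3.49), 0.05)
})

test_that("per-interval superstatistics realizes the beta-2 marginal", {
  al <- 1.91; ka <- 2; R <- 10
  tr <- simulate_superstat(1e5 + 1, ka, gamma_rate_model(al, R), seed = 31)
  isi <- compute_isis(tr)$intervals_ms
  tau <- al / ((R / 1000) * ka)
  ks <- suppressWarnings(
    ks.test(isi, function(q) pbeta2_oracle(q, al, ka, tau)))
  expect_gt(ks$p.value, 1e-3)
  # Kolmogorov distance shrinks ~ n^{-1/2}
  expect_lt(unname(ks$statistic), 3 * 1.63 / sqrt(1e5))

  # true rates stored and consistent with the rate law
  expect_equal(length(tr$true_rates), 1e5)
  expect_lt(abs(mean(tr$true_rates) - R), 3 * R / sqrt(al * 1e5))
})

test_that("blockwise scheme keeps the same marginal ISI law", {
  # compare each scheme against the closed-form beta-2 CDF; blockwise ISIs
  # are correlated within blocks, so its KS noise scales with the number of
  # independent rate draws (blocks), not the number of ISIs
  al <- 1.91; ka <- 2; R <- 10; tau <- al / ((R / 1000) * ka)
  cdf <- function(q) pbeta2_oracle(q, al, ka, tau)
  m <- gamma_rate_model(al, R)
  a <- compute_isis(simulate_superstat(5e4, ka, m, seed = 41))$intervals_ms
  b <- compute_isis(simulate_superstat(5e4, ka, m, scheme = "blockwise",
                                       block_size = 100,
                                       seed = 42))$intervals_ms
  stat_a <- suppressWarnings(unname(ks.test(a, cdf)$statistic))
  stat_b <- suppressWarnings(unname(ks.test(b, cdf)$statistic))
  expect_lt(stat_a, 1.63 / sqrt(length(a)))
  expect_lt(stat_b, 1.63 / sqrt(5e4 / 100))   # ~500 independent blocks
  expect_error(simulate_superstat(100, ka, m, scheme = "bogus"),
               class = "ss_usage_error")
})

test_that("large-alpha superstatistics degenerates to constant rate", {
  a <- compute_isis(simulate_superstat(5e4, 2, gamma_rate_model(1e4, 10),
                                       seed = 51))$intervals_ms
  b <- compute_isis(simulate_constant_rate(5e4, 2, 10,
                                           seed = 52))$intervals_ms
  stat <- suppressWarnings(unname(ks.test(a, b)$statistic))
  expect_lt(stat, ks_crit_1pct(length(a), length(b)))
})

test_that("discrete mixtures behave as rate superpositions", {
  mix <- discrete_rate_model(c(2, 20), c(0.5, 0.5))
  tr <- simulate_discrete_mixture(5e4, 1, mix, seed = 61)
  expect_setequal(unique(tr$true_rates), c(2, 20))
  expect_lt(abs(mean(tr$true_rates) - 11), 3 * 9 / sqrt(5e4 - 1))

  # single rate degenerates to the constant-rate law
  a <- compute_isis(simulate_discrete_mixture(
    5e4, 2, discrete_rate_model(10), seed = 62))$intervals_ms
  b <- compute_isis(simulate_constant_rate(5e4, 2, 10,
                                           seed = 63))$intervals_ms
  stat <- suppressWarnings(unname(ks.test(a, b)$statistic))
  expect_lt(stat, ks_crit_1pct(length(a), length(b)))

  # far-tail semilog slope approaches kappa * xi_low (slowest component):
  # numeric log-derivative of the exact compound density at large T
  gen <- gamma_generator(1)
  Tg <- seq(2000, 4000, by = 500)
  lp <- log(mixture_pdf(Tg, gen, mix))
  slopes <- diff(lp) / diff(Tg)
  expect_lt(max(abs(slopes - (-1 * 0.002))) / 0.002, 0.01)

  expect_error(discrete_rate_model(numeric(0)),
               class = "ss_parameter_error")
})

test_that("identical seeds reproduce identical trains bit-for-bit", {
  m <- gamma_rate_model(1.5, 20)
  t1 <- simulate_superstat(2000, 2, m, seed = 71)
  t2 <- simulate_superstat(2000, 2, m, seed = 71)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$true_rates, t2$true_rates)
  t3 <- simulate_superstat(2000, 2, m, seed = 72)
  expect_false(identical(t1$times, t3$times))
})

test_that("time-averaged rates follow the length-biased limit", {
  # drawing a fresh rate per interval length-biases time toward slow rates:
  # spikes/duration -> 1/E[T] = (alpha-1) R / alpha (alpha > 1), NOT R.
  # The ensemble mean of the rate draws themselves is R.
  al <- 3; R <- 10
  m <- gamma_rate_model(al, R)
  for (sc in c("per-interval", "blockwise")) {
    tr <- simulate_superstat(1e5, 2, m, scheme = sc, seed = 81)
    expect_lt(abs(mean_rate(tr) - (al - 1) * R / al) / R, 0.05)
    expect_lt(abs(mean(tr$true_rates) - R) / R, 0.05)
  }
  trc <- simulate_constant_rate(1e5, 2, 10, seed = 82)
  expect_lt(abs(mean_rate(trc) - 10) / 10, 0.02)
})

test_that("spike train files round-trip with their sidecars", {
  dir <- withr::local_tempdir()
  tr <- simulate_superstat(500, 2, gamma_rate_model(1.91, 10), seed = 91)
  f <- file.path(dir, "train.txt")
  write_spike_train(tr, f)
  back <- read_spike_train(f)
  expect_equal(back$times, tr$times, tolerance = 1e-8)
  expect_equal(back$true_rates, tr$true_rates, tolerance = 1e-7)
  expect_equal(back$metadata$alpha, 1.91)
})
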