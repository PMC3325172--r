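test_that("generator entropy S(kappa) matches quadrature and peaks at 1", {
  expect_equal(generator_entropy_S(1), 1)   # unit-mean exponential
  for (ka in c(0.5, 2, 3.49, 10)) {
    oracle <- entropy_gamma_quad(ka, rate = ka)
    expect_lt(abs(generator_entropy_S(ka) - oracle), 1e-8)
  }
  # the exponential maximizes entropy among unit-mean laws on (0, Inf):
  # S increases on (0, 1), decreases on (1, Inf) -- so more regular firing
  # (kappa > 1) always carries less interval uncertainty
  scan_up <- vapply(seq(0.05, 1, length.out = 20), generator_entropy_S,
                    numeric(1))
  expect_true(all(diff(scan_up) > 0))
  scan_down <- vapply(seq(1, 50, length.out = 40), generator_entropy_S,
                      numeric(1))
  expect_true(all(diff(scan_down) < 0))
})

test_that("rate entropy matches the exponential case and quadrature", {
  expect_equal(rate_entropy(gamma_rate_model(1, 10)), 1 + log(0.01))
  set.seed(41)
  for (i in 1:5) {
    al <- runif(1, 0.5, 5); R <- runif(1, 2.5, 50)
    oracle <- entropy_quad(function(x) {
      dgamma(x, shape = al, rate = al / (R / 1000), log = TRUE)
    })
    expect_lt(abs(rate_entropy(gamma_rate_model(al, R)) - oracle), 1e-8)
  }
  # increasing in R at fixed alpha (scale shift adds log factor)
  expect_equal(rate_entropy(gamma_rate_model(2, 20)) -
                 rate_entropy(gamma_rate_model(2, 10)), log(2))
})

test_that("conditional entropy equals S - E[log xi] and the double integral", {
  # kappa = 1, alpha = 1, R_ms = 1 (R = 1000 spikes/s): 1 - psi(1)
  expect_equal(conditional_entropy(gamma_generator(1),
                                   gamma_rate_model(1, 1000)),
               1 - digamma(1), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:3) {
    ka <- runif(1, 0.5, 4); al <- runif(1, 0.5, 4); R <- runif(1, 2.5, 50)
    oracle <- cond_entropy_quad(ka, al, R / 1000)
    expect_lt(abs(conditional_entropy(gamma_generator(ka),
                                      gamma_rate_model(al, R)) - oracle),
              1e-6)
  }
  # decreasing in R at fixed alpha, kappa
  expect_equal(conditional_entropy(gamma_generator(2),
                                   gamma_rate_model(2, 10)) -
                 conditional_entropy(gamma_generator(2),
                                     gamma_rate_model(2, 20)), log(2))
})

test_that("ISI entropy limits, unit shifts, and MI positivity hold", {
  gen <- gamma_generator(2)
  # alpha -> Inf: H[T] approaches the constant-rate gamma entropy
  big <- beta2_from_rate_model(gen, gamma_rate_model(1e6, 10))
  expect_equal(isi_entropy(big), generator_entropy_S(2) - log(0.01),
               tolerance = 1e-4)

  # unit change: H[T in s] = H[T in ms] - log 1000
  p <- beta2_params(1.91, 2, 30)
  p_s <- beta2_params(1.91, 2, 30 / 1000)
  expect_equal(isi_entropy(p_s), isi_entropy(p) - log(1000),
               tolerance = 1e-8)

  # MI = H[T] - H[T|Xi] >= 0 across randomized parameters
  set.seed(43)
  for (i in 1:8) {
    ka <- runif(1, 0.5, 4); al <- runif(1, 0.3, 6); R <- runif(1, 2.5, 50)
    expect_gte(mutual_information(gamma_generator(ka),
                                  gamma_rate_model(al, R)), -1e-6)
  }
})

test_that("MI vanishes for degenerate rates and grows with rate spread", {
  gen <- gamma_generator(2)
  expect_lt(mutual_information(gen, gamma_rate_model(1e6, 10)), 1e-4)
  # smaller alpha = broader rate distribution = more information
  mis <- vapply(c(8, 4, 2, 1, 0.5), function(a) {
    mutual_information(gen, gamma_rate_model(a, 10))
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("MI is negatively correlated with H[T|Xi] at fixed H[T]", {
  # a population with anti-correlated (kappa, alpha) and near-constant H[T],
  # as the recorded cohort displays; the per-neuron mean rate R is solved so
  # that every member sits exactly on the H[T] contour
  target <- isi_entropy(beta2_from_rate_model(gamma_generator(2.5),
                                              gamma_rate_model(2, 10)))
  fam <- list(c(1.2, 6), c(2, 2.5), c(3, 1.2), c(4.5, 0.7))
  rows <- lapply(fam, function(ak) {
    al <- ak[1]; ka <- ak[2]
    R <- exp(uniroot(function(logR) {
      isi_entropy(beta2_from_rate_model(gamma_generator(ka),
                                        gamma_rate_model(al, exp(logR)))) -
        target
    }, log(c(0.1, 1000)), tol = 1e-12)$root)
    rep_ <- entropy_report(gamma_generator(ka), gamma_rate_model(al, R))
    c(H_cond = rep_$H_cond, MI = rep_$MI, H_isi = rep_$H_isi)
  })
  m <- do.call(rbind, rows)
  expect_lt(max(abs(m[, "H_isi"] - target)), 1e-8)
  expect_gt(diff(range(m[, "H_cond"])), 0.1)  # the family is not degenerate
  expect_lt(cor(m[, "H_cond"], m[, "MI"]), -0.999)
})

test_that("entropy reports are unit- and base-consistent", {
  gen <- gamma_generator(2)
  m <- gamma_rate_model(1.91, 10)
  r_nats <- entropy_report(gen, m)
  r_bits <- entropy_report(gen, m, log_base = "2")
  expect_equal(r_bits$MI * log(2), r_nats$MI, tolerance = 1e-10)
  expect_equal(r_nats$MI, r_nats$H_isi - r_nats$H_cond)
  expect_equal(r_nats$isi_unit, "ms")

  # changing the ISI unit shifts H[T] and H[T|Xi] equally: MI invariant
  m_any <- gamma_rate_model(1.5, 20)
  mi_ms <- mutual_information(gen, m_any)
  p_s <- beta2_params(1.5, 2, beta2_from_rate_model(gen, m_any)$tau / 1000)
  hc_s <- conditional_entropy(gen, m_any) - log(1000)
  expect_equal(isi_entropy(p_s) - hc_s, mi_ms, tolerance = 1e-7)
})
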