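test_that("MFE yields the exponential rate law with tail exponent 2", {
  sol <- solve_mfe(10)
  expect_equal(sol$rate_model$alpha, 1)
  expect_equal(sol$rate_model$R, 10)
  expect_equal(sol$achieved_H_rate, 1 + log(0.01))
  # compound ISI law then has eta = alpha + 1 = 2 for any kappa
  p <- beta2_from_rate_model(gamma_generator(2), sol$rate_model)
  expect_equal(p$eta, 2)
})

test_that("CMFE inverts the conditional-entropy constraint exactly", {
  gen <- gamma_generator(2)
  for (al_star in c(1.2, 1.91, 5)) {
    I <- conditional_entropy(gen, gamma_rate_model(al_star, 10))
    sol <- solve_cmfe(10, I, gen)
    expect_lt(abs(sol$rate_model$alpha - al_star), 1e-8)
    expect_lt(abs(sol$achieved_I - I), 1e-10)   # active constraint
    expect_equal(sol$achieved_R, 10)
  }

  # loose bound: clamp to the MFE solution alpha = 1
  I_loose <- conditional_entropy(gen, gamma_rate_model(1, 10)) + 0.5
  expect_equal(solve_cmfe(10, I_loose, gen)$rate_model$alpha, 1)
  # CMFE contains MFE: the bound computed at alpha = 1 returns alpha = 1
  I1 <- conditional_entropy(gen, gamma_rate_model(1, 10))
  expect_equal(solve_cmfe(10, I1, gen)$rate_model$alpha, 1)

  # psi(alpha) - log(alpha) increases toward 0: the root is unique
  alphas <- 10^seq(-2, 3, length.out = 30)
  g <- digamma(alphas) - log(alphas)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < 0))

  # bound below the infimum S - log R_ms is infeasible
  expect_error(solve_cmfe(10, generator_entropy_S(2) - log(0.01) - 0.01,
                          gen),
               class = "ss_infeasible_error")
})

test_that("grid maximization reproduces the closed-form solutions", {
  # rate-only constraint: exponential with mean R
  g <- grid_maxent(10)
  truth <- dgamma(g$grid$xi_ms, shape = 1, rate = 1 / 0.01)
  expect_lt(max(abs(g$grid$k - truth)) / max(truth), 1e-4)
  expect_lt(abs(g$achieved_R / 10 - 1), 1e-8)

  # both constraints: gamma(alpha*, R) for alpha* in {1.5, 2, 3}
  gen <- gamma_generator(2)
  for (al_star in c(1.5, 2, 3)) {
    I <- conditional_entropy(gen, gamma_rate_model(al_star, 10))
    gs <- grid_maxent(10, I, gen)
    truth <- dgamma(gs$grid$xi_ms, shape = al_star, rate = al_star / 0.01)
    expect_lt(max(abs(gs$grid$k - truth)) / max(truth), 1e-4)
    expect_lt(abs(gs$achieved_I - I), 1e-8)
    expect_lt(abs(gs$achieved_R / 10 - 1), 1e-8)
    expect_lt(abs(gs$multipliers$lambda2 - (al_star - 1)), 1e-3)
  }

  # no constraints: uniform over the grid
  gu <- grid_maxent(NULL)
  expect_lt(diff(range(gu$grid$k)) / mean(gu$grid$k), 1e-12)
})

test_that("the grid solution is a local entropy maximum", {
  gen <- gamma_generator(2)
  I <- conditional_entropy(gen, gamma_rate_model(2, 10))
  gs <- grid_maxent(10, I, gen, grid_spec = list(n = 1500))
  w <- gs$grid$weight; k <- gs$grid$k; xi <- gs$grid$xi_ms
  S <- generator_entropy_S(2)
  H <- function(kk) -sum(w * kk * log(pmax(kk, 1e-300)))
  # random feasible directions: perturb only well-supported grid points
  # (all three constraints are linear in k, so projection onto their null
  # space keeps the perturbed k exactly feasible)
  sel <- which(k > 1e-3 * max(k))
  A <- rbind(w[sel], (w * xi)[sel], (w * (S - log(xi)))[sel])
  Q <- qr.Q(qr(t(A)))
  set.seed(51)
  n_checked <- 0
  for (i in 1:5) {
    d_sel <- rnorm(length(sel))
    d_sel <- d_sel - Q %*% (t(Q) %*% d_sel)
    d <- numeric(length(k)); d[sel] <- d_sel / sqrt(sum(d_sel^2))
    eps <- 1e-3 * min(k[sel])
    kk <- k + eps * d
    if (any(kk <= 0)) next
    n_checked <- n_checked + 1
    expect_lte(H(kk), H(k) + 1e-12)
  }
  expect_gte(n_checked, 3)
})

test_that("the minimization duality returns the same gamma member", {
  gen <- gamma_generator(2)
  for (al_star in c(1.5, 3)) {
    H0 <- rate_entropy(gamma_rate_model(al_star, 10))
    d <- duality_check(10, H0, gen)
    expect_lt(abs(d$alpha_dual - al_star), 1e-6)
    expect_lt(d$gap, 1e-6)
  }
  # boundary: bounds generated at alpha = 1
  d1 <- duality_check(10, rate_entropy(gamma_rate_model(1, 10)), gen)
  expect_equal(d1$alpha_dual, 1)
  expect_equal(d1$alpha_cmfe, 1)
  # slack bounds: a gap is reported, not asserted away
  ds <- duality_check(10, rate_entropy(gamma_rate_model(2, 10)) - 0.3, gen)
  expect_true(is.finite(ds$gap))
  # infeasible entropy bound
  expect_error(duality_check(10, rate_entropy(gamma_rate_model(1, 10)) + 1,
                             gen),
               class = "ss_infeasible_error")
})

test_that("mmi_contrast separates discrete from gamma rate codes", {
  mix <- mmi_contrast(1, discrete_rate_model(c(2, 20), c(0.5, 0.5)),
                      n_spikes = 5e4, seed = 61)
  expect_equal(mix$predicted, "exponential")
  # the binned regression window spans the knee between the two exponential
  # components, so semilog describes the tail better than loglog even
  # though neither always clears 0.95
  expect_gt(mix$classification$cd_semilog, mix$classification$cd_loglog)
  expect_false(mix$classification$verdict == "power_law")

  sup <- mmi_contrast(2, gamma_rate_model(1.91, 10), n_spikes = 5e4,
                      seed = 62)
  expect_equal(sup$predicted, "power_law")
  expect_equal(sup$classification$verdict, "power_law")

  one <- mmi_contrast(2, discrete_rate_model(10), n_spikes = 2e4, seed = 63)
  expect_equal(one$predicted, "exponential")
  expect_gt(one$classification$cd_semilog, 0.95)
})
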