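#' Maximization of firing-rate entropy (MFE) under a mean-rate constraint
#'
#' Maximizing \eqn{H[\Xi] = -\int k \log k \, d\xi} subject to normalization
#' and \eqn{\int k(\xi) \xi \, d\xi = R} yields an exponential rate law with
#' mean R (a gamma law with shape 1), whose compound ISI distribution has the
#' unique power-law tail exponent \eqn{\eta = 2}.
#'
#' @param R_bound mean-rate constraint, spikes/s.
#' @return a \code{maxent_solution}: list with \code{family}
#'   (\code{"exponential"}), \code{rate_model}, \code{achieved_H_rate} (nats,
#'   rate in 1/ms), \code{achieved_R}, \code{multipliers}.
#' @examples
#' solve_mfe(10)$rate_model$alpha  # 1
#' @export
solve_mfe <- function(R_bound) {
  .check_pos(R_bound, "R_bound")
  R_ms <- hz_to_per_ms(R_bound)
  model <- gamma_rate_model(alpha = 1, R = R_bound)
  structure(list(family = "exponential", rate_model = model,
                 achieved_H_rate = 1 + log(R_ms),
                 achieved_R = R_bound, achieved_I = NA_real_,
                 multipliers = list(lambda0 = log(R_ms) - 1,
                                    lambda1 = 1 / R_ms, lambda2 = 0)),
            class = "maxent_solution")
}

#' Conditional maximization of firing-rate entropy (CMFE)
#'
#' Maximizes the firing-rate entropy under two constraints: mean rate
#' \eqn{= R} and conditional response entropy \eqn{H[T|\Xi] \le I}. The
#' solution is a gamma rate law with mean R whose shape alpha solves
#' \deqn{S(\kappa) - \psi(\alpha) - \log(R_{ms}/\alpha) = I}
#' (the observable form of the stationarity condition; the left side is
#' \eqn{H[T|\Xi]} of the gamma family, strictly decreasing in alpha). When
#' the bound is loose (the root would be < 1) the entropy constraint is
#' inactive and the MFE solution alpha = 1 is returned.
#'
#' @param R_bound mean-rate constraint, spikes/s.
#' @param I_bound conditional-response-entropy bound, nats (ISIs in ms).
#' @param generator a \code{\link{gamma_generator}} (its shape kappa sets S).
#' @return a \code{maxent_solution} with \code{family = "gamma"} (or
#'   \code{"exponential"} when clamped to alpha = 1).
#' @export
solve_cmfe <- function(R_bound, I_bound, generator) {
  .check_pos(R_bound, "R_bound")
  if (!inherits(generator, "gamma_generator")) {
    ss_stop("`generator` must be a gamma_generator", "ss_parameter_error")
  }
  if (!is.numeric(I_bound) || length(I_bound) != 1L || !is.finite(I_bound)) {
    ss_stop("`I_bound` must be a finite number", "ss_parameter_error")
  }
  R_ms <- hz_to_per_ms(R_bound)
  S <- generator_entropy_S(generator$kappa)
  resid <- function(log_alpha) {
    al <- exp(log_alpha)
    S - digamma(al) - log(R_ms / al) - I_bound
  }
  # H[T|Xi](alpha) decreases from +Inf (alpha -> 0) to S - log(R_ms)
  if (I_bound <= S - log(R_ms) ||
      resid(log(1e6)) > 0) {
    ss_stop("entropy bound below the infimum S - log(R_ms): infeasible",
            "ss_infeasible_error")
  }
  if (resid(0) <= 0) {
    # bound looser than H[T|Xi] at alpha = 1: constraint inactive, MFE
    sol <- solve_mfe(R_bound)
    sol$achieved_I <- S - digamma(1) - log(R_ms)
    return(sol)
  }
  root <- uniroot(resid, interval = c(log(1e-3), log(1e6)), tol = 1e-14)
  alpha <- exp(root$root)
  if (alpha < 1) alpha <- 1
  model <- gamma_rate_model(alpha = alpha, R = R_bound)
  structure(list(family = if (alpha == 1) "exponential" else "gamma",
                 rate_model = model,
                 achieved_H_rate = rate_entropy(model),
                 achieved_R = R_bound,
                 achieved_I = conditional_entropy(generator, model),
                 multipliers = list(lambda0 = NA_real_,
                                    lambda1 = alpha / R_ms,
                                    lambda2 = alpha - 1)),
            class = "maxent_solution")
}

#' Constrained entropy maximization on a discrete rate grid
#'
#' Independent numeric route to the MFE/CMFE solutions: maximizes the
#' discretized differential entropy \eqn{-\sum_j w_j k_j \log k_j} (log-width
#' trapezoidal weights \eqn{w_j} on a logarithmic rate grid) subject to
#' normalization, \eqn{\sum w_j k_j \xi_j = R}, and optionally
#' \eqn{\sum w_j k_j (S - \log \xi_j) = I}. The stationary solution is the
#' exponential family \eqn{k_j \propto \xi_j^{\lambda_2} e^{-\lambda_1 \xi_j}}
#' whose multipliers are found by nested root finding on the constraint
#' residuals. With no constraints the solution is uniform over the grid.
#'
#' @param R_bound mean-rate constraint, spikes/s; \code{NULL} for the
#'   unconstrained (uniform) problem.
#' @param I_bound optional conditional-response-entropy bound, nats.
#' @param generator a \code{\link{gamma_generator}}; required with
#'   \code{I_bound}.
#' @param grid_spec list with \code{n} (points, default 4000),
#'   \code{lo_frac} (lower edge as fraction of R, default 1e-5) and
#'   \code{hi_mult} (upper edge as multiple of R, default 100).
#' @return a \code{maxent_solution} with \code{family = "numeric-grid"} and a
#'   \code{grid} data.frame (\code{xi_ms}, \code{weight}, \code{k}, density
#'   per unit 1/ms), plus achieved constraint values and multipliers.
#' @export
grid_maxent <- function(R_bound = NULL, I_bound = NULL, generator = NULL,
                        grid_spec = list()) {
  gs <- modifyList(list(n = 4000, lo_frac = 1e-5, hi_mult = 100), grid_spec)
  if (is.null(R_bound)) {
    # no constraints beyond normalization: uniform over an arbitrary grid
    xi <- seq(1e-4, 1e-1, length.out = gs$n)
    w <- rep(diff(range(xi)) / (gs$n - 1), gs$n)
    w[c(1, gs$n)] <- w[1] / 2
    k <- rep(1 / sum(w), gs$n)
    return(structure(list(family = "numeric-grid",
                          grid = data.frame(xi_ms = xi, weight = w, k = k),
                          achieved_H_rate = -sum(w * k * log(k)),
                          achieved_R = NA_real_, achieved_I = NA_real_,
                          multipliers = list(lambda0 = NA_real_,
                                             lambda1 = 0, lambda2 = 0)),
                     class = "maxent_solution"))
  }
  .check_pos(R_bound, "R_bound")
  R_ms <- hz_to_per_ms(R_bound)
  u <- seq(log(R_ms * gs$lo_frac), log(R_ms * gs$hi_mult),
           length.out = gs$n)
  xi <- exp(u)
  du <- u[2] - u[1]
  wu <- rep(du, gs$n); wu[c(1, gs$n)] <- du / 2  # trapezoid in log xi
  w <- wu * xi                                   # d(xi) = xi d(log xi)

  # normalized member of the stationary family and its constraint moments
  member <- function(a, b) {
    lk <- (a - 1) * log(xi) - b * xi
    lk <- lk - max(lk)
    k <- exp(lk); k <- k / sum(w * k)
    k
  }
  mean_of <- function(k) sum(w * k * xi)
  elog_of <- function(k) sum(w * k * log(xi))

  solve_b <- function(a) {
    # b such that the grid mean equals R_ms; bracket around a/R_ms
    f <- function(logb) mean_of(member(a, exp(logb))) - R_ms
    r <- uniroot(f, interval = log(a / R_ms) + c(-10, 10), tol = 1e-14)
    exp(r$root)
  }

  if (is.null(I_bound)) {
    a <- 1
    b <- solve_b(a)
  } else {
    if (!inherits(generator, "gamma_generator")) {
      ss_stop("`generator` required with I_bound", "ss_parameter_error")
    }
    S <- generator_entropy_S(generator$kappa)
    target_elog <- S - I_bound
    g <- function(loga) {
      a <- exp(loga)
      elog_of(member(a, solve_b(a))) - target_elog
    }
    lo <- log(1e-2); hi <- log(1e4)
    if (g(lo) * g(hi) > 0) {
      ss_stop("no multiplier solves the entropy constraint on this grid",
              "ss_numeric_error")
    }
    r <- uniroot(g, interval = c(lo, hi), tol = 1e-14)
    a <- exp(r$root)
    b <- solve_b(a)
  }
  k <- member(a, b)
  structure(list(family = "numeric-grid",
                 grid = data.frame(xi_ms = xi, weight = w, k = k),
                 achieved_H_rate = -sum(w * k * log(k)),
                 achieved_R = per_ms_to_hz(mean_of(k)),
                 achieved_I = if (is.null(I_bound)) NA_real_ else
                   generator_entropy_S(generator$kappa) - elog_of(k),
                 multipliers = list(lambda0 = NA_real_, lambda1 = b,
                                    lambda2 = a - 1)),
            class = "maxent_solution")
}

#' Duality check: CMFE as conditional-entropy minimization
#'
#' The CMFE (maximize H[Xi] subject to mean rate R and H[T|Xi] <= I) can be
#' rewritten as minimizing H[T|Xi] subject to mean rate R and H[Xi] >= H0;
#' the two give the same gamma-family solution when the constraints hold with
#' equality. This check solves both directions over the gamma family and
#' reports the two shape values and their gap.
#'
#' @param R_bound mean rate, spikes/s.
#' @param H_rate_bound firing-rate entropy bound, nats (rate in 1/ms).
#' @param generator a \code{\link{gamma_generator}}.
#' @return list with \code{alpha_dual} (from the minimization direction),
#'   \code{alpha_cmfe} (from \code{\link{solve_cmfe}} at the corresponding
#'   I), and \code{gap}.
#' @export
duality_check <- function(R_bound, H_rate_bound, generator) {
  .check_pos(R_bound, "R_bound")
  h_of <- function(al) rate_entropy(gamma_rate_model(al, R_bound))
  if (H_rate_bound > h_of(1) + 1e-12) {
    ss_stop("H_rate_bound exceeds the exponential maximum: infeasible",
            "ss_infeasible_error")
  }
  # restricted to alpha >= 1, H[Xi](alpha) decreases; minimizing H[T|Xi]
  # pushes alpha up until the entropy bound binds
  alpha_dual <- if (abs(H_rate_bound - h_of(1)) < 1e-12) 1 else
    exp(uniroot(function(la) h_of(exp(la)) - H_rate_bound,
                interval = c(0, log(1e6)), tol = 1e-14)$root)
  I_star <- conditional_entropy(generator,
                                gamma_rate_model(alpha_dual, R_bound))
  alpha_cmfe <- solve_cmfe(R_bound, I_star, generator)$rate_model$alpha
  list(alpha_dual = alpha_dual, alpha_cmfe = alpha_cmfe,
       gap = abs(alpha_dual - alpha_cmfe))
}

#' MMI contrast: tail type of a discrete-rate compound law
#'
#' The maximization of mutual information predicts discrete rate
#' distributions, hence a finite superposition of gamma ISI densities whose
#' tail decays exponentially — in contrast to the power-law tail produced by
#' a gamma (continuous) rate distribution. This helper returns the compound
#' density, the predicted asymptotic tail type, and the empirical tail
#' classification of a simulated train run through the histogram pipeline.
#'
#' @param kappa interval-generator shape.
#' @param rates a \code{\link{discrete_rate_model}} or
#'   \code{\link{gamma_rate_model}}.
#' @param n_spikes spikes to simulate for the empirical classification.
#' @param seed integer seed.
#' @return list with \code{predicted} (\code{"exponential"} or
#'   \code{"power_law"}), \code{compound_pdf} (function of T in ms),
#'   \code{classification} (a \code{tail_class}).
#' @export
mmi_contrast <- function(kappa, rates, n_spikes = 100001, seed = 1) {
  gen <- gamma_generator(kappa)
  if (inherits(rates, "discrete_rate_model")) {
    predicted <- "exponential"
    train <- simulate_discrete_mixture(n_spikes, kappa, rates, seed = seed)
  } else if (inherits(rates, "gamma_rate_model")) {
    predicted <- "power_law"
    train <- simulate_superstat(n_spikes, kappa, rates, seed = seed)
  } else {
    ss_stop("`rates` must be a discrete_rate_model or gamma_rate_model",
            "ss_parameter_error")
  }
  cls <- classify_tail(log_binned_histogram(train))
  list(predicted = predicted,
       compound_pdf = function(T_ms) mixture_pdf(T_ms, gen, rates),
       classification = cls)
}

#' @export
print.maxent_solution <- function(x, ...) {
  cat(sprintf("<maxent_solution> family=%s", x$family))
  if (!is.null(x$rate_model)) {
    cat(sprintf(" alpha=%.6g R=%.6g spikes/s", x$rate_model$alpha,
                x$rate_model$R))
  }
  cat(sprintf(" H[Xi]=%.6g\n", x$achieved_H_rate))
  invisible(x)
}
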