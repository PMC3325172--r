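#' Rate-independent entropy of the gamma interval generator
#'
#' Differential entropy (nats) of the unit-mean gamma density
#' \eqn{f(x) = \kappa^\kappa x^{\kappa-1} e^{-\kappa x}/\Gamma(\kappa)}:
#' \deqn{S(\kappa) = \kappa - \log\kappa + \log\Gamma(\kappa) +
#'   (1-\kappa)\psi(\kappa)}
#' where \eqn{\psi} is the digamma function. \eqn{S(1) = 1} (unit-mean
#' exponential); S decreases strictly with kappa (more regular firing carries
#' less interval uncertainty). The conditional ISI entropy at fixed rate
#' \eqn{\xi} is \eqn{S(\kappa) - \log\xi}.
#'
#' @param kappa generator shape (> 0).
#' @return entropy, nats.
#' @examples
#' generator_entropy_S(1)  # 1
#' @export
generator_entropy_S <- function(kappa) {
  .check_pos(kappa, "kappa")
  kappa - log(kappa) + lgamma(kappa) + (1 - kappa) * digamma(kappa)
}

#' Entropy of the gamma firing-rate distribution H[Xi]
#'
#' Differential entropy (nats) of gamma(shape alpha, mean R), with the rate
#' expressed in the internal 1/ms unit:
#' \eqn{H[\Xi] = \alpha + \log(R_{ms}/\alpha) + \log\Gamma(\alpha) +
#' (1-\alpha)\psi(\alpha)}.
#'
#' @param model a \code{\link{gamma_rate_model}}.
#' @return entropy, nats (rate unit 1/ms).
#' @export
rate_entropy <- function(model) {
  if (!inherits(model, "gamma_rate_model")) {
    ss_stop("`model` must be a gamma_rate_model", "ss_parameter_error")
  }
  al <- model$alpha
  R_ms <- hz_to_per_ms(model$R)
  al + log(R_ms / al) + lgamma(al) + (1 - al) * digamma(al)
}

#' Conditional response entropy H[T|Xi]
#'
#' Average ISI uncertainty at given rate ("neuronal noise"):
#' \eqn{H[T|\Xi] = S(\kappa) - E_k[\log\xi]}, and for gamma rates
#' \eqn{E[\log\xi] = \psi(\alpha) + \log(R_{ms}/\alpha)}. ISIs in ms.
#'
#' @param generator a \code{\link{gamma_generator}}.
#' @param rates a \code{\link{gamma_rate_model}}.
#' @return entropy, nats.
#' @export
conditional_entropy <- function(generator, rates) {
  if (!inherits(generator, "gamma_generator")) {
    ss_stop("`generator` must be a gamma_generator", "ss_parameter_error")
  }
  if (!inherits(rates, "gamma_rate_model")) {
    ss_stop("`rates` must be a gamma_rate_model", "ss_parameter_error")
  }
  R_ms <- hz_to_per_ms(rates$R)
  generator_entropy_S(generator$kappa) -
    (digamma(rates$alpha) + log(R_ms / rates$alpha))
}

#' ISI entropy H[T] of the beta-2 marginal law
#'
#' Differential entropy (nats, ISIs in ms) of the compound ISI distribution,
#' by adaptive quadrature of \eqn{-\int P \log P \, dT} on a log axis.
#'
#' @param params a \code{\link{beta2_params}}.
#' @return entropy, nats.
#' @export
isi_entropy <- function(params) {
  if (!inherits(params, "beta2_params")) {
    ss_stop("`params` must be beta2_params", "ss_parameter_error")
  }
  f <- function(u) {
    lp <- beta2_logpdf(exp(u), params)
    -exp(lp + u) * lp
  }
  val <- tryCatch(
    integrate(f, lower = -40, upper = 40, rel.tol = 1e-11, abs.tol = 1e-12,
              subdivisions = 400L),
    error = function(e) ss_stop(paste("entropy quadrature failed:",
                                      conditionMessage(e)),
                                "ss_numeric_error"))
  val$value
}

#' Mutual information between rate and interval I[T, Xi]
#'
#' \eqn{I[T,\Xi] = H[T] - H[T|\Xi]}, nonnegative; zero when the rate is
#' degenerate (constant-rate firing carries no rate information in the ISIs).
#'
#' @param generator a \code{\link{gamma_generator}}.
#' @param rates a \code{\link{gamma_rate_model}}.
#' @return mutual information, nats.
#' @export
mutual_information <- function(generator, rates) {
  isi_entropy(beta2_from_rate_model(generator, rates)) -
    conditional_entropy(generator, rates)
}

#' Entropy report for one neuron model
#'
#' Collects the firing-rate entropy H[Xi], generator entropy S, conditional
#' response entropy H[T|Xi], ISI entropy H[T] and mutual information
#' I[T,Xi] = H[T] - H[T|Xi] for a (generator, gamma-rate) pair. Differential
#' entropies depend on the unit (ISIs ms, rates 1/ms) and base, which are
#' therefore recorded in the report; MI is invariant to both.
#'
#' @param generator a \code{\link{gamma_generator}}.
#' @param rates a \code{\link{gamma_rate_model}}.
#' @param log_base \code{"e"} (nats, default) or \code{"2"} (bits).
#' @return an \code{entropy_report}: list with \code{H_rate},
#'   \code{S_generator}, \code{H_cond}, \code{H_isi}, \code{MI},
#'   \code{log_base}, \code{isi_unit}.
#' @export
entropy_report <- function(generator, rates, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  conv <- if (log_base == "2") 1 / log(2) else 1
  H_cond <- conditional_entropy(generator, rates)
  H_isi <- isi_entropy(beta2_from_rate_model(generator, rates))
  structure(list(H_rate = conv * rate_entropy(rates),
                 S_generator = conv * generator_entropy_S(generator$kappa),
                 H_cond = conv * H_cond,
                 H_isi = conv * H_isi,
                 MI = conv * (H_isi - H_cond),
                 log_base = log_base, isi_unit = "ms"),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  unit <- if (x$log_base == "e") "nats" else "bits"
  cat(sprintf(
    "<entropy_report> H[Xi]=%.4f H[T|Xi]=%.4f H[T]=%.4f I[T,Xi]=%.4f %s (ISI in %s)\n",
    x$H_rate, x$H_cond, x$H_isi, x$MI, unit, x$isi_unit))
  invisible(x)
}
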