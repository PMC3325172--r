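#' superspike: superstatistical analysis of cortical spike trains
#'
#' In vivo cortical neurons fire irregularly. Conditional on a (latent)
#' instantaneous firing rate \eqn{\xi}, inter-spike intervals (ISIs) of
#' cortical neurons follow a gamma law with shape \eqn{\kappa} and mean
#' \eqn{1/\xi}. When \eqn{\xi} itself fluctuates on a slower timescale with a
#' gamma distribution of shape \eqn{\alpha} and mean \eqn{R}, the marginal ISI
#' law is the generalized beta distribution of the second kind ("beta-2"),
#' whose tail decays as a power law with exponent \eqn{\eta = \alpha + 1}.
#' This package provides the simulation, histogram, tail-regression, beta-2
#' fitting, decomposition, entropy and constrained maximum-entropy machinery
#' needed to analyse spike trains under this superstatistical model and to
#' contrast the entropy-maximization coding hypotheses (MFE, CMFE, MMI).
#'
#' @section Units:
#' Spike times are seconds; ISIs are milliseconds; firing rates are spikes/s
#' at every user-facing boundary. Internally rates are converted once to
#' 1/ms (\code{xi_ms = R_hz / 1000}) so that \code{xi * T} is dimensionless.
#'
#' @keywords internal
#' @importFrom stats rgamma dgamma integrate optim uniroot lm coef sd
#'   runif ks.test setNames
#' @importFrom utils write.table read.table read.csv modifyList
"_PACKAGE"

# classed error helper so callers/tests can discriminate failure modes
ss_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "superspike_error", "error")))
}

.check_pos <- function(x, name, class = "ss_parameter_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    ss_stop(sprintf("`%s` must be a single positive finite number", name),
            class)
  }
  invisible(x)
}

# single boundary between biological (spikes/s) and internal (1/ms) rate units
hz_to_per_ms <- function(R_hz) R_hz / 1000
per_ms_to_hz <- function(R_ms) R_ms * 1000

#' Gamma interval generator
#'
#' The conditional ISI law of a neuron at fixed rate \eqn{\xi}:
#' \eqn{q(T|\xi) = (\kappa\xi)^\kappa T^{\kappa-1} e^{-\kappa\xi T} /
#' \Gamma(\kappa)}, a gamma density with shape \eqn{\kappa} and mean
#' \eqn{1/\xi}. The family is scale invariant: the rate only sets the scale,
#' \eqn{1/\kappa} measures firing irregularity.
#'
#' @param kappa positive shape parameter (dimensionless).
#' @return An object of class \code{gamma_generator}.
#' @examples
#' gen <- gamma_generator(2)
#' @export
gamma_generator <- function(kappa) {
  .check_pos(kappa, "kappa")
  structure(list(kappa = kappa), class = "gamma_generator")
}

#' Gamma firing-rate model
#'
#' The latent firing-rate distribution \eqn{k(\xi)}: gamma with shape
#' \eqn{\alpha} and mean \eqn{R}. \eqn{1/\alpha} measures the degree of rate
#' modulation; as \eqn{\alpha \to \infty} the law collapses to a point mass at
#' \eqn{R} (constant-rate firing).
#'
#' @param alpha positive shape parameter.
#' @param R mean firing rate, spikes/s.
#' @return An object of class \code{gamma_rate_model}.
#' @examples
#' m <- gamma_rate_model(alpha = 1.91, R = 10)
#' @export
gamma_rate_model <- function(alpha, R) {
  .check_pos(alpha, "alpha")
  .check_pos(R, "R")
  structure(list(alpha = alpha, R = R), class = "gamma_rate_model")
}

#' Discrete firing-rate model
#'
#' A finite mixture of rates, the form the maximization of mutual information
#' (MMI) predicts for gamma-interval channels: the rate takes one of a few
#' values (e.g. low/high) with fixed probabilities, so the marginal ISI law is
#' a finite superposition of gamma densities with an exponential tail.
#'
#' @param rates positive rates, spikes/s.
#' @param weights nonnegative mixing weights; normalized to sum to one
#'   (must already sum to 1 within 1e-12 after normalization sanity check).
#' @return An object of class \code{discrete_rate_model}.
#' @examples
#' m <- discrete_rate_model(c(2, 20), c(0.5, 0.5))
#' @export
discrete_rate_model <- function(rates, weights = NULL) {
  if (length(rates) < 1L) {
    ss_stop("`rates` must contain at least one rate", "ss_parameter_error")
  }
  if (!is.numeric(rates) || any(!is.finite(rates)) || any(rates <= 0)) {
    ss_stop("`rates` must be positive finite numbers", "ss_parameter_error")
  }
  if (is.null(weights)) weights <- rep(1 / length(rates), length(rates))
  if (length(weights) != length(rates) || any(!is.finite(weights)) ||
      any(weights < 0) || sum(weights) <= 0) {
    ss_stop("`weights` must be nonnegative and match `rates` in length",
            "ss_parameter_error")
  }
  weights <- weights / sum(weights)
  stopifnot(abs(sum(weights) - 1) < 1e-12)
  structure(list(rates = rates, weights = weights),
            class = "discrete_rate_model")
}

#' Spike train
#'
#' An ordered sequence of spike times in seconds, with optional metadata
#' (functional label, recording depth, spike width) and, for simulated trains,
#' the true per-interval rates used to generate it (so parameter-recovery
#' tests need no rate estimator).
#'
#' @param times strictly increasing, nonnegative spike times in seconds.
#' @param metadata optional named list (e.g. \code{label}, \code{depth_um},
#'   \code{spike_width_ms}).
#' @param true_rates optional numeric vector of per-interval rates (spikes/s),
#'   length \code{length(times) - 1}.
#' @return An object of class \code{spike_train}.
#' @examples
#' tr <- spike_train(c(0, 0.1, 0.35))
#' @export
spike_train <- function(times, metadata = list(), true_rates = NULL) {
  if (!is.numeric(times) || length(times) < 2L) {
    ss_stop("a spike train needs at least 2 spike times",
            "ss_parameter_error")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    ss_stop("spike times must be finite and nonnegative",
            "ss_parameter_error")
  }
  if (any(diff(times) <= 0)) {
    ss_stop("spike times must be strictly increasing", "ss_parameter_error")
  }
  if (!is.null(true_rates) && length(true_rates) != length(times) - 1L) {
    ss_stop("`true_rates` must have one rate per inter-spike interval",
            "ss_parameter_error")
  }
  structure(list(times = as.numeric(times), metadata = metadata,
                 true_rates = true_rates),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- diff(range(x$times))
  cat(sprintf("<spike_train> %d spikes, %.1f s, mean rate %.2f spikes/s\n",
              length(x$times), dur, (length(x$times) - 1) / dur))
  invisible(x)
}

#' Number of spikes and duration helpers
#'
#' @param train a \code{spike_train}.
#' @return \code{n_spikes}: integer count; \code{train_duration}: seconds;
#'   \code{mean_rate}: spikes/s computed as (spike count - 1) / duration.
#' @export
n_spikes <- function(train) length(train$times)

#' @rdname n_spikes
#' @export
train_duration <- function(train) diff(range(train$times))

#' @rdname n_spikes
#' @export
mean_rate <- function(train) (n_spikes(train) - 1) / train_duration(train)
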