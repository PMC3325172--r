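#' Draw firing rates from a gamma rate model
#'
#' i.i.d. draws from the gamma law with shape \code{alpha} and mean \code{R}
#' (so the rate parameter of the gamma is \code{alpha / R}).
#'
#' @param n number of draws.
#' @param model a \code{\link{gamma_rate_model}}.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return numeric vector of rates, spikes/s.
#' @examples
#' r <- draw_rates(1000, gamma_rate_model(1, 10), seed = 1)
#' @export
draw_rates <- function(n, model, seed = NULL) {
  if (!inherits(model, "gamma_rate_model")) {
    ss_stop("`model` must be a gamma_rate_model", "ss_parameter_error")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    ss_stop("`n` must be a positive integer", "ss_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  rgamma(n, shape = model$alpha, rate = model$alpha / model$R)
}

# Core: build a spike_train from per-interval rates (spikes/s) and a gamma
# interval generator of shape kappa. ISI_i | xi_i ~ gamma(kappa, mean 1/xi_i).
# Times start at 0 s; n_spikes = length(rates_hz) + 1.
.train_from_rates <- function(rates_hz, kappa, metadata = list()) {
  xi_ms <- hz_to_per_ms(rates_hz)
  isi_ms <- rgamma(length(xi_ms), shape = kappa, rate = kappa * xi_ms)
  times_s <- cumsum(c(0, isi_ms)) / 1000
  spike_train(times_s, metadata = metadata, true_rates = rates_hz)
}

#' Simulate a constant-rate gamma renewal spike train
#'
#' A neuron driven by stationary input fires with ISIs i.i.d. gamma with shape
#' \code{kappa} and mean \code{1/rate}: the in-vitro regime. The ISI histogram
#' tail is exponential (linear in a semi-log plot).
#'
#' @param n_spikes number of spikes (the train has \code{n_spikes - 1} ISIs).
#' @param kappa gamma shape of the interval generator.
#' @param rate firing rate, spikes/s.
#' @param seed integer seed.
#' @return a \code{\link{spike_train}}.
#' @examples
#' tr <- simulate_constant_rate(1000, kappa = 3, rate = 10, seed = 1)
#' @export
simulate_constant_rate <- function(n_spikes, kappa, rate, seed = NULL) {
  .check_pos(kappa, "kappa"); .check_pos(rate, "rate")
  if (n_spikes < 2) ss_stop("need n_spikes >= 2", "ss_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  tr <- .train_from_rates(rep(rate, n_spikes - 1), kappa,
                          metadata = list(model = "constant_rate",
                                          kappa = kappa, rate = rate,
                                          seed = seed))
  tr
}

#' Simulate a doubly-stochastic (superstatistical) spike train
#'
#' The latent rate is drawn from a gamma distribution (shape \code{alpha},
#' mean \code{R}) and, conditional on the rate, ISIs are gamma with shape
#' \code{kappa}. Two rate-refresh schemes are provided:
#' \describe{
#'   \item{per-interval}{an independent rate draw per ISI; this realizes the
#'     mixture marginal exactly, i.e. the ISIs are i.i.d. beta-2 with
#'     parameters \eqn{(\alpha, \kappa, \tau = \alpha/(R\kappa))}.}
#'   \item{blockwise}{one rate draw per consecutive block of
#'     \code{block_size} ISIs, emulating rate modulation slower than the
#'     typical ISI; the marginal ISI law is the same.}
#' }
#' The true per-interval rates are retained in the returned train.
#'
#' @param n_spikes number of spikes (\code{n_spikes - 1} ISIs).
#' @param kappa interval-generator shape.
#' @param rate_model a \code{\link{gamma_rate_model}}.
#' @param scheme \code{"per-interval"} (default) or \code{"blockwise"}.
#' @param block_size ISIs per rate draw when \code{scheme = "blockwise"}.
#' @param seed integer seed.
#' @return a \code{\link{spike_train}} with \code{true_rates} filled.
#' @examples
#' tr <- simulate_superstat(5000, kappa = 2,
#'                          rate_model = gamma_rate_model(1.91, 10), seed = 1)
#' @export
simulate_superstat <- function(n_spikes, kappa, rate_model,
                               scheme = c("per-interval", "blockwise"),
                               block_size = 100, seed = NULL) {
  .check_pos(kappa, "kappa")
  if (!inherits(rate_model, "gamma_rate_model")) {
    ss_stop("`rate_model` must be a gamma_rate_model", "ss_parameter_error")
  }
  if (n_spikes < 2) ss_stop("need n_spikes >= 2", "ss_parameter_error")
  if (is.character(scheme) && length(scheme) >= 1 &&
      !scheme[1] %in% c("per-interval", "blockwise")) {
    ss_stop(sprintf("unknown scheme '%s'", scheme[1]), "ss_usage_error")
  }
  scheme <- match.arg(scheme)
  n_isi <- n_spikes - 1
  if (!is.null(seed)) set.seed(seed)
  if (scheme == "per-interval") {
    rates <- draw_rates(n_isi, rate_model)
  } else {
    if (block_size < 1) ss_stop("block_size must be >= 1", "ss_usage_error")
    n_blocks <- ceiling(n_isi / block_size)
    rates <- rep(draw_rates(n_blocks, rate_model),
                 each = block_size)[seq_len(n_isi)]
  }
  .train_from_rates(rates, kappa,
                    metadata = list(model = "superstat", kappa = kappa,
                                    alpha = rate_model$alpha,
                                    R = rate_model$R, scheme = scheme,
                                    block_size =
                                      if (scheme == "blockwise") block_size,
                                    seed = seed))
}

#' Simulate a discrete-rate mixture spike train (MMI regime)
#'
#' Each ISI's rate is sampled from a finite set with the model's weights, so
#' the marginal ISI law is a finite superposition of gamma densities with an
#' asymptotically exponential tail, as the maximization of mutual information
#' predicts for gamma-interval channels.
#'
#' @param n_spikes number of spikes (\code{n_spikes - 1} ISIs).
#' @param kappa interval-generator shape.
#' @param model a \code{\link{discrete_rate_model}}.
#' @param seed integer seed.
#' @return a \code{\link{spike_train}} with \code{true_rates} filled.
#' @examples
#' tr <- simulate_discrete_mixture(5000, 1,
#'                                 discrete_rate_model(c(2, 20)), seed = 1)
#' @export
simulate_discrete_mixture <- function(n_spikes, kappa, model, seed = NULL) {
  .check_pos(kappa, "kappa")
  if (!inherits(model, "discrete_rate_model")) {
    ss_stop("`model` must be a discrete_rate_model", "ss_parameter_error")
  }
  if (n_spikes < 2) ss_stop("need n_spikes >= 2", "ss_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  n_isi <- n_spikes - 1
  # index-based draw (sample() treats a length-1 rates vector as 1:n)
  idx <- sample.int(length(model$rates), n_isi, replace = TRUE,
                    prob = model$weights)
  rates <- model$rates[idx]
  .train_from_rates(rates, kappa,
                    metadata = list(model = "discrete_mixture", kappa = kappa,
                                    rates = model$rates,
                                    weights = model$weights, seed = seed))
}

#' Read and write spike-time files
#'
#' Plain-text format: one ascending spike time in seconds per line. The
#' optional JSON sidecar (same path with extension \code{.json}) stores the
#' generation parameters and true per-interval rates of simulated trains.
#'
#' @param train a \code{\link{spike_train}}.
#' @param path file to write/read.
#' @param sidecar write/read the JSON sidecar if generation metadata exists.
#' @return \code{read_spike_train} returns a \code{spike_train};
#'   \code{write_spike_train} returns \code{path} invisibly.
#' @export
write_spike_train <- function(train, path, sidecar = TRUE) {
  if (!inherits(train, "spike_train")) {
    ss_stop("`train` must be a spike_train", "ss_parameter_error")
  }
  writeLines(sprintf("%.9f", train$times), path)
  if (sidecar && (length(train$metadata) > 0 || !is.null(train$true_rates))) {
    side <- list(metadata = train$metadata, true_rates = train$true_rates)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Attach neuron metadata from a CSV table
#'
#' The CSV carries one row per neuron with columns \code{id} and any of
#' \code{depth_um}, \code{spike_width_ms}, \code{label}, \code{mean_rate_hz};
#' the row whose \code{id} matches is merged into the train's metadata (so
#' \code{\link{analyze_neuron}} can call the cell type).
#'
#' @param train a \code{\link{spike_train}}.
#' @param csv_path path to the metadata CSV.
#' @param id neuron id to look up; defaults to the train's metadata id.
#' @return the train with merged metadata.
#' @export
attach_metadata <- function(train, csv_path, id = NULL) {
  meta <- read.csv(csv_path, stringsAsFactors = FALSE)
  if (!"id" %in% names(meta)) {
    ss_stop("metadata CSV needs an `id` column", "ss_parameter_error")
  }
  id <- id %||% train$metadata$id
  row <- meta[meta$id == id, , drop = FALSE]
  if (nrow(row) != 1L) {
    ss_stop(sprintf("metadata CSV has %d rows for id '%s'", nrow(row), id),
            "ss_parameter_error")
  }
  train$metadata <- modifyList(train$metadata, as.list(row))
  train
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path, sidecar = TRUE) {
  times <- as.numeric(readLines(path))
  meta <- list(); rates <- NULL
  side_path <- paste0(path, ".json")
  if (sidecar && file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    meta <- as.list(side$metadata)
    if (!is.null(side$true_rates)) rates <- as.numeric(side$true_rates)
  }
  spike_train(times, metadata = meta, true_rates = rates)
}
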