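#' Analysis configuration
#'
#' All pipeline thresholds in one auditable place. Defaults reproduce the
#' recorded-cohort analysis settings: 80 logarithmic bins (M = 20) on
#' [1, 1e4] ms, tail regression from twice the histogram mode, c.d. > 0.95
#' goodness criterion, and a 2000-spike minimum per train.
#'
#' @param M bins per decade.
#' @param cd_threshold coefficient-of-determination criterion.
#' @param min_spikes minimum spikes required by \code{\link{analyze_neuron}}.
#' @param tail_mode_multiplier fit-range lower bound, multiples of the mode.
#' @param min_tail_bins minimum usable tail bins.
#' @return named list of settings (with a \code{version} stamp).
#' @export
default_config <- function(M = 20, cd_threshold = 0.95, min_spikes = 2000,
                           tail_mode_multiplier = 2, min_tail_bins = 5) {
  list(version = "1", M = M, cd_threshold = cd_threshold,
       min_spikes = min_spikes, tail_mode_multiplier = tail_mode_multiplier,
       min_tail_bins = min_tail_bins, isi_unit = "ms", rate_unit = "spikes/s")
}

#' Full per-neuron analysis
#'
#' Runs the complete workflow on one spike train: ISI histogram, stationarity
#' split, tail regressions in both scales with classification, beta-2 fit,
#' decomposition into the gamma rate model, entropy report, and (when spike
#' width metadata is available) cell-type call. Stage failures are collected
#' into \code{failures} rather than aborting the report.
#'
#' @param x a \code{\link{spike_train}} or path to a spike-times file.
#' @param config settings from \code{\link{default_config}}.
#' @param allow_short analyze trains below \code{min_spikes} anyway (with a
#'   warning) instead of refusing.
#' @return a \code{neuron_report}: list with \code{id}, \code{n_spikes},
#'   \code{duration_s}, \code{mean_rate_hz}, \code{tail} (a
#'   \code{tail_class}), \code{beta2} (a \code{beta2_fit}), \code{rate_model},
#'   \code{entropy} (an \code{entropy_report}), \code{cell_type},
#'   \code{stationarity}, \code{eta_consistent} (|eta - (alpha+1)| <= 0.3),
#'   \code{config}, \code{failures}.
#' @export
analyze_neuron <- function(x, config = default_config(),
                           allow_short = FALSE) {
  train <- if (inherits(x, "spike_train")) x else read_spike_train(x)
  if (n_spikes(train) < config$min_spikes) {
    if (!allow_short) {
      ss_stop(sprintf(
        "train has %d spikes; analysis requires >= %d (set allow_short=TRUE to override)",
        n_spikes(train), config$min_spikes), "ss_validation_error")
    }
    warning(sprintf("analyzing a short train (%d < %d spikes)",
                    n_spikes(train), config$min_spikes))
  }
  failures <- list()
  grab <- function(stage, expr) {
    tryCatch(expr, superspike_error = function(e) {
      failures[[stage]] <<- conditionMessage(e)
      NULL
    })
  }
  hist <- grab("histogram",
               log_binned_histogram(compute_isis(train), M = config$M))
  tail <- if (!is.null(hist)) {
    classify_tail(hist, cd_threshold = config$cd_threshold,
                  mode_multiplier = config$tail_mode_multiplier,
                  min_bins = config$min_tail_bins)
  }
  fit <- if (!is.null(hist)) grab("beta2_fit", fit_beta2(hist))
  rate_model <- if (!is.null(fit)) {
    grab("decompose", rate_model_from_beta2(fit$params))
  }
  entropy <- if (!is.null(fit) && !is.null(rate_model)) {
    grab("entropy",
         entropy_report(gamma_generator(fit$params$kappa), rate_model))
  }
  stat <- grab("stationarity", stationarity_ks(train))
  cell <- if (!is.null(train$metadata$spike_width_ms)) {
    grab("cell_type",
         classify_cell_type(mean_rate(train), train$metadata$spike_width_ms))
  }
  eta_fit <- if (!is.null(tail) && !is.null(tail$fit_loglog)) {
    tail$fit_loglog$eta
  } else NA_real_
  structure(list(id = train$metadata$id %||% NA_character_,
                 n_spikes = n_spikes(train),
                 duration_s = train_duration(train),
                 mean_rate_hz = mean_rate(train),
                 tail = tail, beta2 = fit, rate_model = rate_model,
                 entropy = entropy, cell_type = cell, stationarity = stat,
                 eta_consistent =
                   if (!is.null(fit) && is.finite(eta_fit))
                     abs(eta_fit - (fit$params$alpha + 1)) <= 0.3
                   else NA,
                 config = config, failures = failures),
            class = "neuron_report")
}

#' @export
print.neuron_report <- function(x, ...) {
  cat(sprintf("<neuron_report> %d spikes, %.1f s, %.2f spikes/s\n",
              x$n_spikes, x$duration_s, x$mean_rate_hz))
  if (!is.null(x$tail)) {
    cat(sprintf("  tail: %s (cd loglog %.3f, semilog %.3f)\n",
                x$tail$verdict, x$tail$cd_loglog, x$tail$cd_semilog))
  }
  if (!is.null(x$beta2)) print(x$beta2)
  if (!is.null(x$entropy)) print(x$entropy)
  if (length(x$failures)) {
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate the deterministic synthetic fixture battery
#'
#' Emulates the scale of the recorded cohort (2000+ spikes per train, rates
#' within 2.5-50.9 spikes/s, durations of minutes): superstatistical trains
#' on the grid alpha in \{0.8, 1, 1.5, 1.91, 3\} x kappa in \{1, 2, 3.49\}
#' (the alpha < 1 cells mirror the minority of recorded neurons with
#' alpha < 1), plus constant-rate and binary discrete-mixture controls. Each
#' train is written as a spike-times text file with a JSON sidecar holding
#' the generation truth.
#'
#' @param out_dir writable directory (created if missing).
#' @param seed integer seed; the battery is byte-identical for a given seed.
#' @param n_spikes spikes per fixture train.
#' @return invisibly, a data.frame manifest (file, model, parameters).
#' @export
make_fixtures <- function(out_dir, seed = 1, n_spikes = 5000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  alphas <- c(0.8, 1, 1.5, 1.91, 3)
  kappas <- c(1, 2, 3.49)
  rates <- c(2.5, 5, 10, 20, 50.9)  # spans the recorded 2.5-50.9 spikes/s
  i <- 0L
  for (ai in seq_along(alphas)) {
    for (ki in seq_along(kappas)) {
      i <- i + 1L
      R <- rates[(i - 1L) %% length(rates) + 1L]
      f <- file.path(out_dir, sprintf("superstat_a%.3g_k%.3g.txt",
                                      alphas[ai], kappas[ki]))
      tr <- simulate_superstat(n_spikes, kappas[ki],
                               gamma_rate_model(alphas[ai], R),
                               seed = seed * 1000L + i)
      write_spike_train(tr, f)
      manifest[[length(manifest) + 1L]] <-
        data.frame(file = f, model = "superstat", alpha = alphas[ai],
                   kappa = kappas[ki], R = R)
    }
  }
  for (ki in seq_along(kappas)) {
    i <- i + 1L
    f <- file.path(out_dir, sprintf("constant_k%.3g.txt", kappas[ki]))
    tr <- simulate_constant_rate(n_spikes, kappas[ki], rate = 10,
                                 seed = seed * 1000L + i)
    write_spike_train(tr, f)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = f, model = "constant_rate", alpha = NA,
                 kappa = kappas[ki], R = 10)
  }
  for (ki in c(1, 2)) {
    i <- i + 1L
    f <- file.path(out_dir, sprintf("mixture_k%.3g.txt", ki))
    tr <- simulate_discrete_mixture(n_spikes, ki,
                                    discrete_rate_model(c(2, 20),
                                                        c(0.5, 0.5)),
                                    seed = seed * 1000L + i)
    write_spike_train(tr, f)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = f, model = "discrete_mixture", alpha = NA,
                 kappa = ki, R = 11)
  }
  manifest <- do.call(rbind, manifest)
  portable <- manifest
  portable$file <- basename(portable$file)  # keep the battery relocatable
  write.table(portable, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
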