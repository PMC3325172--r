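#' Mode of a log-binned ISI histogram
#'
#' Geometric center of the maximal-density bin; ties are broken toward the
#' smallest ISI. For monotonically decreasing densities (kappa <= 1) this is
#' the first bin center.
#'
#' @param hist a \code{log_binned_histogram}.
#' @return mode location, ms.
#' @export
find_mode <- function(hist) {
  if (!inherits(hist, "log_binned_histogram")) {
    ss_stop("`hist` must be a log_binned_histogram", "ss_parameter_error")
  }
  if (all(hist$counts == 0)) {
    ss_stop("empty histogram has no mode", "ss_degenerate_input")
  }
  hist$centers_ms[which.max(hist$densities)]  # which.max takes first maximum
}

#' Linear regression of the histogram tail
#'
#' Ordinary least squares of log10(density) against log10(T) (double-log
#' scale, slope magnitude = power-law exponent eta) or against T (semi-log
#' scale, exponential decay), over bins with nonzero counts whose centers lie
#' at or beyond twice the histogram mode, up to the last nonzero bin. The
#' coefficient of determination is computed in the regression's ordinate
#' space (log10 density in both scales).
#'
#' @param hist a \code{log_binned_histogram}.
#' @param scale \code{"loglog"} or \code{"semilog"}.
#' @param mode_multiplier fit-range lower bound as a multiple of the mode
#'   (default 2).
#' @param min_bins minimum usable bins (default 5).
#' @return a \code{tail_fit}: list with \code{scale}, \code{eta} (slope
#'   magnitude), \code{intercept}, \code{cd}, \code{fit_range_ms},
#'   \code{n_bins_used}.
#' @export
fit_tail <- function(hist, scale = c("loglog", "semilog"),
                     mode_multiplier = 2, min_bins = 5) {
  scale <- match.arg(scale)
  mode_ms <- find_mode(hist)
  usable <- hist$counts > 0 & hist$centers_ms >= mode_multiplier * mode_ms
  if (sum(usable) < min_bins) {
    ss_stop(sprintf("only %d usable tail bins (< %d)", sum(usable), min_bins),
            "ss_insufficient_tail")
  }
  y <- log10(hist$densities[usable])
  x <- if (scale == "loglog") log10(hist$centers_ms[usable])
       else hist$centers_ms[usable]
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  cd <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(scale = scale, eta = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 cd = max(0, min(1, cd)),
                 fit_range_ms = range(hist$centers_ms[usable]),
                 n_bins_used = sum(usable)),
            class = "tail_fit")
}

#' Classify a histogram tail as power law or exponential
#'
#' Applies \code{\link{fit_tail}} in both scales and the c.d. > 0.95
#' criterion: \code{power_law} iff only the double-log regression passes,
#' \code{exponential} iff only the semi-log regression passes, \code{both} if
#' both pass, \code{neither} otherwise (including when too few tail bins are
#' available in either scale).
#'
#' @param hist a \code{log_binned_histogram}.
#' @param cd_threshold goodness criterion (default 0.95).
#' @param ... passed to \code{\link{fit_tail}}.
#' @return a \code{tail_class}: list with \code{verdict}, \code{cd_loglog},
#'   \code{cd_semilog}, \code{fit_loglog}, \code{fit_semilog}.
#' @export
classify_tail <- function(hist, cd_threshold = 0.95, ...) {
  safe_fit <- function(scale) {
    tryCatch(fit_tail(hist, scale, ...),
             ss_insufficient_tail = function(e) NULL,
             ss_degenerate_input = function(e) NULL)
  }
  f_ll <- safe_fit("loglog")
  f_sl <- safe_fit("semilog")
  cd_ll <- if (is.null(f_ll)) NA_real_ else f_ll$cd
  cd_sl <- if (is.null(f_sl)) NA_real_ else f_sl$cd
  pass_ll <- isTRUE(cd_ll > cd_threshold)
  pass_sl <- isTRUE(cd_sl > cd_threshold)
  verdict <- if (pass_ll && pass_sl) "both"
             else if (pass_ll) "power_law"
             else if (pass_sl) "exponential"
             else "neither"
  structure(list(verdict = verdict, cd_loglog = cd_ll, cd_semilog = cd_sl,
                 fit_loglog = f_ll, fit_semilog = f_sl),
            class = "tail_class")
}
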