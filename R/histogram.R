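#' Inter-spike intervals of a spike train
#'
#' Successive differences of the spike times, converted to milliseconds.
#'
#' @param train a \code{\link{spike_train}} (at least 2 spikes).
#' @return an \code{isi_sample}: list with \code{intervals_ms} and
#'   \code{source}.
#' @examples
#' compute_isis(spike_train(c(0, 0.1, 0.35)))$intervals_ms  # 100, 250
#' @export
compute_isis <- function(train) {
  if (!inherits(train, "spike_train")) {
    ss_stop("`train` must be a spike_train", "ss_parameter_error")
  }
  if (n_spikes(train) < 2L) {
    ss_stop("need at least 2 spikes to form an ISI", "ss_empty_input")
  }
  structure(list(intervals_ms = diff(train$times) * 1000,
                 source = train$metadata$id %||% NA_character_),
            class = "isi_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_isi_sample <- function(x) {
  if (inherits(x, "isi_sample")) return(x)
  if (inherits(x, "spike_train")) return(compute_isis(x))
  if (is.numeric(x)) {
    if (any(x <= 0)) ss_stop("ISIs must be positive", "ss_parameter_error")
    return(structure(list(intervals_ms = x, source = NA_character_),
                     class = "isi_sample"))
  }
  ss_stop("cannot interpret input as ISIs", "ss_parameter_error")
}

#' Logarithmically binned ISI histogram
#'
#' Bin edges are \eqn{10^{j/M}} ms for \eqn{j = 0, \dots, 4M}, so the
#' \eqn{j}th bin covers \eqn{[10^{(j-1)/M}, 10^{j/M}]} ms with width
#' \eqn{\Delta T_j = (1 - 10^{-1/M}) 10^{j/M}} ms, and the histogram spans
#' 1 ms to 10^4 ms (80 bins at the default \code{M = 20}). Densities are
#' counts divided by bin width and by the number of in-range ISIs, so the
#' density integrates to the in-range fraction. ISIs outside the range are
#' excluded but counted in \code{n_below} / \code{n_above}.
#'
#' @param isis an \code{isi_sample}, \code{spike_train}, or numeric vector of
#'   ISIs in ms.
#' @param M bins per decade (default 20, i.e. 4M = 80 bins).
#' @return a \code{log_binned_histogram}: list with \code{M}, \code{edges_ms}
#'   (length 4M+1), \code{centers_ms} (geometric bin centers), \code{widths_ms},
#'   \code{counts}, \code{densities} (1/ms), \code{n_below}, \code{n_above},
#'   \code{n_in}.
#' @examples
#' h <- log_binned_histogram(runif(500, 5, 500))
#' @export
log_binned_histogram <- function(isis, M = 20) {
  isis <- as_isi_sample(isis)
  if (!is.numeric(M) || length(M) != 1L || M < 2 || M != round(M)) {
    ss_stop("`M` must be an integer >= 2", "ss_parameter_error")
  }
  x <- isis$intervals_ms
  edges <- 10^((0:(4 * M)) / M)
  lo <- edges[1]; hi <- edges[length(edges)]
  n_below <- sum(x < lo)
  n_above <- sum(x > hi)
  inr <- x[x >= lo & x <= hi]
  if (length(inr) == 0L) {
    ss_stop("all ISIs fall outside [1, 1e4] ms", "ss_degenerate_input")
  }
  # right-closed bins [10^{(j-1)/M}, 10^{j/M}]; values equal to lo go to bin 1
  counts <- tabulate(pmin(pmax(ceiling(log10(inr) * M), 1L), 4L * M),
                     nbins = 4L * M)
  widths <- diff(edges)            # (1 - 10^{-1/M}) * 10^{j/M}
  structure(list(M = M, edges_ms = edges,
                 centers_ms = sqrt(edges[-1] * edges[-length(edges)]),
                 widths_ms = widths, counts = counts,
                 densities = counts / (widths * length(inr)),
                 n_below = n_below, n_above = n_above, n_in = length(inr)),
            class = "log_binned_histogram")
}

#' @export
print.log_binned_histogram <- function(x, ...) {
  cat(sprintf(
    "<log_binned_histogram> %d bins (M = %d), %d ISIs in [1, 1e4] ms (%d below, %d above)\n",
    length(x$counts), x$M, x$n_in, x$n_below, x$n_above))
  invisible(x)
}

#' Split a spike train into early and late halves
#'
#' The halves contain the same number of spikes (the first half gets the
#' extra spike when the count is odd); comparing their ISI histograms is the
#' stationarity check used for recorded neurons.
#'
#' @param train a \code{\link{spike_train}} with at least 4 spikes.
#' @return list of two \code{spike_train}s, \code{early} and \code{late}.
#' @export
split_halves <- function(train) {
  if (!inherits(train, "spike_train")) {
    ss_stop("`train` must be a spike_train", "ss_parameter_error")
  }
  n <- n_spikes(train)
  if (n < 4L) ss_stop("need at least 4 spikes to split", "ss_parameter_error")
  k <- ceiling(n / 2)
  list(early = spike_train(train$times[1:k], metadata = train$metadata,
                           true_rates = train$true_rates[seq_len(k - 1)]),
       late = spike_train(train$times[(k + 1):n], metadata = train$metadata,
                          true_rates =
                            if (!is.null(train$true_rates))
                              train$true_rates[(k + 1):(n - 1)]))
}

#' Two-sample KS stationarity check on the half-train ISIs
#'
#' @param train a \code{\link{spike_train}}.
#' @return list with the KS statistic, the 1\% critical value
#'   \eqn{1.628\sqrt{(n_1+n_2)/(n_1 n_2)}}, and the verdict
#'   \code{stationary} (statistic below the critical value).
#' @export
stationarity_ks <- function(train) {
  halves <- split_halves(train)
  a <- compute_isis(halves$early)$intervals_ms
  b <- compute_isis(halves$late)$intervals_ms
  stat <- suppressWarnings(unname(ks.test(a, b)$statistic))
  n1 <- as.numeric(length(a)); n2 <- as.numeric(length(b))
  crit <- 1.628 * sqrt((n1 + n2) / (n1 * n2))
  list(statistic = stat, critical_1pct = crit, stationary = stat < crit)
}

#' Classify a neuron as putative pyramidal or fast-spiking
#'
#' Putative pyramidal iff mean firing rate < 30 spikes/s (strict) AND average
#' spike width > 0.2 ms (strict); otherwise putative fast-spiking interneuron.
#' Classification is refused (not defaulted) when the spike width is missing.
#'
#' @param rate mean firing rate, spikes/s.
#' @param spike_width average spike width, ms.
#' @return a \code{cell_type_call}: list with \code{label}
#'   (\code{"pyramidal"} or \code{"fast-spiking"}), \code{mean_rate},
#'   \code{spike_width}.
#' @examples
#' classify_cell_type(10, 0.4)$label   # pyramidal
#' classify_cell_type(40, 0.15)$label  # fast-spiking
#' @export
classify_cell_type <- function(rate, spike_width) {
  if (missing(spike_width) || is.null(spike_width) || is.na(spike_width)) {
    ss_stop("spike width missing: classification refused",
            "ss_parameter_error")
  }
  .check_pos(rate, "rate"); .check_pos(spike_width, "spike_width")
  label <- if (rate < 30 && spike_width > 0.2) "pyramidal" else "fast-spiking"
  structure(list(label = label, mean_rate = rate, spike_width = spike_width),
            class = "cell_type_call")
}

#' Write / read a histogram as TSV
#'
#' Columns: \code{bin_left_ms}, \code{bin_right_ms}, \code{count},
#' \code{density}.
#'
#' @param hist a \code{log_binned_histogram}.
#' @param path file path.
#' @return \code{read_histogram_tsv} reconstructs the
#'   \code{log_binned_histogram} (out-of-range counts are stored in comment
#'   headers).
#' @export
write_histogram_tsv <- function(hist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# M=%d n_below=%d n_above=%d n_in=%d",
                     hist$M, hist$n_below, hist$n_above, hist$n_in), con)
  df <- data.frame(bin_left_ms = hist$edges_ms[-length(hist$edges_ms)],
                   bin_right_ms = hist$edges_ms[-1],
                   count = hist$counts, density = hist$densities)
  write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_tsv
#' @export
read_histogram_tsv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- as.integer(sub(".*=", "", strsplit(sub("^# ", "", header),
                                             " ")[[1]]))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  M <- meta[1]
  edges <- c(df$bin_left_ms[1], df$bin_right_ms)
  structure(list(M = M, edges_ms = edges,
                 centers_ms = sqrt(edges[-1] * edges[-length(edges)]),
                 widths_ms = diff(edges), counts = df$count,
                 densities = df$density, n_below = meta[2],
                 n_above = meta[3], n_in = meta[4]),
            class = "log_binned_histogram")
}
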