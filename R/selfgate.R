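# Self-gating extraction and respiratory binning.
#
# Pipeline per receive channel: (1) average the complex self-gating samples
# of each excitation, (2) project the (Re, Im) series onto its first
# principal component, (3) Gaussian-smooth and subtract a 10 s moving
# average, (4) score each channel by the respiratory band-power ratio Theta,
# (5) keep the best channel, (6) bin excitations by gating amplitude.

#' Gating presets
#'
#' Protocol presets bundling the Gaussian smoothing window and nucleus:
#' `phantom-na` (0.7 s), `phantom-h` (0.2 s), `invivo` (1.5 s, both nuclei).
#' The moving-average detrending window is 10 s for all presets.
#' @param name preset name.
#' @return list with `gauss_window` and `ma_window` in seconds.
#' @export
gating_preset <- function(name = c("phantom-na", "phantom-h", "invivo")) {
  name <- match.arg(name)
  list(name = name,
       gauss_window = switch(name, "phantom-na" = 0.7, "phantom-h" = 0.2,
                             "invivo" = 1.5),
       ma_window = 10)
}

#' Average the self-gating samples of each excitation
#'
#' @param ksp a `kspace_data`.
#' @return complex matrix `[n_channels x n_projections]`, the arithmetic
#'   mean over each excitation's self-gating block.
#' @export
average_sg_points <- function(ksp) {
  stopifnot(inherits(ksp, "kspace_data"))
  if (is.null(ksp$selfgating) || dim(ksp$selfgating)[3] < 1) {
    stop("no self-gating samples present")
  }
  d <- dim(ksp$selfgating)
  out <- apply(ksp$selfgating, c(1, 2), mean)
  dim(out) <- d[1:2]
  out
}

#' Project a complex series onto its first principal component
#'
#' Treats each sample as the 2-vector (Re, Im), centers, and projects onto
#' the leading eigenvector of the 2x2 covariance. The sign is fixed so the
#' score correlates positively with the magnitude series (PCA sign is
#' arbitrary; a fixed rule keeps bin labels reproducible). A constant
#' (zero-variance) series returns all zeros rather than erroring, so dead
#' channels do not abort the pipeline.
#'
#' @param series complex vector (length >= 2).
#' @return real score series, mean zero.
#' @export
pca_project <- function(series) {
  if (length(series) < 2) stop("series must have length >= 2")
  X <- cbind(Re(series) - mean(Re(series)), Im(series) - mean(Im(series)))
  C <- crossprod(X) / (nrow(X) - 1)
  if (sum(C) == 0 || all(abs(C) < .Machine$double.eps)) {
    return(numeric(length(series)))
  }
  e <- eigen(C, symmetric = TRUE)
  score <- as.numeric(X %*% e$vectors[, 1])
  m <- Mod(series)
  s <- suppressWarnings(cor(score, m))
  if (!is.na(s) && s < 0) score <- -score
  score
}

# Gaussian kernel with total support `window` (sigma = window/4, truncated
# at +-2 sigma), and a boxcar of length `window`; both edge-renormalized.
.smooth_kernel <- function(x, kern) {
  n <- length(x)
  k <- length(kern)
  xs <- as.numeric(stats::filter(c(rep(0, k), x, rep(0, k)), kern, sides = 2))
  ms <- as.numeric(stats::filter(c(rep(0, k), rep(1, n), rep(0, k)), kern,
                                 sides = 2))
  (xs / ms)[(k + 1):(k + n)]
}

#' Smooth and detrend a gating series
#'
#' Gaussian smoothing (total window `gauss_window`; sigma = window/4,
#' truncated at two sigma) followed by subtraction of the same input
#' smoothed with a `ma_window` moving average. Output is approximately
#' zero-mean for stationary input. If a window exceeds the series duration
#' the global mean is subtracted instead, with a warning.
#'
#' @param series real vector sampled at `fs` Hz.
#' @param fs sampling rate in Hz (1000 / TR).
#' @param gauss_window,ma_window window lengths in seconds.
#' @return real vector of the same length.
#' @export
smooth_detrend <- function(series, fs, gauss_window = 0.7, ma_window = 10) {
  if (gauss_window <= 0 || ma_window <= 0) stop("windows must be positive")
  n <- length(series)
  dur <- n / fs
  if (gauss_window > dur || ma_window > dur) {
    warning("smoothing window exceeds series duration; subtracting global mean")
    return(series - mean(series))
  }
  sig <- gauss_window / 4 * fs
  half <- max(1L, floor(2 * sig))
  g <- exp(-0.5 * ((-half):half / sig)^2)
  sm <- .smooth_kernel(series, g / sum(g))
  mk <- max(1L, round(ma_window * fs))
  ma <- .smooth_kernel(series, rep(1 / mk, mk))
  sm - ma
}

#' Respiratory band-power quality metric
#'
#' `Theta = P[0.1, 1.0 Hz] / P[1.0, 10 Hz]` from a plain (unwindowed)
#' periodogram with rectangular band integration; larger values indicate a
#' cleaner respiratory signal. Zero high-band power yields `Inf` with a
#' warning.
#'
#' @param series real vector; @param fs sampling rate in Hz (> 20 so the
#'   high band lies below Nyquist).
#' @param band_low,band_high frequency bands in Hz.
#' @return scalar Theta > 0.
#' @export
quality_metric <- function(series, fs, band_low = c(0.1, 1), band_high = c(1, 10)) {
  if (fs <= 2 * band_high[2]) stop("fs must exceed twice the high-band edge")
  n <- length(series)
  P <- Mod(fft(series - mean(series)))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  P <- P[keep]; f <- f[keep]
  p_lo <- sum(P[f >= band_low[1] & f < band_low[2]])
  p_hi <- sum(P[f >= band_high[1] & f < band_high[2]])
  if (p_hi == 0) {
    warning("zero high-band power; Theta is infinite")
    return(Inf)
  }
  p_lo / p_hi
}

#' Extract the representative self-gating signal
#'
#' Runs the averaging, PCA projection, smoothing/detrending and
#' quality-metric steps for every channel and returns the channel with the
#' highest Theta (ties broken by the lowest channel index).
#'
#' @param ksp a `kspace_data`.
#' @param preset a [gating_preset()] or preset name.
#' @return object of class `selfgating_signal`: `values` (one real sample
#'   per excitation), `fs` (Hz), `theta`, `theta_all`, `source_channel`.
#' @export
select_gating_signal <- function(ksp, preset = "phantom-na") {
  if (is.character(preset)) preset <- gating_preset(preset)
  fs <- 1000 / ksp$tr
  avg <- average_sg_points(ksp)
  nch <- nrow(avg)
  sig <- matrix(0, nrow = nch, ncol = ncol(avg))
  theta <- numeric(nch)
  for (c in seq_len(nch)) {
    pc <- pca_project(avg[c, ])
    if (all(pc == 0)) { theta[c] <- 0; next }
    sig[c, ] <- smooth_detrend(pc, fs, preset$gauss_window, preset$ma_window)
    theta[c] <- quality_metric(sig[c, ], fs)
  }
  best <- which.max(theta)
  structure(list(values = sig[best, ], fs = fs, theta = theta[best],
                 theta_all = theta, source_channel = best,
                 preset = preset$name),
            class = "selfgating_signal")
}

#' @export
print.selfgating_signal <- function(x, ...) {
  cat(sprintf(
    "selfgating_signal: %d excitations at %g Hz, channel %d, Theta = %.3g\n",
    length(x$values), x$fs, x$source_channel, x$theta))
  invisible(x)
}

#' Amplitude-based equal-count respiratory binning
#'
#' Sorts excitations by gating amplitude and splits them into `n_bins`
#' contiguous quantile groups whose sizes differ by at most one; bin 1
#' holds the lowest amplitudes. Equal-count binning makes a 12-of-24-bin
#' motion state contain exactly half of the data.
#'
#' @param sg a `selfgating_signal` (or numeric vector of amplitudes).
#' @param n_bins number of bins (default 24).
#' @return object of class `bin_grouping` with `n_bins` and
#'   `bin_of_excitation`.
#' @export
assign_bins <- function(sg, n_bins = 24) {
  values <- if (inherits(sg, "selfgating_signal")) sg$values else as.numeric(sg)
  n <- length(values)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (n_bins > n) stop("n_bins exceeds the number of excitations")
  ord <- order(values)
  base <- n %/% n_bins
  sizes <- base + (seq_len(n_bins) <= n %% n_bins)
  lab <- integer(n)
  lab[ord] <- rep(seq_len(n_bins), times = sizes)
  structure(list(n_bins = as.integer(n_bins), bin_of_excitation = lab,
                 windows = NULL),
            class = "bin_grouping")
}

#' Group bins into sliding-window motion states
#'
#' Each motion state is a window of `width` consecutive bins. With
#' `n_states = "all"`, every window is emitted (`n_bins - width + 1`
#' windows; 19 for width 6 over 24 bins). With a finite `n_states`, window
#' start bins are spread evenly over the available range
#' (`round(seq(0, n_bins - width, length.out = n_states))`), covering both
#' extreme (end-inspiration / end-expiration) states.
#'
#' @param grouping a `bin_grouping` from [assign_bins()].
#' @param width bins per motion state (1 <= width <= n_bins).
#' @param n_states `"all"` or a finite window count.
#' @return the grouping with a `windows` data frame (`state`, `start_bin`,
#'   `width`) and `excitations_per_state` membership list.
#' @export
group_bins <- function(grouping, width, n_states = "all") {
  stopifnot(inherits(grouping, "bin_grouping"))
  nb <- grouping$n_bins
  if (width < 1 || width > nb) stop("width must lie in [1, n_bins]")
  starts <- if (identical(n_states, "all")) {
    seq_len(nb - width + 1L)
  } else {
    unique(round(seq(0, nb - width, length.out = n_states))) + 1L
  }
  windows <- data.frame(state = seq_along(starts), start_bin = starts,
                        width = as.integer(width))
  members <- lapply(starts, function(s) {
    which(grouping$bin_of_excitation %in% s:(s + width - 1L))
  })
  grouping$windows <- windows
  grouping$excitations_per_state <- members
  grouping
}

#' @export
print.bin_grouping <- function(x, ...) {
  cat(sprintf("bin_grouping: %d bins over %d excitations", x$n_bins,
              length(x$bin_of_excitation)))
  if (!is.null(x$windows)) {
    cat(sprintf(", %d motion states of width %d", nrow(x$windows),
                x$windows$width[1]))
  }
  cat("\n")
  invisible(x)
}
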