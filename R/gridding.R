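# R-side wrappers around the Kaiser-Bessel gridding primitives.
#
# All image arrays use "centered" layout: axis index i (1-based) represents
# the spatial position (i - 1 - N/2) * voxel mm, so the object center sits at
# index N/2 + 1. FFTs are evaluated with fftshift/ifftshift so that k-space
# grids are centered the same way.

.kb_defaults <- function() {
  W <- 4L
  os <- 1.25
  # Beatty et al. minimum-aliasing beta for width W and oversampling os
  beta <- pi * sqrt((W / os)^2 * (os - 0.5)^2 - 0.8)
  list(W = W, os = os, beta = beta)
}

.fftshift3 <- function(x) {
  d <- dim(x)
  ix <- lapply(d, function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2))))
  x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

.ifftshift3 <- function(x) {
  d <- dim(x)
  ix <- lapply(d, function(n) c((ceiling(n / 2) + 1):n, seq_len(ceiling(n / 2))))
  x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# Continuous Fourier transform of the (unnormalized) KB kernel of width W,
# evaluated at xi cycles-per-grid-unit; sinh branch inside the main lobe.
.kb_apod_1d <- function(xi, W, beta) {
  arg <- beta^2 - (pi * W * xi)^2
  out <- numeric(length(arg))
  pos <- arg > 0
  out[pos] <- W * sinh(sqrt(arg[pos])) / sqrt(arg[pos])
  neg <- arg < 0
  out[neg] <- W * sin(sqrt(-arg[neg])) / sqrt(-arg[neg])
  out[arg == 0] <- W
  out
}

# 3D deapodization array for an N^3 crop of a G^3 oversampled grid.
.kb_apod3 <- function(N, G, W, beta) {
  x <- (seq_len(N) - 1 - N / 2) / G
  a <- .kb_apod_1d(x, W, beta)
  outer(outer(a, a), a)
}

# Sample coordinates (cycles/mm) -> oversampled-grid units for grid G over
# voxel size vx mm.
.k_to_grid_units <- function(k_mm, G, vx) k_mm * G * vx

.oversampled_size <- function(N, os) 2L * as.integer(ceiling(os * N / 2))

#' Adjoint (gridding) NUFFT of non-Cartesian k-space samples
#'
#' Grids weighted samples onto an oversampled Cartesian grid with a
#' Kaiser-Bessel kernel (width 4, oversampling 1.25), inverse-FFTs, crops
#' and deapodizes. Approximates the adjoint discrete Fourier sum
#' `sum_i w_i y_i exp(+2i pi k_i . x)` over the `N^3` centered voxel grid.
#'
#' @param samples complex vector of k-space samples.
#' @param k_mm numeric matrix `[n x 3]` of sample coordinates in cycles/mm.
#' @param weights density-compensation weights (same length as `samples`).
#' @param n grid size N (isotropic).
#' @param voxel_size voxel size in mm.
#' @return complex `N^3` array in centered layout.
#' @export
nufft_adjoint <- function(samples, k_mm, weights, n, voxel_size) {
  p <- .kb_defaults()
  G <- .oversampled_size(n, p$os)
  u <- .k_to_grid_units(k_mm, G, voxel_size)
  vals <- as.complex(samples) * weights
  kg <- .kb_spread3(u, vals, G, p$W, p$beta)
  dim(kg) <- c(G, G, G)
  img <- .fftshift3(fft(.ifftshift3(kg), inverse = TRUE))
  lo <- G / 2 - n / 2 + 1
  img <- img[lo:(lo + n - 1), lo:(lo + n - 1), lo:(lo + n - 1)]
  img / .kb_apod3(n, G, p$W, p$beta)
}

#' Forward NUFFT: evaluate the DFT of a gridded image at arbitrary k-locations
#'
#' Deapodizes, zero-pads to the oversampled grid, FFTs and interpolates with
#' the Kaiser-Bessel kernel. Approximates
#' `F(k_i) = sum_x rho(x) exp(-2i pi k_i . x)` over voxel centers `x` (mm).
#'
#' @param img complex or numeric `N^3` array in centered layout.
#' @param k_mm numeric matrix `[n x 3]` in cycles/mm.
#' @param voxel_size voxel size in mm.
#' @return complex vector of samples.
#' @export
nufft_forward <- function(img, k_mm, voxel_size) {
  kg <- .nufft_forward_grid(img, voxel_size)
  .nufft_forward_eval(kg, k_mm, voxel_size)
}

# Split form so callers can reuse the Cartesian spectrum for many subsets.
.nufft_forward_grid <- function(img, voxel_size) {
  p <- .kb_defaults()
  n <- dim(img)[1]
  G <- .oversampled_size(n, p$os)
  imgc <- img / .kb_apod3(n, G, p$W, p$beta)
  pad <- array(0+0i, dim = c(G, G, G))
  lo <- G / 2 - n / 2 + 1
  pad[lo:(lo + n - 1), lo:(lo + n - 1), lo:(lo + n - 1)] <- imgc
  structure(.fftshift3(fft(.ifftshift3(pad))), G = G, n = n)
}

.nufft_forward_eval <- function(kgrid, k_mm, voxel_size) {
  p <- .kb_defaults()
  G <- attr(kgrid, "G")
  u <- .k_to_grid_units(k_mm, G, voxel_size)
  .kb_interp3(as.complex(kgrid), u, G, p$W, p$beta)
}

# Brute-force DFT oracles (used by the test-suite on tiny grids, and by the
# phantom simulator's exact mode). x runs over centered voxel positions.
.voxel_positions <- function(n, voxel_size) (seq_len(n) - 1 - n / 2) * voxel_size

.dft3_forward <- function(img, k_mm, voxel_size) {
  n <- dim(img)[1]
  x <- .voxel_positions(n, voxel_size)
  g <- expand.grid(x = x, y = x, z = x)
  v <- as.vector(img)
  out <- complex(length.out = nrow(k_mm))
  step <- max(1L, floor(2e6 / length(v)))
  for (i0 in seq(1, nrow(k_mm), by = step)) {
    ii <- i0:min(nrow(k_mm), i0 + step - 1)
    ph <- outer(g$x, k_mm[ii, 1]) + outer(g$y, k_mm[ii, 2]) +
      outer(g$z, k_mm[ii, 3])
    out[ii] <- as.vector(crossprod(exp(-2i * pi * ph), v))
  }
  out
}

.dft3_adjoint <- function(samples, k_mm, weights, n, voxel_size) {
  x <- .voxel_positions(n, voxel_size)
  g <- expand.grid(x = x, y = x, z = x)
  wv <- as.complex(samples) * weights
  out <- complex(length.out = nrow(g))
  step <- max(1L, floor(2e6 / length(wv)))
  for (i0 in seq(1, nrow(g), by = step)) {
    ii <- i0:min(nrow(g), i0 + step - 1)
    ph <- outer(k_mm[, 1], g$x[ii]) + outer(k_mm[, 2], g$y[ii]) +
      outer(k_mm[, 3], g$z[ii])
    out[ii] <- as.vector(crossprod(exp(+2i * pi * ph), wv))
  }
  array(out, dim = c(n, n, n))
}
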