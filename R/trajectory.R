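#' @useDynLib sodiumgate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor fft mad median quantile rnorm runif sd var
NULL

# 2D golden means: phi2 is the real root of x^3 + x = 1, phi1 = phi2^2.
# Increments of phi1 drive cos(polar angle), increments of phi2 the azimuth,
# giving a quasi-uniform, prefix-stable ordering of spoke directions.
.golden_means <- function() {
  phi2 <- polyroot(c(-1, 1, 0, 1))
  phi2 <- Re(phi2[abs(Im(phi2)) < 1e-9][1])
  c(phi1 = phi2^2, phi2 = phi2)
}

#' Generate a 2D golden-means koosh-ball trajectory
#'
#' Builds the ordered unit readout directions of a 3D center-out radial
#' ("koosh-ball") acquisition using the two-dimensional golden means
#' (increments of about 0.4656 and 0.6823). The sequence is deterministic
#' and prefix-stable: the first `m` directions of an `n`-projection
#' trajectory equal the `m`-projection trajectory.
#'
#' The polar coordinate of projection `i` (0-based) is
#' `cos(theta) = 2 * frac(i * phi1) - 1` and the azimuth
#' `phi = 2 * pi * frac(i * phi2)`.
#'
#' @param n_projections number of radial spokes (>= 1).
#' @param fov field of view in mm (isotropic).
#' @param resolution nominal isotropic voxel size in mm; sets
#'   `k_max = 0.5 / resolution` (Nyquist of the stated resolution).
#' @param tr repetition time in ms.
#' @param n_readout samples per spoke (center-out). Default
#'   `fov / (2 * resolution) + 1`, i.e. radial spacing `1 / fov` up to
#'   `k_max`.
#' @return an object of class `radial_trajectory` with fields
#'   `n_projections`, `directions` (n x 3, unit rows), `n_readout`,
#'   `k_radii` (cycles/mm, non-decreasing from 0 to `k_max`), `tr`, `fov`,
#'   `resolution`.
#' @examples
#' tr <- golden_means_trajectory(100)
#' range(sqrt(rowSums(tr$directions^2)))
#' @export
golden_means_trajectory <- function(n_projections, fov = 320, resolution = 3,
                                    tr = 10, n_readout = NULL) {
  if (length(n_projections) != 1L || !is.finite(n_projections) ||
      n_projections < 1) {
    stop("n_projections must be a positive integer")
  }
  n_projections <- as.integer(n_projections)
  if (fov <= 0 || resolution <= 0) stop("fov and resolution must be positive")
  gm <- .golden_means()
  i <- as.numeric(seq_len(n_projections) - 1L)
  cz <- 2 * ((i * gm[["phi1"]]) %% 1) - 1       # cos(polar) in [-1, 1)
  az <- 2 * pi * ((i * gm[["phi2"]]) %% 1)      # azimuth in [0, 2*pi)
  sz <- sqrt(pmax(0, 1 - cz^2))
  directions <- cbind(sz * cos(az), sz * sin(az), cz)
  if (is.null(n_readout)) n_readout <- as.integer(round(fov / (2 * resolution))) + 1L
  n_readout <- as.integer(n_readout)
  if (n_readout < 1L) stop("n_readout must be >= 1")
  k_max <- 0.5 / resolution
  k_radii <- if (n_readout == 1L) 0 else k_max * (seq_len(n_readout) - 1L) / (n_readout - 1L)
  structure(
    list(n_projections = n_projections, directions = directions,
         n_readout = n_readout, k_radii = k_radii, tr = tr, fov = fov,
         resolution = resolution),
    class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf(
    "radial_trajectory: %d projections x %d samples, FOV %g mm, %g mm voxels, TR %g ms\n",
    x$n_projections, x$n_readout, x$fov, x$resolution, x$tr))
  invisible(x)
}

#' Density-compensation weights for a 3D radial trajectory
#'
#' Per-sample weights proportional to the sampled k-space shell area
#' (`r^2` for 3D radial sampling). The center sample (`r = 0`) receives the
#' `r^2` weight of half the first radial spacing so the DC sample, which also
#' carries the gating information, is not annihilated; because every spoke
#' samples the same `k = 0` point, that floor weight is shared across the
#' spokes (divided by their number) so the center cell is not over-counted.
#' Weights are normalized to sum to one over all samples of the trajectory.
#'
#' @param traj a `radial_trajectory`.
#' @return numeric matrix `[n_readout x n_projections]` of positive weights
#'   summing to 1.
#' @export
density_compensation <- function(traj) {
  stopifnot(inherits(traj, "radial_trajectory"))
  r <- traj$k_radii
  if (length(r) == 0L || traj$n_projections < 1L) stop("empty trajectory")
  w <- r^2
  if (length(r) > 1L) {
    w[r == 0] <- (0.5 * (r[2] - r[1]))^2 / traj$n_projections
  } else {
    w[] <- 1
  }
  W <- matrix(w, nrow = traj$n_readout, ncol = traj$n_projections)
  W / sum(W)
}

#' k-space sample coordinates of a trajectory subset
#'
#' Expands spoke directions and radii into explicit per-sample coordinates
#' (cycles/mm), readout-sample fastest.
#'
#' @param traj a `radial_trajectory`.
#' @param subset projection indices (default all).
#' @return numeric matrix `[n_readout * length(subset)] x 3`.
#' @export
trajectory_coords <- function(traj, subset = seq_len(traj$n_projections)) {
  d <- traj$directions[subset, , drop = FALSE]
  r <- traj$k_radii
  # outer product: for each spoke, all radii along its direction
  kx <- outer(r, d[, 1])
  ky <- outer(r, d[, 2])
  kz <- outer(r, d[, 3])
  cbind(as.vector(kx), as.vector(ky), as.vector(kz))
}

#' Write / read a trajectory as HDF5
#'
#' Stores directions, radii and acquisition metadata in a flat HDF5 layout.
#' @param traj a `radial_trajectory`.
#' @param path output file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `radial_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(traj$directions, path, "directions")
  rhdf5::h5write(traj$k_radii, path, "k_radii")
  for (f in c("tr", "fov", "resolution", "n_projections", "n_readout")) {
    rhdf5::h5write(traj[[f]], path, f)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- rhdf5::h5read(path, "directions")
  r <- as.numeric(rhdf5::h5read(path, "k_radii"))
  rd <- function(f) as.numeric(rhdf5::h5read(path, f))
  out <- structure(
    list(n_projections = as.integer(rd("n_projections")),
         directions = d, n_readout = as.integer(rd("n_readout")),
         k_radii = r, tr = rd("tr"), fov = rd("fov"),
         resolution = rd("resolution")),
    class = "radial_trajectory")
  rhdf5::h5closeAll()
  out
}

#' Total acquisition time of a trajectory
#'
#' `n_projections x TR`, e.g. 180 000 projections at TR 10 ms give 1800 s
#' (30:00 min).
#' @param traj a `radial_trajectory` (or projection count).
#' @param tr repetition time in ms (taken from the trajectory if omitted).
#' @return list with `seconds` and a `mm:ss` display string.
#' @export
acquisition_time <- function(traj, tr = NULL) {
  np <- if (inherits(traj, "radial_trajectory")) traj$n_projections else traj
  if (is.null(tr)) tr <- if (inherits(traj, "radial_trajectory")) traj$tr else
    stop("tr required when traj is a count")
  secs <- np * tr / 1000
  list(seconds = secs,
       display = sprintf("%d:%02d", floor(secs / 60), round(secs %% 60)))
}

#' Radial k-space apodization of density-compensation weights
#'
#' Multiplies per-sample weights by a radial window, the usual low-SNR
#' X-nuclei practice: it suppresses the truncation/undersampling ringing of
#' the radial point-spread function at the cost of a broader main lobe.
#' `"hamming"` applies `0.54 + 0.46 cos(pi r / k_max)`.
#'
#' @param traj a `radial_trajectory`.
#' @param weights weight matrix from [density_compensation()].
#' @param type `"hamming"` or `"none"`.
#' @return re-normalized weight matrix.
#' @export
apodize_weights <- function(traj, weights, type = c("hamming", "none")) {
  type <- match.arg(type)
  if (type == "none") return(weights)
  h <- 0.54 + 0.46 * cos(pi * traj$k_radii / max(traj$k_radii))
  W <- weights * h
  W / sum(W)
}
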