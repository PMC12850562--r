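# Motion-resolved reconstruction: density-compensated adjoint gridding per
# channel, lowpass-ratio sensitivity estimation, and unaccelerated
# sensitivity-weighted least-squares (SENSE1) channel combination.

#' Construct an image-volume container
#'
#' @param data 3D array (complex or real), centered layout.
#' @param voxel_size isotropic voxel size in mm.
#' @param nucleus nucleus label.
#' @param motion_state window descriptor or `"unbinned"`.
#' @return object of class `image_volume`; `fov = n * voxel_size`.
#' @export
image_volume <- function(data, voxel_size, nucleus = "23Na",
                         motion_state = "unbinned") {
  stopifnot(length(dim(data)) == 3)
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data)))) {
    stop("image data must be finite everywhere")
  }
  structure(list(data = data, voxel_size = voxel_size,
                 fov = dim(data)[1] * voxel_size, nucleus = nucleus,
                 motion_state = motion_state),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume (%s, %s): %s voxels at %g mm, FOV %g mm\n",
              x$nucleus, paste(x$motion_state, collapse = ":"),
              paste(dim(x$data), collapse = "x"), x$voxel_size, x$fov))
  invisible(x)
}

#' Adjoint gridding reconstruction of an excitation subset
#'
#' Density-compensated Kaiser-Bessel gridding (adjoint NUFFT) of the
#' readout data restricted to `subset`, one volume per channel. Linear in
#' the data; weights are applied as given (no renormalization).
#'
#' @param ksp a `kspace_data`.
#' @param traj the matching `radial_trajectory`.
#' @param weights per-sample weights `[n_readout x n_projections]` from
#'   [density_compensation()].
#' @param subset excitation (projection) indices; default all.
#' @param n reconstruction grid size; default `fov / resolution` of the
#'   trajectory.
#' @return list of per-channel complex `n^3` arrays with attributes
#'   `voxel_size` and `fov`.
#' @export
adjoint_recon <- function(ksp, traj, weights, subset = NULL, n = NULL) {
  stopifnot(inherits(ksp, "kspace_data"), inherits(traj, "radial_trajectory"))
  if (is.null(subset)) subset <- seq_len(traj$n_projections)
  if (length(subset) == 0) stop("empty excitation subset")
  if (is.null(n)) n <- as.integer(round(traj$fov / traj$resolution))
  vx <- traj$fov / n
  kmm <- trajectory_coords(traj, subset)
  w <- as.vector(weights[, subset])
  imgs <- vector("list", ksp$n_channels)
  for (c in seq_len(ksp$n_channels)) {
    y <- as.vector(t(ksp$readout[c, subset, , drop = TRUE]))
    if (length(subset) == 1L) y <- as.vector(ksp$readout[c, subset, ])
    imgs[[c]] <- nufft_adjoint(y, kmm, w, n, vx)
  }
  attr(imgs, "voxel_size") <- vx
  attr(imgs, "fov") <- traj$fov
  attr(imgs, "nucleus") <- ksp$nucleus
  imgs
}

# isotropic Gaussian lowpass in image space via FFT, sigma in voxels
.lowpass3 <- function(img, sigma_vox = 2) {
  n <- dim(img)[1]
  f <- c(0:(n / 2), -(n / 2 - 1):-1) / n
  h <- exp(-2 * pi^2 * sigma_vox^2 * f^2)
  H <- outer(outer(h, h), h)
  fft(fft(img) * H, inverse = TRUE) / length(img)
}

#' Estimate coil sensitivity maps from channel images
#'
#' Lowpass-ratio estimator with root-sum-of-squares (RSS) normalization:
#' `m_c = lowpass(I_c) / RSS(lowpass(I))`. The RSS of the returned maps is
#' one wherever the object support exceeds `support_frac` of the peak RSS;
#' outside the support the maps are zero and flagged in the `support`
#' attribute.
#'
#' @param channel_images list of complex arrays (one per channel).
#' @param sigma_vox lowpass Gaussian sigma in voxels.
#' @param support_frac support threshold as a fraction of the peak RSS.
#' @return list of complex maps with logical attribute `support`.
#' @export
estimate_sensitivities <- function(channel_images, sigma_vox = 1,
                                   support_frac = 0.1) {
  if (length(channel_images) < 1) stop("need at least one channel image")
  lp <- lapply(channel_images, .lowpass3, sigma_vox = sigma_vox)
  rss <- sqrt(Reduce(`+`, lapply(lp, function(x) Mod(x)^2)))
  if (max(rss) == 0) stop("all-zero channel images")
  support <- rss > support_frac * max(rss)
  maps <- lapply(lp, function(x) {
    m <- x / rss
    m[!support] <- 0+0i
    m
  })
  attr(maps, "support") <- support
  maps
}

#' SENSE1 channel combination
#'
#' Unaccelerated sensitivity-weighted least-squares combination:
#' `rho = sum_c conj(s_c) I_c / sum_c |s_c|^2`, voxelwise. Voxels where all
#' sensitivities vanish are set to zero and flagged in the `mask`
#' attribute.
#'
#' @param channel_images list of per-channel complex arrays.
#' @param sensitivities matching list of complex maps.
#' @param ... metadata passed to [image_volume()].
#' @return an `image_volume` (complex data) with attribute `mask`.
#' @export
sense1_combine <- function(channel_images, sensitivities, ...) {
  if (length(channel_images) != length(sensitivities)) {
    stop("channel count mismatch between images and sensitivities")
  }
  num <- Reduce(`+`, Map(function(i, s) Conj(s) * i, channel_images,
                         sensitivities))
  den <- Reduce(`+`, lapply(sensitivities, function(s) Mod(s)^2))
  mask <- den > .Machine$double.eps
  out <- num
  out[mask] <- num[mask] / den[mask]
  out[!mask] <- 0+0i
  vx <- attr(channel_images, "voxel_size")
  vol <- image_volume(out, if (is.null(vx)) 1 else vx, ...)
  attr(vol, "mask") <- mask
  vol
}

#' Reconstruct all motion states of a bin grouping
#'
#' One SENSE1 volume per sliding-window motion state, each reconstructed
#' from exactly that window's excitations, plus the unbinned (all-data)
#' volume. Sensitivity maps are estimated once from the unbinned
#' reconstruction and reused for every state, which stabilizes states with
#' few excitations. Density-compensation weights are renormalized within
#' each subset so state volumes share a common intensity scale.
#'
#' @param ksp a `kspace_data`; @param traj the matching trajectory.
#' @param grouping a `bin_grouping` with windows from [group_bins()].
#' @param n reconstruction grid size (default from the trajectory).
#' @return list with `unbinned` (an `image_volume`), `states` (list of
#'   `image_volume`), `sensitivities`.
#' @export
recon_motion_states <- function(ksp, traj, grouping, n = NULL) {
  stopifnot(inherits(grouping, "bin_grouping"))
  if (is.null(grouping$windows)) stop("grouping has no windows; call group_bins()")
  w <- density_compensation(traj)
  all_imgs <- adjoint_recon(ksp, traj, w, n = n)
  sens <- estimate_sensitivities(all_imgs)
  unbinned <- sense1_combine(all_imgs, sens, nucleus = ksp$nucleus,
                             motion_state = "unbinned")
  states <- vector("list", nrow(grouping$windows))
  for (s in seq_len(nrow(grouping$windows))) {
    idx <- grouping$excitations_per_state[[s]]
    ws <- w / sum(w[, idx])
    imgs <- adjoint_recon(ksp, traj, ws, subset = idx, n = n)
    states[[s]] <- sense1_combine(imgs, sens, nucleus = ksp$nucleus,
                                  motion_state = sprintf(
                                    "state%02d(w%d@%d)", s,
                                    grouping$windows$width[s],
                                    grouping$windows$start_bin[s]))
  }
  list(unbinned = unbinned, states = states, sensitivities = sens)
}
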