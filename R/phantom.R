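# Synthetic motion-phantom generator: a static oval body with a motor-driven
# cylindrical insert holding an agar "kidney" cylinder surrounded by water,
# imaged by an 8-channel transceiver array. The generator produces raw radial
# k-space with k-space-center self-gating samples plus the ground-truth
# motion trace.

#' Build a motion-phantom model
#'
#' Describes the digital phantom: a static oval body, a static cylindrical
#' insert filled with the same solution, and a moving cylindrical insert
#' containing a concentric agar "kidney" cylinder (175 mM sodium)
#' surrounded by deionized water, translated rigidly along one axis.
#' Compartment amplitudes are relaxation-weighted scalars in arbitrary
#' units; sodium presets scale with concentration (body solution about
#' 159 mM NaCl, kidney 175 mM, deionized water none), proton presets with
#' water content.
#'
#' @param nucleus `"23Na"` or `"1H"`; selects the amplitude preset.
#' @param n grid size (isotropic voxels per dimension).
#' @param fov field of view in mm.
#' @param amplitudes optional named list overriding `body`, `static_insert`,
#'   `water`, `kidney` amplitudes (arbitrary units, all >= 0).
#' @param motion_axis unit 3-vector of insert travel (default z).
#' @return object of class `phantom_model`.
#' @export
phantom_model <- function(nucleus = c("23Na", "1H"), n = 48, fov = 320,
                          amplitudes = NULL, motion_axis = c(0, 0, 1)) {
  nucleus <- match.arg(nucleus)
  amp <- if (nucleus == "23Na") {
    list(body = 159, static_insert = 159, water = 0, kidney = 175)
  } else {
    list(body = 0.7, static_insert = 0.7, water = 1.0, kidney = 0.9)
  }
  if (!is.null(amplitudes)) amp[names(amplitudes)] <- amplitudes
  if (any(unlist(amp) < 0)) stop("compartment amplitudes must be >= 0")
  motion_axis <- motion_axis / sqrt(sum(motion_axis^2))
  geom <- list(
    body = list(semi_x = 225, semi_y = 95),
    static_insert = list(center = c(-80, 0), radius = 35, length = 280),
    bore = list(center = c(80, 0), radius = 40),
    chamber = list(center = c(80, 0), radius = 35, length = 160),
    kidney = list(center = c(80, 0), radius = 22, length = 80))
  if (geom$kidney$radius >= geom$chamber$radius ||
      geom$kidney$length >= geom$chamber$length) {
    stop("kidney cylinder must lie strictly inside the water chamber")
  }
  if (geom$chamber$radius >= geom$bore$radius) {
    stop("water chamber must lie strictly inside the moving insert bore")
  }
  structure(list(nucleus = nucleus, n = as.integer(n), fov = fov,
                 voxel_size = fov / n, amplitudes = amp, geometry = geom,
                 motion_axis = motion_axis),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("phantom_model (%s): %d^3 grid, FOV %g mm, kidney %g/%g mm\n",
              x$nucleus, x$n, x$fov, x$geometry$kidney$radius,
              x$geometry$kidney$length))
  invisible(x)
}

# fractional xy coverage of a disc of radius R centered at c0, linear
# anti-aliasing over one voxel
.disc_coverage <- function(x, y, c0, R, vx) {
  rho <- sqrt(outer((x - c0[1])^2, (y - c0[2])^2, `+`))
  pmin(pmax((R - rho) / vx + 0.5, 0), 1)
}

# fractional z coverage of the slab [z1, z2] by voxels centered at z
.slab_coverage <- function(z, z1, z2, vx) {
  pmin(pmax((pmin(z2, z + vx / 2) - pmax(z1, z - vx / 2)) / vx, 0), 1)
}

#' Rasterize the phantom at a given insert displacement
#'
#' Paints the compartments onto the voxel grid with partial-volume
#' (anti-aliased) edges, compositing in order: body, static insert, moving
#' insert bore (signal-free housing), water chamber, kidney. Only the
#' chamber and kidney translate; the body is static.
#'
#' @param phantom a `phantom_model`.
#' @param displacement insert displacement along the motion axis in mm.
#' @return numeric `n^3` array (centered layout) of signal amplitudes.
#' @export
rasterize_phantom <- function(phantom, displacement = 0) {
  n <- phantom$n
  vx <- phantom$voxel_size
  g <- phantom$geometry
  a <- phantom$amplitudes
  pos <- .voxel_positions(n, vx)
  x <- pos; y <- pos; z <- pos
  dz <- displacement * phantom$motion_axis[3]
  vol <- array(0, dim = c(n, n, n))

  paint <- function(vol, axy, az, amp) {
    A <- outer(axy, az)         # n x n x n coverage
    vol * (1 - A) + amp * A
  }
  # body: oval cylinder spanning the full FOV in z
  s <- sqrt(outer((x / g$body$semi_x)^2, (y / g$body$semi_y)^2, `+`))
  axy <- pmin(pmax((1 - s) * min(g$body$semi_x, g$body$semi_y) / vx + 0.5, 0), 1)
  vol <- paint(vol, axy, rep(1, n), a$body)
  # static insert (same solution as body)
  axy <- .disc_coverage(x, y, g$static_insert$center, g$static_insert$radius, vx)
  az <- .slab_coverage(z, -g$static_insert$length / 2, g$static_insert$length / 2, vx)
  vol <- paint(vol, axy, az, a$static_insert)
  # moving-insert bore: signal-free housing through the body
  axy <- .disc_coverage(x, y, g$bore$center, g$bore$radius, vx)
  vol <- paint(vol, axy, rep(1, n), 0)
  # water chamber and kidney, rigidly displaced along z
  axy <- .disc_coverage(x, y, g$chamber$center, g$chamber$radius, vx)
  az <- .slab_coverage(z, dz - g$chamber$length / 2, dz + g$chamber$length / 2, vx)
  vol <- paint(vol, axy, az, a$water)
  axy <- .disc_coverage(x, y, g$kidney$center, g$kidney$radius, vx)
  az <- .slab_coverage(z, dz - g$kidney$length / 2, dz + g$kidney$length / 2, vx)
  vol <- paint(vol, axy, az, a$kidney)
  vol
}

#' Generate a synthetic respiratory waveform
#'
#' Quasi-periodic displacement trace standing in for a respiratory-belt
#' recording. `regular` is a raised-cosine breathing cycle; `variable` adds
#' slow amplitude and period modulation; `apnea` interleaves breathing
#' epochs with pauses and occasional deep breaths, emulating severely
#' irregular (sleep-apnea-like) patterns. Deterministic given `seed`.
#'
#' @param duration trace length in seconds (must cover the acquisition,
#'   `n_projections * TR`).
#' @param mode `"regular"`, `"variable"` or `"apnea"`.
#' @param seed integer seed for the mode-specific randomness.
#' @param f fundamental respiratory frequency in Hz (0.1-0.5 Hz typical).
#' @param amplitude peak-to-peak excursion in mm.
#' @param dt sampling interval in seconds.
#' @return object of class `motion_waveform` with fields `t` (s),
#'   `displacement` (mm), `duration`, `dt`, `mode`.
#' @export
make_respiratory_waveform <- function(duration, mode = c("regular", "variable",
                                                         "apnea"),
                                      seed = 1, f = 0.25, amplitude = 15,
                                      dt = 0.01) {
  if (duration <= 0) stop("duration must be positive")
  mode <- match.arg(mode)
  if (f < 0.1 || f > 0.5) stop("fundamental must lie in 0.1-0.5 Hz")
  t <- seq(0, duration - dt / 2, by = dt)
  nt <- length(t)
  # smooth unit-variance modulation from a few seeded low-frequency tones
  slow <- function(fmax) {
    fr <- runif(4, 0.2 * fmax, fmax)
    ph <- runif(4, 0, 2 * pi)
    m <- rowSums(sapply(seq_len(4), function(i) sin(2 * pi * fr[i] * t + ph[i])))
    pmin(pmax(m / sd(m), -2), 2)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d <- switch(mode,
    regular = amplitude / 2 * (1 - cos(2 * pi * f * t)),
    variable = {
      # depth and rate vary slowly while the insert oscillates about its
      # home position, as a programmable motion stage executes a trace
      am <- 1 + 0.15 * slow(0.03)
      fm <- 1 + 0.15 * slow(0.02)
      phase <- 2 * pi * f * cumsum(fm) * dt
      amplitude / 2 * (1 - am * cos(phase))
    },
    apnea = {
      am <- 1 + 0.2 * slow(0.03)
      base <- amplitude / 2 * am * (1 - cos(2 * pi * f * t))
      # breathing epochs separated by pauses, smoothed over ~2 s
      env <- numeric(nt)
      tcur <- 0
      while (tcur < duration) {
        breathe <- runif(1, 20, 40)
        pause <- runif(1, 8, 20)
        env[t >= tcur & t < tcur + breathe] <- 1
        tcur <- tcur + breathe + pause
      }
      k <- round(2 / dt)
      env <- stats::filter(env, rep(1 / k, k), sides = 2)
      env[is.na(env)] <- 0
      deep <- 1 + 0.5 * (slow(0.01) > 1.5)      # occasional deep breaths
      base * as.numeric(env) * deep
    })
  structure(list(t = t, displacement = as.numeric(d), duration = duration,
                 dt = dt, mode = mode, f = f, amplitude = amplitude,
                 seed = seed),
            class = "motion_waveform")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Resample a waveform at arbitrary times
#'
#' Linear interpolation of the displacement trace at the requested times
#' (e.g. excitation timestamps, one per TR).
#' @param waveform a `motion_waveform`.
#' @param times numeric vector of times in seconds.
#' @return numeric vector of displacements (mm).
#' @export
resample_waveform <- function(waveform, times) {
  if (max(times) > waveform$duration) {
    stop("waveform shorter than requested times")
  }
  approx(waveform$t, waveform$displacement, xout = times, rule = 2)$y
}

#' Synthetic receive/transmit sensitivity maps
#'
#' Smooth per-channel complex maps emulating a body array of loop elements:
#' four anterior and four posterior Gaussian-profile elements ringing the
#' body (for other channel counts, elements are placed on a circle). The
#' anterior and posterior rows are staggered along z, as in a real flexible
#' array wrap. Channel phases increase in `360 / n_channels` degree steps
#' (45 degrees for 8 channels, as set by the feed-network splitters). A
#' small magnitude floor keeps the root-sum-of-squares positive everywhere.
#'
#' @param n grid size; @param fov field of view in mm.
#' @param n_channels number of elements (>= 1).
#' @param sigma Gaussian falloff scale in mm.
#' @return list of `n^3` complex arrays (one per channel), with attribute
#'   `centers` (element positions, mm).
#' @export
make_sensitivity_maps <- function(n, fov, n_channels = 8, sigma = 70) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  vx <- fov / n
  pos <- .voxel_positions(n, vx)
  if (n_channels == 8) {
    xs <- c(-135, -45, 45, 135)
    centers <- rbind(cbind(xs, 110, 40), cbind(xs, -110, -40))
  } else {
    ang <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
    centers <- cbind(135 * cos(ang), 110 * sin(ang),
                     ifelse(seq_len(n_channels) %% 2 == 0, 40, -40))
  }
  dph <- 2 * pi / n_channels
  maps <- vector("list", n_channels)
  for (c in seq_len(n_channels)) {
    d2 <- outer(outer((pos - centers[c, 1])^2, (pos - centers[c, 2])^2, `+`),
                (pos - centers[c, 3])^2, `+`)
    mag <- exp(-d2 / (2 * sigma^2)) + 0.02
    maps[[c]] <- mag * exp(1i * dph * (c - 1))
  }
  attr(maps, "centers") <- centers
  maps
}

# Noiseless k-space-center (DC) signal per channel for each unique quantized
# displacement; returns list(levels, dc [n_channels x n_levels]).
.dc_by_level <- function(phantom, sensitivities, levels) {
  n <- phantom$n
  nch <- length(sensitivities)
  S <- vapply(sensitivities, as.vector, complex(n^3))
  dc <- matrix(0+0i, nrow = nch, ncol = length(levels))
  for (l in seq_along(levels)) {
    v <- as.vector(rasterize_phantom(phantom, levels[l]))
    dc[, l] <- crossprod(S, v)[, 1]
  }
  dc
}

#' Per-sample noise SD realizing a given self-gating-sample SNR
#'
#' The self-gating SNR is defined as the RMS of the noiseless
#' motion-induced k-space-center modulation (best channel, static mean
#' removed) divided by the complex noise SD per sample. The absolute DC
#' level depends on arbitrary amplitude units and is removed by the
#' detrending step, so noise regimes are referenced to the modulation that
#' actually carries the respiratory information.
#'
#' @param phantom,traj,waveform,sensitivities simulation inputs.
#' @param snr target self-gating-sample SNR (e.g. 50 for a clean 1H-like
#'   regime, 10 for a noisy 23Na-like regime).
#' @param displacement_step displacement quantization of the forward model, mm.
#' @return noise SD per complex sample (same units as the phantom
#'   amplitudes).
#' @export
noise_sd_for_snr <- function(phantom, traj, waveform, sensitivities, snr,
                             displacement_step = 0.25) {
  stopifnot(snr > 0)
  ts <- (seq_len(traj$n_projections) - 1) * traj$tr / 1000
  d <- resample_waveform(waveform, ts)
  dq <- round(d / displacement_step) * displacement_step
  levels <- sort(unique(dq))
  dc <- .dc_by_level(phantom, sensitivities, levels)
  series <- dc[, match(dq, levels), drop = FALSE]
  mod <- apply(series, 1, function(z) sqrt(mean(Mod(z - mean(z))^2)))
  max(mod) / snr
}

#' Simulate a self-gated radial acquisition of the motion phantom
#'
#' Forward model: at each excitation the moving insert is displaced by the
#' waveform value at that excitation's timestamp (quantized to
#' `displacement_step`); readout samples are the discrete Fourier transform
#' of the sensitivity-weighted rasterized phantom at the spoke's k-space
#' locations (rasterize-then-NUFFT, cached per unique displacement);
#' self-gating samples are `n_sg` repeats of the k-space-center value
#' acquired before the readout. Independent complex Gaussian noise of SD
#' `noise_sd` is added to every sample. Deterministic given `seed`.
#'
#' @param phantom a `phantom_model`.
#' @param traj a `radial_trajectory` (grid/FOV need not match the phantom's;
#'   the phantom raster defines the object, the trajectory the sampling).
#' @param waveform a `motion_waveform` covering the acquisition duration.
#' @param sensitivities per-channel complex maps on the phantom grid.
#' @param noise_sd complex-sample noise SD (see [noise_sd_for_snr()]).
#' @param seed integer seed for the noise.
#' @param n_sg self-gating samples per excitation (10 for the phantom
#'   protocols, 6 for the in vivo sodium protocol).
#' @param compute_readout if `FALSE`, skip the readout forward model and
#'   return a zero readout block (fast path for gating-only studies).
#' @param displacement_step displacement quantization in mm.
#' @return object of class `kspace_data`: complex arrays `readout`
#'   `[channel x projection x readout-sample]` and `selfgating`
#'   `[channel x projection x n_sg]`, `timestamps` (s), `tr` (ms),
#'   `nucleus`, and the ground-truth motion `truth` (mm, the waveform
#'   resampled at the excitation timestamps, un-quantized).
#' @export
simulate_acquisition <- function(phantom, traj, waveform, sensitivities,
                                 noise_sd = 0, seed = 1, n_sg = 10,
                                 compute_readout = TRUE,
                                 displacement_step = 0.25) {
  stopifnot(inherits(phantom, "phantom_model"),
            inherits(traj, "radial_trajectory"),
            inherits(waveform, "motion_waveform"))
  nch <- length(sensitivities)
  np <- traj$n_projections
  nro <- traj$n_readout
  ts <- (seq_len(np) - 1) * traj$tr / 1000
  if (max(ts) > waveform$duration) {
    stop("waveform (", waveform$duration, " s) shorter than acquisition (",
         max(ts), " s)")
  }
  truth <- resample_waveform(waveform, ts)
  dq <- round(truth / displacement_step) * displacement_step
  levels <- sort(unique(dq))
  lev_of <- match(dq, levels)

  dc <- .dc_by_level(phantom, sensitivities, levels)
  sg_clean <- dc[, lev_of, drop = FALSE]       # n_channels x n_projections

  readout <- array(0+0i, dim = c(nch, np, nro))
  if (compute_readout) {
    vx <- phantom$voxel_size
    for (l in seq_along(levels)) {
      idx <- which(lev_of == l)
      kmm <- trajectory_coords(traj, idx)
      vol <- rasterize_phantom(phantom, levels[l])
      for (c in seq_len(nch)) {
        kg <- .nufft_forward_grid(vol * sensitivities[[c]], vx)
        readout[c, idx, ] <- matrix(.nufft_forward_eval(kg, kmm, vx),
                                    nrow = nro, byrow = FALSE) |> t()
      }
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cgauss <- function(n, sd) {
    complex(real = rnorm(n, sd = sd / sqrt(2)),
            imaginary = rnorm(n, sd = sd / sqrt(2)))
  }
  selfgating <- array(rep(as.vector(sg_clean), times = n_sg),
                      dim = c(nch, np, n_sg))
  if (noise_sd > 0) {
    selfgating <- selfgating + array(cgauss(nch * np * n_sg, noise_sd),
                                     dim = dim(selfgating))
    if (compute_readout) {
      readout <- readout + array(cgauss(nch * np * nro, noise_sd),
                                 dim = dim(readout))
    }
  }
  structure(list(readout = readout, selfgating = selfgating, tr = traj$tr,
                 timestamps = ts, nucleus = phantom$nucleus,
                 n_channels = nch, n_sg = n_sg, truth = truth,
                 noise_sd = noise_sd, seed = seed),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf(
    "kspace_data (%s): %d channels x %d projections x %d samples, %d self-gating points, TR %g ms\n",
    x$nucleus, x$n_channels, dim(x$readout)[2], dim(x$readout)[3], x$n_sg,
    x$tr))
  invisible(x)
}
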