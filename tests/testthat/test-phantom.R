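test_that("respiratory waveforms are deterministic, band-limited and protocol-length", {
  wf1 <- make_respiratory_waveform(60, "variable", seed = 7)
  wf2 <- make_respiratory_waveform(60, "variable", seed = 7)
  expect_identical(wf1$displacement, wf2$displacement)
  expect_false(identical(
    wf1$displacement,
    make_respiratory_waveform(60, "variable", seed = 8)$displacement))

  # dominant periodogram peak inside the respiratory band for every mode
  for (mode in c("regular", "variable", "apnea")) {
    wf <- make_respiratory_waveform(120, mode, seed = 3, f = 0.25,
                                    amplitude = 15)
    x <- wf$displacement - mean(wf$displacement)
    P <- Mod(fft(x))^2
    fr <- (seq_along(x) - 1) / (length(x) * wf$dt)
    half <- fr > 0 & fr <= 0.5 / wf$dt / 2
    fpk <- fr[half][which.max(P[half])]
    expect_gt(fpk, 0.1)
    expect_lt(fpk, 1.0)
  }

  # a 30-min trace resampled at TR = 10 ms covers 180 000 excitations
  wf <- make_respiratory_waveform(1800, "regular", seed = 1)
  ts <- (seq_len(180000) - 1) * 10 / 1000
  expect_length(resample_waveform(wf, ts), 180000)
  expect_error(make_respiratory_waveform(60, "sigh"), "arg")
  expect_error(make_respiratory_waveform(-5), "positive")
})

test_that("phantom model enforces geometry and amplitude invariants", {
  expect_error(phantom_model("23Na", amplitudes = list(body = -1)), ">= 0")
  ph <- phantom_model("23Na", n = 16, fov = 320)
  g <- ph$geometry
  expect_lt(g$kidney$radius, g$chamber$radius)
  expect_lt(g$kidney$length, g$chamber$length)
  expect_lt(g$chamber$radius, g$bore$radius)
  vol <- rasterize_phantom(ph, 0)
  expect_true(all(vol >= 0))
  expect_lte(max(vol), max(unlist(ph$amplitudes)))
  # displacement moves the kidney's center of signal along z
  com_z <- function(d) {
    v <- rasterize_phantom(ph, d)
    z <- sodiumgate:::.voxel_positions(ph$n, ph$voxel_size)
    w <- apply(v, 3, sum)
    sum(w * z) / sum(w)
  }
  expect_gt(com_z(20), com_z(0))
})

test_that("sensitivity maps are smooth, distinct and cover the volume", {
  maps <- make_sensitivity_maps(16, 320, 8)
  expect_length(maps, 8)
  rss <- sqrt(Reduce(`+`, lapply(maps, function(m) Mod(m)^2)))
  expect_true(all(rss > 0))
  mags <- vapply(maps, function(m) as.vector(Mod(m)), numeric(16^3))
  cors <- cor(mags)
  expect_true(all(cors[upper.tri(cors)] < 0.99))
  one <- make_sensitivity_maps(16, 320, 1)
  expect_length(one, 1)
  expect_error(make_sensitivity_maps(16, 320, 0), ">= 1")
})

test_that("static noiseless acquisition has constant self-gating samples", {
  s <- tiny_static_sim()
  sg <- s$ksp$selfgating
  for (c in 1:2) {
    expect_lt(max(Mod(sweep(sg[c, , ], 1, sg[c, 1, 1]))), 1e-9 * Mod(sg[c, 1, 1]))
  }
})

test_that("k-space center equals the sensitivity-weighted volume sum", {
  s <- tiny_static_sim()
  vol <- rasterize_phantom(s$phantom, 0)
  for (c in seq_along(s$sens)) {
    expect_equal(s$ksp$selfgating[c, 1, 1], sum(vol * s$sens[[c]]),
                 tolerance = 1e-10)
  }
  # moving case: oracle at the excitation's (quantized) displacement
  traj <- tiny_traj(50, n = 16)
  wf <- make_respiratory_waveform(2, "regular", seed = 2, amplitude = 12)
  ksp <- simulate_acquisition(s$phantom, traj, wf, s$sens, noise_sd = 0,
                              seed = 1, n_sg = 2, compute_readout = FALSE,
                              displacement_step = 0.25)
  i <- 27
  dq <- round(ksp$truth[i] / 0.25) * 0.25
  vol_i <- rasterize_phantom(s$phantom, dq)
  expect_equal(ksp$selfgating[2, i, 1], sum(vol_i * s$sens[[2]]),
               tolerance = 1e-10)
})

test_that("channel phases of the k-space center step by 360/n degrees", {
  s <- tiny_static_sim()
  ph <- Arg(s$ksp$selfgating[, 1, 1])
  dph <- diff(ph) %% (2 * pi)
  expect_equal(dph, rep(2 * pi / 4, 3), tolerance = 1e-9)
  maps8 <- make_sensitivity_maps(16, 320, 8)
  dc8 <- vapply(maps8, function(m) sum(m * rasterize_phantom(s$phantom, 0)),
                complex(1))
  expect_equal(diff(Arg(dc8)) %% (2 * pi), rep(pi / 4, 7), tolerance = 1e-9)
})

test_that("simulation is reproducible and validates its inputs", {
  s <- tiny_static_sim()
  traj <- tiny_traj(30, n = 16)
  wf <- make_respiratory_waveform(1, "regular", seed = 1)
  expect_error(simulate_acquisition(s$phantom, tiny_traj(200, n = 16), wf,
                                    s$sens, compute_readout = FALSE),
               "shorter")
  k1 <- simulate_acquisition(s$phantom, traj, s$wf, s$sens, noise_sd = 2,
                             seed = 9, n_sg = 3, compute_readout = FALSE)
  k2 <- simulate_acquisition(s$phantom, traj, s$wf, s$sens, noise_sd = 2,
                             seed = 9, n_sg = 3, compute_readout = FALSE)
  expect_identical(k1$selfgating, k2$selfgating)
  # ground truth travels with the data, bit-identical to the resampled trace
  expect_identical(k1$truth, resample_waveform(s$wf, k1$timestamps))
})

test_that("noiseless k-space satisfies Parseval on a Cartesian comparison grid", {
  s <- tiny_static_sim()
  n <- 16; vx <- 20
  img <- rasterize_phantom(s$phantom, 0) * s$sens[[1]]
  kidx <- (seq_len(n) - 1 - n / 2) / (n * vx)
  kmm <- as.matrix(expand.grid(kidx, kidx, kidx))
  F <- sodiumgate:::.dft3_forward(img, kmm, vx)
  expect_equal(sum(Mod(F)^2) / n^3, sum(Mod(img)^2), tolerance = 1e-8)
})
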