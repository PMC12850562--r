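test_that("self-gating averaging reduces each excitation's ADC block to its mean", {
  v <- matrix(complex(real = 1:6, imaginary = 6:1), nrow = 2)
  ksp <- synthetic_ksp(v, n_sg = 5)
  expect_equal(average_sg_points(ksp), v)
  # two-point block {1, i} averages to 0.5 + 0.5i
  ksp2 <- synthetic_ksp(matrix(0i, 1, 4), n_sg = 2)
  ksp2$selfgating[1, , 1] <- 1 + 0i
  ksp2$selfgating[1, , 2] <- 0 + 1i
  expect_equal(as.vector(average_sg_points(ksp2)), rep(0.5 + 0.5i, 4))
  # the in vivo sodium protocol stores 6 points per excitation
  ksp6 <- synthetic_ksp(matrix(complex(real = rnorm(30)), 3, 10), n_sg = 6)
  expect_equal(dim(ksp6$selfgating)[3], 6L)
  expect_equal(dim(average_sg_points(ksp6)), c(3L, 10L))
  ksp6$selfgating <- ksp6$selfgating[, , integer(0), drop = FALSE]
  expect_error(average_sg_points(ksp6), "self-gating")
})

test_that("PCA projection equals the 2x2 eigen-decomposition oracle", {
  set.seed(21)
  # purely real series: projection is the centered real part (up to sign)
  x <- rnorm(100)
  p <- pca_project(complex(real = x, imaginary = 0))
  expect_equal(abs(cor(p, x)), 1, tolerance = 1e-12)
  expect_equal(sd(p), sd(x), tolerance = 1e-12)

  # fixed-phase modulation: output proportional to the centered modulation
  m <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, sd = 0.01)
  z <- 3 * exp(1i * 0.7) * m + (2 - 1i)
  p <- pca_project(z)
  expect_equal(abs(cor(p, m)), 1, tolerance = 1e-6)

  # output variance equals the leading eigenvalue of the (Re, Im) covariance
  z <- complex(real = rnorm(500), imaginary = rnorm(500, sd = 0.4))
  p <- pca_project(z)
  C <- cov(cbind(Re(z), Im(z)))
  expect_equal(var(p), max(eigen(C, symmetric = TRUE)$values),
               tolerance = 1e-10)

  # constant (dead-channel) series yields a zero projection, not an error
  expect_equal(pca_project(rep(2 + 3i, 50)), rep(0, 50))
  expect_error(pca_project(1 + 0i), "length")
})

test_that("smoothing preserves respiratory oscillation and removes drift", {
  fs <- 100
  expect_equal(smooth_detrend(rep(5, 2000), fs), rep(0, 2000),
               tolerance = 1e-10)
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  ramp <- 0.2 * t
  sine <- sin(2 * pi * 0.3 * t)
  out <- smooth_detrend(ramp + sine, fs, gauss_window = 0.2, ma_window = 10)
  core <- seq(10 * fs, 30 * fs)        # avoid filter edge effects
  fitc <- lm(out[core] ~ sin(2 * pi * 0.3 * t[core]) +
               cos(2 * pi * 0.3 * t[core]) + t[core])
  amp <- sqrt(sum(coef(fitc)[2:3]^2))
  expect_equal(amp, 1, tolerance = 0.1)                # sinusoid preserved
  expect_lt(abs(coef(fitc)[4]), 0.02)                  # ramp suppressed
  expect_warning(smooth_detrend(rnorm(50), fs, ma_window = 10), "window")
})

test_that("the quality metric ranks respiratory-band signals", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  set.seed(22)
  dither <- rnorm(length(t), sd = 1e-4)
  expect_gt(quality_metric(sin(2 * pi * 0.3 * t) + dither, fs), 100)
  expect_lt(quality_metric(sin(2 * pi * 5 * t) + dither, fs), 0.01)
  both <- sin(2 * pi * 0.3 * t) + sin(2 * pi * 3 * t)
  # equal band powers by the periodogram oracle
  expect_equal(quality_metric(both, fs), 1, tolerance = 0.1)
  # constant input: both band powers vanish identically
  expect_warning(th <- quality_metric(rep(1, 500), fs), "high-band")
  expect_identical(th, Inf)
  expect_error(quality_metric(both, fs = 15), "Nyquist|fs")
})

test_that("Theta decreases monotonically along a seeded noise ladder", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  base <- sin(2 * pi * 0.25 * t)
  set.seed(23)
  noise <- rnorm(length(t))
  th <- vapply(c(0.01, 0.05, 0.2, 1, 5),
               function(s) quality_metric(base + s * noise, fs), numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("the channel with the cleanest respiratory signal is selected", {
  fs <- 100
  np <- 3000
  t <- (seq_len(np) - 1) / fs
  set.seed(24)
  v <- matrix(complex(real = rnorm(3 * np), imaginary = rnorm(3 * np)),
              nrow = 3)
  v[2, ] <- v[2, ] + 40 * exp(1i * 0.3) * sin(2 * pi * 0.25 * t)
  sg <- select_gating_signal(synthetic_ksp(v), preset = "phantom-na")
  expect_equal(sg$source_channel, 2L)
  expect_equal(sg$theta, max(sg$theta_all))
  expect_length(sg$values, np)
  one <- select_gating_signal(synthetic_ksp(v[2, , drop = FALSE]),
                              preset = gating_preset("phantom-h"))
  expect_equal(one$source_channel, 1L)
})

test_that("noiseless end-to-end gating tracks the ground truth", {
  # small excursions keep the k-space-center response in its linear range
  traj <- golden_means_trajectory(6000, fov = 320, resolution = 10, tr = 10)
  wf <- make_respiratory_waveform(61, "regular", seed = 1, f = 0.25,
                                  amplitude = 5)
  ph <- phantom_model("1H", n = 32, fov = 320)
  sens <- make_sensitivity_maps(32, 320, 8)
  ksp <- simulate_acquisition(ph, traj, wf, sens, noise_sd = 0, seed = 1,
                              compute_readout = FALSE)
  sg <- select_gating_signal(ksp, "phantom-h")
  expect_gt(gating_correlation(sg, ksp$truth), 0.999)
})

test_that("amplitude binning is equal-count with bin 1 at the lowest amplitudes", {
  g <- assign_bins(seq_len(240), n_bins = 24)
  expect_equal(g$bin_of_excitation, rep(1:24, each = 10))
  set.seed(25)
  g2 <- assign_bins(rnorm(1003), n_bins = 24)
  occ <- tabulate(g2$bin_of_excitation, 24)
  expect_lte(max(occ) - min(occ), 1L)
  v <- rnorm(100)
  g3 <- assign_bins(v, n_bins = 5)
  expect_lt(max(v[g3$bin_of_excitation == 1]), min(v[g3$bin_of_excitation == 5]))
  expect_error(assign_bins(rnorm(10), n_bins = 24), "exceeds")
  expect_error(assign_bins(rnorm(10), n_bins = 0), ">= 1")
})

test_that("sliding-window motion states cover the bins without duplication", {
  set.seed(26)
  g <- assign_bins(rnorm(480), n_bins = 24)
  g6 <- group_bins(g, width = 6, n_states = "all")
  expect_equal(nrow(g6$windows), 19L)
  expect_equal(nrow(group_bins(g, 24)$windows), 1L)
  expect_equal(nrow(group_bins(g, 1)$windows), 24L)
  expect_error(group_bins(g, 25), "width")

  # six states of width 12 each hold exactly half of the excitations
  g12 <- group_bins(g, width = 12, n_states = 6)
  expect_equal(nrow(g12$windows), 6L)
  expect_equal(g12$windows$start_bin, c(0, 2, 5, 7, 10, 12) + 1L)
  expect_true(all(lengths(g12$excitations_per_state) == 240L))

  # window membership equals the union of its bins, with no duplicates
  w3 <- group_bins(g, width = 3, n_states = "all")
  for (s in c(1, 10, 22)) {
    bins <- w3$windows$start_bin[s] + 0:2
    ref <- which(g$bin_of_excitation %in% bins)
    expect_identical(w3$excitations_per_state[[s]], ref)
    expect_equal(anyDuplicated(w3$excitations_per_state[[s]]), 0L)
  }
  # width-24 window contains all data
  expect_length(group_bins(g, 24)$excitations_per_state[[1]], 480L)
})
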