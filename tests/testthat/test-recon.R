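test_that("adjoint reconstruction is linear and matches the DFT oracle", {
  s <- tiny_static_sim()
  w <- density_compensation(s$traj)
  expect_error(adjoint_recon(s$ksp, s$traj, w, subset = integer(0)), "empty")

  imgs <- adjoint_recon(s$ksp, s$traj, w, n = 16)
  kmm <- trajectory_coords(s$traj)
  for (c in c(1, 3)) {
    y <- as.vector(t(s$ksp$readout[c, , ]))
    oracle <- sodiumgate:::.dft3_adjoint(y, kmm, as.vector(w), 16, 20)
    expect_lt(rel_l2(imgs[[c]], oracle), 1e-2)
  }
  # zero data give a zero image
  k0 <- s$ksp
  k0$readout[] <- 0
  z <- adjoint_recon(k0, s$traj, w, n = 16)
  expect_true(all(Mod(z[[1]]) == 0))
})

test_that("a point source at the FOV center reconstructs at the center voxel", {
  s <- tiny_static_sim()
  w <- density_compensation(s$traj)
  kd <- s$ksp
  kd$readout[] <- 1 + 0i    # constant spectrum = delta at the center
  imgs <- adjoint_recon(kd, s$traj, w, n = 16)
  peak <- which(Mod(imgs[[1]]) == max(Mod(imgs[[1]])), arr.ind = TRUE)
  expect_equal(as.vector(peak[1, ]), c(9, 9, 9))
})

test_that("sensitivity estimation recovers the maps used in simulation", {
  smooth <- with_fixture("smooth32", {
    # smooth digital object: three Gaussian compartments, 8 channels
    n <- 32; fov <- 320; vx <- 10
    pos <- sodiumgate:::.voxel_positions(n, vx)
    g3 <- function(cx, cy, cz, s, amp) {
      amp * exp(-outer(outer((pos - cx)^2, (pos - cy)^2, `+`),
                       (pos - cz)^2, `+`) / (2 * s^2))
    }
    rho <- g3(0, 0, 0, 55, 1) + g3(70, 20, -10, 30, 0.8) +
      g3(-60, -30, 20, 25, 0.6)
    sens <- make_sensitivity_maps(n, fov, 8)
    traj <- golden_means_trajectory(12000, fov = fov, resolution = vx, tr = 10)
    kmm <- trajectory_coords(traj)
    readout <- array(0+0i, dim = c(8, traj$n_projections, traj$n_readout))
    for (c in 1:8) {
      readout[c, , ] <- t(matrix(nufft_forward(rho * sens[[c]], kmm, vx),
                                 nrow = traj$n_readout))
    }
    ksp <- structure(list(
      readout = readout, selfgating = array(1 + 0i, c(8, traj$n_projections, 1)),
      tr = 10, timestamps = (seq_len(traj$n_projections) - 1) * 0.01,
      nucleus = "23Na", n_channels = 8, n_sg = 1,
      truth = rep(0, traj$n_projections), noise_sd = 0, seed = 1L),
      class = "kspace_data")
    imgs <- adjoint_recon(ksp, traj, density_compensation(traj), n = n)
    list(rho = rho, sens = sens, traj = traj, ksp = ksp, imgs = imgs,
         rss = sqrt(Reduce(`+`, lapply(sens, function(s) Mod(s)^2))))
  })
  est <- estimate_sensitivities(smooth$imgs)
  # RSS of the returned maps is 1 on the support
  rss_est <- sqrt(Reduce(`+`, lapply(est, function(m) Mod(m)^2)))
  sup <- attr(est, "support")
  expect_equal(range(rss_est[sup]), c(1, 1), tolerance = 1e-6)
  # magnitudes match the ground-truth maps inside the object
  interior <- array(FALSE, dim = rep(32, 3))
  interior[4:29, 4:29, 4:29] <- TRUE
  roi <- sup & interior & smooth$rho > 0.2
  for (c in c(2, 5, 8)) {
    tn <- Mod(smooth$sens[[c]]) / smooth$rss
    err <- median(abs(Mod(est[[c]][roi]) - tn[roi]) / tn[roi])
    expect_lt(err, 0.05)
  }
  # single channel: unit-magnitude map on support
  one <- estimate_sensitivities(smooth$imgs[1])
  expect_equal(range(Mod(one[[1]][attr(one, "support")])), c(1, 1),
               tolerance = 1e-6)
  expect_error(estimate_sensitivities(list(array(0i, rep(4, 3)))), "zero")
})

test_that("SENSE1 combination is the least-squares channel merge", {
  n <- 8
  rho <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), rep(n, 3))
  s1 <- array(1 + 0i, rep(n, 3))
  out <- sense1_combine(list(rho), list(s1))
  expect_equal(out$data, rho)                       # identity for one channel
  maps <- lapply(1:3, function(c) {
    array(complex(real = rnorm(n^3, 1), imaginary = rnorm(n^3, 0, 0.2)),
          rep(n, 3))
  })
  imgs <- lapply(maps, function(s) s * rho)
  out <- sense1_combine(imgs, maps)
  expect_lt(rel_l2(out$data, rho), 1e-12)           # exact consistency
  # voxels with zero sensitivity everywhere are zeroed and masked
  maps0 <- lapply(maps, function(s) { s[1, 1, 1] <- 0; s })
  out0 <- sense1_combine(lapply(maps0, function(s) s * rho), maps0)
  expect_identical(out0$data[1, 1, 1], 0 + 0i)
  expect_false(attr(out0, "mask")[1, 1, 1])
  expect_error(sense1_combine(imgs[1:2], maps), "channel count")
})

test_that("noiseless 8-channel simulation reconstructs the digital object", {
  smooth <- with_fixture("smooth32", stop("fixture built in earlier test"))
  est <- estimate_sensitivities(smooth$imgs)
  vol <- sense1_combine(smooth$imgs, est)
  interior <- array(FALSE, dim = rep(32, 3))
  interior[4:29, 4:29, 4:29] <- TRUE
  m <- interior & attr(est, "support")
  ref <- smooth$rho * smooth$rss
  expect_lt(rel_l2_fit(vol$data, ref, m), 0.05)
})

test_that("motion-state reconstruction partitions the data as labelled", {
  s <- tiny_static_sim()
  set.seed(30)
  g <- assign_bins(rnorm(s$traj$n_projections), n_bins = 6)
  # disjoint bins together cover every excitation exactly once
  expect_identical(sort(unlist(lapply(1:6, function(b)
    which(g$bin_of_excitation == b)))), seq_len(s$traj$n_projections))
  g <- group_bins(g, width = 6)     # single window = all data
  rec <- recon_motion_states(s$ksp, s$traj, g, n = 16)
  expect_length(rec$states, 1)
  expect_equal(rec$states[[1]]$data, rec$unbinned$data, tolerance = 1e-12)
  g2 <- group_bins(assign_bins(rnorm(s$traj$n_projections), 6), width = 2)
  rec2 <- recon_motion_states(s$ksp, s$traj, g2, n = 16)
  expect_length(rec2$states, 5)
  expect_s3_class(rec2$states[[3]], "image_volume")
  expect_error(recon_motion_states(s$ksp, s$traj, assign_bins(rnorm(300), 6),
                                   n = 16), "windows")
})
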