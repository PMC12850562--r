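# Shared tiny fixtures, built in code and memoised across tests in a file.

.fx <- new.env(parent = emptyenv())

with_fixture <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, force(expr), envir = .fx)
  }
  get(key, envir = .fx)
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# scale-invariant relative L2 over a mask (adjoint recon has arbitrary scale)
rel_l2_fit <- function(a, b, mask = TRUE) {
  a <- Mod(a)[mask]; b <- Mod(b)[mask]
  sc <- sum(a * b) / sum(b^2)
  sqrt(sum((a / sc - b)^2) / sum(b^2))
}

tiny_traj <- function(np = 200, n = 16, fov = 320) {
  golden_means_trajectory(np, fov = fov, resolution = fov / n, tr = 10)
}

# small static sodium-phantom acquisition with full readout
tiny_static_sim <- function() {
  with_fixture("static16", {
    traj <- tiny_traj(300, n = 16)
    ph <- phantom_model("23Na", n = 16, fov = 320)
    sens <- make_sensitivity_maps(16, 320, 4)
    wf <- make_respiratory_waveform(4, "regular", seed = 1, amplitude = 0)
    ksp <- simulate_acquisition(ph, traj, wf, sens, noise_sd = 0, seed = 1,
                                n_sg = 4)
    list(traj = traj, phantom = ph, sens = sens, wf = wf, ksp = ksp)
  })
}

# hand-built k-space container (no simulation) for IO / gating-surface tests
synthetic_ksp <- function(values, n_sg = 3, tr = 10, nucleus = "23Na") {
  nch <- nrow(values)
  np <- ncol(values)
  structure(list(
    readout = array(complex(real = seq_len(nch * np * 2)), c(nch, np, 2)),
    selfgating = array(rep(as.vector(values), times = n_sg), c(nch, np, n_sg)),
    tr = tr, timestamps = (seq_len(np) - 1) * tr / 1000, nucleus = nucleus,
    n_channels = nch, n_sg = n_sg, truth = NULL, noise_sd = 0, seed = 1L),
    class = "kspace_data")
}
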