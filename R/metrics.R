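# Quantitative evaluation: logistic edge-spread fit as a relative-resolution
# readout, NRMSE for model validation, and gating-vs-ground-truth
# correlation.

#' Mean signal profile along z within a cylindrical ROI
#'
#' Averages the magnitude signal over the x-y cross-section of an
#' axis-aligned cylinder at each z slice, yielding the 1D edge profile used
#' for resolution fitting.
#'
#' @param volume an `image_volume`.
#' @param roi list with `center_xy` (mm), `radius` (mm) and `z_range`
#'   (length-2, mm) describing the cylinder.
#' @return data frame with columns `z` (mm, slice centers) and `signal`.
#' @export
edge_profile <- function(volume, roi) {
  stopifnot(inherits(volume, "image_volume"))
  n <- dim(volume$data)[1]
  vx <- volume$voxel_size
  pos <- .voxel_positions(n, vx)
  inxy <- outer((pos - roi$center_xy[1])^2, (pos - roi$center_xy[2])^2,
                `+`) <= roi$radius^2
  zsel <- which(pos >= roi$z_range[1] & pos <= roi$z_range[2])
  if (!any(inxy) || length(zsel) == 0) stop("empty ROI")
  mag <- Mod(volume$data)
  sig <- vapply(zsel, function(iz) mean(mag[, , iz][inxy]), numeric(1))
  data.frame(z = pos[zsel], signal = sig)
}

#' Fit a logistic edge-spread model to a 1D profile
#'
#' Least-squares fit of `S(z) = a / (1 + exp(-(z + z0) / b)) + c`, where
#' `b` (mm) measures the transition sharpness and serves as the relative
#' image-resolution readout. Rising and falling edges are both supported
#' through the sign of `a`; `b` is kept positive. Initialization: `a` from
#' the profile endpoints, `c` from the starting level, `z0` at the
#' half-rise crossing, `b` at 10 percent of the z span, with `b` bounded by
#' the span. Non-convergence is flagged in the result rather than raised.
#'
#' @param profile numeric signal values (or the data frame from
#'   [edge_profile()], in which case `z` is taken from it).
#' @param z z coordinates in mm (>= 5 points).
#' @return object of class `logistic_fit`: `a`, `b`, `c`, `z0`, `rss`,
#'   `converged`, `fitted`.
#' @export
fit_logistic_edge <- function(profile, z = NULL) {
  if (is.data.frame(profile)) {
    z <- profile$z
    profile <- profile$signal
  }
  if (length(profile) < 5) stop("need at least 5 profile points")
  if (length(profile) != length(z)) stop("profile/z length mismatch")
  span <- diff(range(z))
  a0 <- profile[length(profile)] - profile[1]
  c0 <- profile[1]
  half <- (profile[1] + profile[length(profile)]) / 2
  cross <- which.min(abs(profile - half))
  start <- list(a = if (a0 != 0) a0 else max(profile) - min(profile),
                b = 0.1 * span, c = c0, z0 = -z[cross])
  # plogis(x) = 1 / (1 + exp(-x)), numerically safe for steep transitions;
  # nls.lm is used directly so a converged near-step edge (transition width
  # below the sample spacing) is not rejected for a rank-deficient Jacobian
  model <- function(p) p[["a"]] * stats::plogis((z + p[["z0"]]) / p[["b"]]) +
    p[["c"]]
  run_lm <- function(st) tryCatch(
    minpack.lm::nls.lm(
      par = st, fn = function(p) profile - model(p),
      lower = c(a = -Inf, b = 1e-9, c = -Inf, z0 = -Inf),
      upper = c(a = Inf, b = span, c = Inf, z0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # two starts (moderate and steep initial width) guard against the local
  # minimum that traps near-step edges
  fits <- Filter(Negate(is.null),
                 list(run_lm(start),
                      run_lm(utils::modifyList(start,
                                               list(b = 0.02 * span)))))
  fit <- if (length(fits)) fits[[which.min(vapply(fits, function(f)
    f$deviance, numeric(1)))]] else NULL
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          z0 = NA_real_, rss = NA_real_, converged = FALSE,
                          fitted = rep(NA_real_, length(z))),
                     class = "logistic_fit"))
  }
  p <- as.list(fit$par)
  structure(list(a = p$a, b = p$b, c = p$c, z0 = p$z0,
                 rss = fit$deviance, converged = TRUE,
                 fitted = model(fit$par)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: a=%.4g b=%.4g mm c=%.4g z0=%.4g (rss %.3g%s)\n",
              x$a, x$b, x$c, x$z0, x$rss,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit both faces of the kidney-cylinder edge
#'
#' Splits the z profile at the kidney center and fits the logistic edge
#' model to each dark/light transition (entering and leaving the bright
#' cylinder), pooling two sharpness readouts per volume.
#'
#' @param volume an `image_volume`; @param roi as in [edge_profile()],
#'   spanning both faces.
#' @param z_center z position of the kidney center in mm (default midpoint
#'   of `roi$z_range`).
#' @return list of two `logistic_fit` objects (`lower`, `upper`).
#' @export
fit_kidney_edges <- function(volume, roi, z_center = mean(roi$z_range)) {
  prof <- edge_profile(volume, roi)
  lower <- prof[prof$z <= z_center, ]
  upper <- prof[prof$z >= z_center, ]
  list(lower = fit_logistic_edge(lower$signal, lower$z),
       upper = fit_logistic_edge(upper$signal, upper$z))
}

#' Normalize sharpness values to a static reference
#'
#' Divides each fitted `b` by the median `b` of the static-acquisition
#' reference, so the static distribution has median one by construction.
#'
#' @param b numeric vector of fitted transition widths (mm).
#' @param reference_b numeric vector of static-reference widths (mm).
#' @return numeric vector of relative resolutions (dimensionless).
#' @export
relative_resolution <- function(b, reference_b) {
  if (length(reference_b) == 0) stop("empty reference")
  m <- median(reference_b, na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("zero or undefined reference median")
  b / m
}

#' Normalized root-mean-square error
#'
#' RMSE between `test` and `reference`, normalized by the mean of the
#' reference (the convention used for field/SAR map validation).
#'
#' @param reference,test numeric arrays of matching shape.
#' @return scalar >= 0; zero iff the arrays are identical.
#' @export
nrmse <- function(reference, test) {
  if (!isTRUE(all.equal(dim(reference), dim(test))) ||
      length(reference) != length(test)) {
    stop("shape mismatch")
  }
  m <- mean(reference)
  if (m == 0) stop("reference mean is zero")
  sqrt(mean((test - reference)^2)) / m
}

#' Correlation of a gating signal with the ground-truth motion
#'
#' Pearson correlation after sign alignment: the gating sign is arbitrary
#' (PCA orientation), so the magnitude of the correlation with the chosen
#' orientation is reported.
#'
#' @param sg a `selfgating_signal` or numeric vector.
#' @param truth numeric vector of the ground-truth displacement resampled
#'   at the excitation timestamps (same length).
#' @return Pearson `|r|` in `[0, 1]`.
#' @export
gating_correlation <- function(sg, truth) {
  v <- if (inherits(sg, "selfgating_signal")) sg$values else as.numeric(sg)
  if (length(v) != length(truth)) stop("length mismatch")
  if (sd(v) == 0 || sd(truth) == 0) stop("zero-variance input")
  abs(cor(v, truth))
}
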