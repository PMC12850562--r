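# Readers/writers: HDF5 raw container (ISMRMRD-style acquisition layout),
# NIfTI-1 image volumes, CSV waveforms and gating tables, YAML configs.
# All coordinates are physical millimetres, volume-centered origin; k-space
# in cycles/mm.

.RAW_VERSION <- "sodiumgate-raw-1"

#' Write / read the raw k-space container (HDF5)
#'
#' Stores the per-channel readout and self-gating blocks, timestamps and
#' acquisition metadata in a flat HDF5 layout. Complex data are written as
#' paired float64 real/imag datasets (HDF5 has no native complex type), so
#' the payload round-trips bit-exactly. The ground-truth motion trace, when
#' present, travels with the data.
#'
#' @param ksp a `kspace_data`.
#' @param path output `.h5` path (overwritten if present).
#' @return `write_raw` returns `path` invisibly; `read_raw` a `kspace_data`.
#' @export
write_raw <- function(ksp, path) {
  stopifnot(inherits(ksp, "kspace_data"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)
  h5w(.RAW_VERSION, "version")
  h5w(ksp$nucleus, "nucleus")
  h5w(ksp$tr, "tr")
  h5w(ksp$n_channels, "n_channels")
  h5w(ksp$n_sg, "n_sg")
  h5w(ksp$noise_sd, "noise_sd")
  h5w(ksp$timestamps, "timestamps")
  h5w(Re(ksp$readout), "readout_real")
  h5w(Im(ksp$readout), "readout_imag")
  h5w(Re(ksp$selfgating), "selfgating_real")
  h5w(Im(ksp$selfgating), "selfgating_imag")
  if (!is.null(ksp$truth)) h5w(ksp$truth, "truth")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_raw
#' @export
read_raw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)$name
  need <- c("version", "nucleus", "tr", "n_channels", "n_sg", "timestamps",
            "readout_real", "readout_imag", "selfgating_real",
            "selfgating_imag")
  miss <- setdiff(need, ls)
  if (length(miss)) stop("truncated raw container; missing: ",
                         paste(miss, collapse = ", "))
  ver <- as.character(rhdf5::h5read(path, "version"))
  if (!identical(ver, .RAW_VERSION)) {
    stop("raw container version mismatch: found '", ver, "', expected '",
         .RAW_VERSION, "'")
  }
  rd <- function(f) rhdf5::h5read(path, f)
  rr <- rd("readout_real")
  ri <- rd("readout_imag")
  sr <- rd("selfgating_real")
  si <- rd("selfgating_imag")
  nch <- as.integer(rd("n_channels"))
  if (dim(rr)[1] != nch || dim(sr)[1] != nch) {
    stop("schema error: channel count in data blocks (", dim(rr)[1],
         ") does not match header (", nch, ")")
  }
  ts <- as.numeric(rhdf5::h5read(path, "timestamps"))
  if (dim(rr)[2] != length(ts)) {
    stop("schema error: record count ", dim(rr)[2],
         " does not match timestamps (", length(ts), ")")
  }
  truth <- if ("truth" %in% ls) as.numeric(rhdf5::h5read(path, "truth")) else NULL
  nucleus <- as.character(rhdf5::h5read(path, "nucleus"))
  rhdf5::h5closeAll()
  structure(list(
    readout = array(complex(real = rr, imaginary = ri), dim = dim(rr)),
    selfgating = array(complex(real = sr, imaginary = si), dim = dim(sr)),
    tr = as.numeric(rd("tr")), timestamps = ts, nucleus = nucleus,
    n_channels = nch, n_sg = as.integer(rd("n_sg")), truth = truth,
    noise_sd = if ("noise_sd" %in% ls) as.numeric(rd("noise_sd")) else NA_real_,
    seed = NA_integer_),
    class = "kspace_data")
}

#' Write / read an image volume (NIfTI-1)
#'
#' Magnitude images with the isotropic voxel size in the header, float32
#' on disk. Reading a file with a non-isotropic header warns but proceeds
#' using the first pixel dimension.
#'
#' @param volume an `image_volume` (complex data are written as magnitude).
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  arr <- Mod(volume$data)
  attr(arr, "pixdim") <- rep(volume$voxel_size, 3)
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 1e-6 * pd[1]) {
    warning("non-isotropic voxel header (", paste(signif(pd, 4),
            collapse = " x "), " mm); using the first dimension")
  }
  image_volume(unclass(as.array(img)), voxel_size = pd[1])
}

#' Write / read a motion waveform (CSV)
#'
#' Two columns, `t` (s) and `displacement` (mm).
#' @param waveform a `motion_waveform`.
#' @param path CSV path.
#' @export
write_waveform <- function(waveform, path) {
  utils::write.csv(data.frame(t = waveform$t,
                              displacement = waveform$displacement),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t", "displacement") %in% names(d))) {
    stop("waveform CSV needs columns 't' and 'displacement'")
  }
  dt <- stats::median(diff(d$t))
  structure(list(t = d$t, displacement = d$displacement,
                 duration = max(d$t) + dt, dt = dt, mode = "recorded",
                 f = NA_real_, amplitude = max(d$displacement) -
                   min(d$displacement), seed = NA_integer_),
            class = "motion_waveform")
}

#' Export a gating result (CSV)
#'
#' Writes the per-excitation gating amplitude and, when a grouping is
#' given, the bin label; channel Theta values go to a `# theta:` comment
#' header.
#' @param sg a `selfgating_signal`; @param path CSV path.
#' @param grouping optional `bin_grouping`.
#' @export
write_gating <- function(sg, path, grouping = NULL) {
  con <- file(path, "w")
  writeLines(sprintf("# channel: %d", sg$source_channel), con)
  writeLines(sprintf("# theta: %s",
                     paste(signif(sg$theta_all, 6), collapse = ",")), con)
  d <- data.frame(excitation = seq_along(sg$values), value = sg$values)
  if (!is.null(grouping)) d$bin <- grouping$bin_of_excitation
  utils::write.csv(d, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a phantom/simulation configuration (YAML)
#'
#' Returns the YAML document as a list; recognized top-level sections are
#' `phantom`, `trajectory`, `waveform`, `noise`.
#' @param path YAML path.
#' @export
read_config <- function(path) yaml::read_yaml(path)
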