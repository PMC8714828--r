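# Shepp-Logan IVIM digital phantom: six tissue classes with ground-truth
# (f, D, D*) maps, bi-exponential DWI simulation, multi-coil complex
# Gaussian noise and sum-of-squares combination with per-slice SNR control.

# Classic ten-ellipse Shepp-Logan geometry: intensity, semi-axes (a, b),
# centre (x0, y0), rotation (degrees), in the [-1, 1]^2 head frame.
.shepp_logan_ellipses <- function() {
  m <- rbind(
    c(2.00, 0.6900, 0.9200,  0.00,  0.0000,   0),
    c(-0.98, 0.6624, 0.8740,  0.00, -0.0184,   0),
    c(-0.02, 0.1100, 0.3100,  0.22,  0.0000, -18),
    c(-0.02, 0.1600, 0.4100, -0.22,  0.0000,  18),
    c(0.01, 0.2100, 0.2500,  0.00,  0.3500,   0),
    c(0.01, 0.0460, 0.0460,  0.00,  0.1000,   0),
    c(0.01, 0.0460, 0.0460,  0.00, -0.1000,   0),
    c(0.01, 0.0460, 0.0230, -0.08, -0.6050,   0),
    c(0.01, 0.0230, 0.0230,  0.00, -0.6060,   0),
    c(0.01, 0.0230, 0.0460,  0.06, -0.6050,   0))
  colnames(m) <- c("intensity", "a", "b", "x0", "y0", "phi")
  m
}

# Ellipse -> tissue-class binning (painted in order, later ellipses
# overwrite). Classes: 1 normal tissue, 2 infiltrating tumor, 3 low-perfused
# tumor, 4 high-perfused tumor, 5 cavity, 6 CSF; 0 background.
.shepp_logan_classes <- c(1L, 1L, 6L, 6L, 2L, 4L, 3L, 5L, 5L, 4L)

#' Tissue-class labels
#'
#' @return Named integer vector mapping class names to label codes.
#' @export
tissue_classes <- function() {
  c(background = 0L, normal = 1L, infiltrating_tumor = 2L,
    low_perfused_tumor = 3L, high_perfused_tumor = 4L,
    cavity = 5L, csf = 6L)
}

#' Default IVIM tissue parameter table
#'
#' Literature-plausible (f, D, D*) triples for the six phantom classes.
#' D and D* in mm2/s. The cavity and CSF classes are free fluid: no
#' perfusion compartment (f = 0, D* = 0) and fast diffusion.
#'
#' @return data.frame with columns `class`, `f`, `D`, `Dstar`.
#' @export
default_tissue_table <- function() {
  data.frame(
    class = c("normal", "infiltrating_tumor", "low_perfused_tumor",
              "high_perfused_tumor", "cavity", "csf"),
    f     = c(0.10, 0.15, 0.05, 0.30, 0.00, 0.00),
    D     = c(0.0008, 0.0010, 0.0012, 0.0012, 0.0030, 0.0030),
    Dstar = c(0.010, 0.015, 0.008, 0.030, 0.000, 0.000),
    stringsAsFactors = FALSE)
}

#' Rasterize the Shepp-Logan geometry into tissue-class labels
#'
#' Evaluates analytic point-in-ellipse membership for the classic ten-ellipse
#' head phantom on an `nx` x `ny` grid over \[-1, 1\]^2 and paints each
#' ellipse with its tissue class (later ellipses overwrite earlier ones; the
#' binning table is `.shepp_logan_classes`, documented in the package
#' vignette). Identical for every slice.
#'
#' @param shape Integer vector `(nx, ny)` or `(nx, ny, nslices)`; nx, ny >=
#'   32.
#' @return Integer label array (2-D, or 3-D when nslices is given) with
#'   values of [tissue_classes()].
#' @export
shepp_logan_labels <- function(shape) {
  nx <- shape[1L]; ny <- shape[2L]
  if (nx < 32L || ny < 32L) stop("phantom grid must be at least 32 x 32")
  ell <- .shepp_logan_ellipses()
  x <- seq(-1, 1, length.out = nx)
  y <- seq(-1, 1, length.out = ny)
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  lab <- matrix(0L, nx, ny)
  for (i in seq_len(nrow(ell))) {
    phi <- ell[i, "phi"] * pi / 180
    dx <- X - ell[i, "x0"]; dy <- Y - ell[i, "y0"]
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    inside <- (u / ell[i, "a"])^2 + (v / ell[i, "b"])^2 <= 1
    lab[inside] <- .shepp_logan_classes[i]
  }
  if (length(shape) >= 3L && shape[3L] > 1L) {
    array(lab, dim = c(nx, ny, shape[3L]))
  } else if (length(shape) >= 3L) {
    array(lab, dim = c(nx, ny, 1L))
  } else lab
}

#' Assign ground-truth IVIM parameters to a label map
#'
#' @param labels Integer label array from [shepp_logan_labels()].
#' @param tissue_table data.frame as [default_tissue_table()].
#' @return List of arrays `gt_f`, `gt_D`, `gt_Dstar` (same shape as
#'   `labels`; background voxels are 0).
#' @export
assign_params <- function(labels, tissue_table = default_tissue_table()) {
  codes <- tissue_classes()
  present <- setdiff(unique(as.vector(labels)), 0L)
  have <- codes[tissue_table$class]
  if (any(is.na(have)) || !all(present %in% have))
    stop("configuration error: tissue_table is missing a class present in the labels")
  lut_f <- lut_D <- lut_Ds <- numeric(max(codes) + 1L)
  for (i in seq_len(nrow(tissue_table))) {
    code <- codes[[tissue_table$class[i]]]
    lut_f[code + 1L] <- tissue_table$f[i]
    lut_D[code + 1L] <- tissue_table$D[i]
    lut_Ds[code + 1L] <- tissue_table$Dstar[i]
  }
  shp <- dim(labels)
  list(gt_f = array(lut_f[labels + 1L], shp),
       gt_D = array(lut_D[labels + 1L], shp),
       gt_Dstar = array(lut_Ds[labels + 1L], shp))
}

#' Noiseless DWI simulation
#'
#' Voxelwise `s0 * ivim_signal(gt params, scheme)`.
#'
#' @param gt List with `gt_f`, `gt_D`, `gt_Dstar` 3-D arrays.
#' @param scheme An [acquisition_scheme()].
#' @param s0_map 3-D array of b = 0 amplitudes.
#' @return 4-D array `(nx, ny, nslices, m)`.
#' @export
simulate_dwi_noiseless <- function(gt, scheme, s0_map) {
  shp <- dim(gt$gt_f)
  if (!all(dim(s0_map) == shp)) stop("s0_map shape does not match ground truth")
  m <- length(scheme$bvalues)
  out <- array(0, c(shp, m))
  fv <- as.vector(gt$gt_f); Dv <- as.vector(gt$gt_D); Dsv <- as.vector(gt$gt_Dstar)
  s0 <- as.vector(s0_map)
  for (k in seq_len(m)) {
    b <- scheme$bvalues[k]
    out[, , , k] <- array(s0 * (fv * exp(-b * Dsv) + (1 - fv) * exp(-b * Dv)), shp)
  }
  out
}

#' Smooth complex coil-sensitivity maps
#'
#' Analytic multi-channel model: each coil has a Gaussian-profile magnitude
#' centred at an equally spaced angular position on a circle just outside
#' the field of view, and a linear phase ramp pointing at the coil. Maps are
#' normalized so the sum-of-squares magnitude is exactly 1 at every voxel
#' (so the zero-noise sum-of-squares combination returns the noiseless
#' magnitude unchanged). A seeded jitter of the coil radii and widths makes
#' the maps "measured-looking" yet exactly reproducible.
#'
#' @param shape `(nx, ny)`.
#' @param n_coils Number of channels (>= 1).
#' @param seed Integer seed.
#' @return Complex array `(nx, ny, n_coils)`.
#' @export
coil_sensitivity <- function(shape, n_coils = 8L, seed = 0L) {
  nx <- shape[1L]; ny <- shape[2L]
  if (n_coils < 1L) stop("need at least one coil")
  x <- seq(-1, 1, length.out = nx)
  y <- seq(-1, 1, length.out = ny)
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  jit <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% 2147483647))
    list(r = stats::runif(n_coils, 1.1, 1.3), w = stats::runif(n_coils, 0.7, 0.9))
  })
  sens <- array(complex(real = 0), c(nx, ny, n_coils))
  for (cth in seq_len(n_coils)) {
    ang <- 2 * pi * (cth - 1) / n_coils
    cx <- jit$r[cth] * cos(ang); cy <- jit$r[cth] * sin(ang)
    mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * jit$w[cth]^2))
    phase <- pi * (X * cos(ang) + Y * sin(ang)) / 2
    sens[, , cth] <- mag * exp(1i * phase)
  }
  sos <- sqrt(apply(abs(sens)^2, c(1, 2), sum))
  for (cth in seq_len(n_coils)) sens[, , cth] <- sens[, , cth] / sos
  sens
}

#' Multi-coil complex Gaussian noise and sum-of-squares combination
#'
#' Per coil c, the complex image is `signal * sens_c + N(0, sigma) +
#' i N(0, sigma)`; the combined magnitude is `sqrt(sum_c |.|^2)`. sigma is
#' chosen per slice so that (mean noiseless b = 0 signal over the
#' normal-tissue label) / sigma equals that slice's target SNR. sigma is
#' held constant across b-values within a slice (SNR is defined on the b0
#' image).
#'
#' @param noiseless 4-D array `(nx, ny, nslices, m)`.
#' @param sens Complex coil maps `(nx, ny, n_coils)` from
#'   [coil_sensitivity()].
#' @param snr_per_slice Numeric vector, one target SNR per slice (> 0).
#' @param labels Label array (2-D or 3-D) locating the normal-tissue region.
#' @param b0_index Index of a b = 0 volume (default 1).
#' @param seed Integer seed.
#' @return List with `dwi` (noisy magnitude 4-D array) and
#'   `sigma_per_slice`.
#' @export
add_noise_sos <- function(noiseless, sens, snr_per_slice, labels,
                          b0_index = 1L, seed = 0L) {
  dims <- dim(noiseless)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]; m <- dims[4L]
  if (length(snr_per_slice) != nz)
    stop("need one SNR per slice")
  if (any(snr_per_slice <= 0)) stop("SNR must be positive")
  n_coils <- dim(sens)[3L]
  lab3 <- if (length(dim(labels)) == 2L) array(labels, c(nx, ny, nz)) else labels
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  dwi <- array(0, dims)
  sigma <- numeric(nz)
  for (z in seq_len(nz)) {
    normal <- lab3[, , z] == tissue_classes()[["normal"]]
    if (!any(normal))
      stop(sprintf("slice %d has no normal-tissue voxels to calibrate SNR", z))
    b0 <- noiseless[, , z, b0_index]
    sigma[z] <- mean(b0[normal]) / snr_per_slice[z]
    acc <- array(0, c(nx, ny, m))
    sl <- noiseless[, , z, ]                  # nx x ny x m
    for (cth in seq_len(n_coils)) {
      sre <- Re(sens[, , cth]); sim <- Im(sens[, , cth])
      nre <- array(stats::rnorm(nx * ny * m, 0, sigma[z]), c(nx, ny, m))
      nim <- array(stats::rnorm(nx * ny * m, 0, sigma[z]), c(nx, ny, m))
      re <- sl * as.vector(sre) + nre
      im <- sl * as.vector(sim) + nim
      acc <- acc + re * re + im * im
    }
    dwi[, , z, ] <- sqrt(acc)
  }
  list(dwi = dwi, sigma_per_slice = sigma)
}

#' Phantom specification
#'
#' The default reproduces the reference geometry: 256 x 256 x 5 voxels, 54
#' b-values spanning 0-1000 s/mm2, per-slice SNR (2, 5, 10, 20, 50), 8
#' coils.
#'
#' @param shape `(nx, ny, nslices)`.
#' @param tissue_table See [default_tissue_table()].
#' @param bvalues An [acquisition_scheme()] or numeric b-value vector.
#' @param snr_per_slice One SNR per slice; `Inf` entries give noiseless
#'   slices.
#' @param n_coils Number of receive channels.
#' @param s0 b = 0 amplitude inside tissue (arbitrary scale, default 100).
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L, 5L),
                         tissue_table = default_tissue_table(),
                         bvalues = make_bvalues(54L),
                         snr_per_slice = c(2, 5, 10, 20, 50),
                         n_coils = 8L, s0 = 100, seed = 0L) {
  scheme <- if (inherits(bvalues, "acquisition_scheme")) bvalues
            else acquisition_scheme(bvalues)
  if (length(shape) != 3L) stop("shape must be (nx, ny, nslices)")
  if (length(snr_per_slice) != shape[3L])
    stop("need one SNR per slice")
  if (any(snr_per_slice <= 0)) stop("SNR must be positive")
  need <- setdiff(names(tissue_classes()), "background")
  if (!setequal(tissue_table$class, need))
    stop("tissue_table must contain exactly the six tissue classes")
  structure(list(shape = as.integer(shape), tissue_table = tissue_table,
                 scheme = scheme, snr_per_slice = as.numeric(snr_per_slice),
                 n_coils = as.integer(n_coils), s0 = as.numeric(s0),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the full IVIM phantom
#'
#' Composes labels, ground-truth maps, noiseless DWI simulation, coil
#' sensitivities and sum-of-squares noise. `Inf` SNR yields a noiseless
#' slice (sigma = 0).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_output`: list with `dwi`, `gt_f`,
#'   `gt_D`, `gt_Dstar`, `labels`, `sigma_per_slice`, `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- shepp_logan_labels(spec$shape)
  gt <- assign_params(labels, spec$tissue_table)
  s0_map <- array(ifelse(as.vector(labels) > 0L, spec$s0, 0), dim(labels))
  noiseless <- simulate_dwi_noiseless(gt, spec$scheme, s0_map)
  if (all(is.infinite(spec$snr_per_slice))) {
    dwi <- noiseless
    sigma <- rep(0, spec$shape[3L])
  } else {
    sens <- coil_sensitivity(spec$shape[1:2], spec$n_coils, spec$seed)
    snr <- spec$snr_per_slice
    snr[is.infinite(snr)] <- 1e12   # effectively noiseless slices
    noisy <- add_noise_sos(noiseless, sens, snr, labels,
                           b0_index = spec$scheme$b0_indices[1L],
                           seed = spec$seed + 1L)
    dwi <- noisy$dwi
    sigma <- noisy$sigma_per_slice
    sigma[is.infinite(spec$snr_per_slice)] <- 0
  }
  structure(list(dwi = dwi, gt_f = gt$gt_f, gt_D = gt$gt_D,
                 gt_Dstar = gt$gt_Dstar, labels = labels,
                 sigma_per_slice = sigma, spec = spec),
            class = "phantom_output")
}

#' @export
print.phantom_output <- function(x, ...) {
  d <- dim(x$dwi)
  cat(sprintf("IVIM phantom: %d x %d x %d x %d, SNR per slice: %s\n",
              d[1], d[2], d[3], d[4],
              paste(x$spec$snr_per_slice, collapse = ", ")))
  invisible(x)
}
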