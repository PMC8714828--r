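# Quantitative comparison harness: normalized RMSE per parameter and slice,
# method-to-method ratios, alternating b-value test-retest splitting and
# Pearson reliability.

#' Range-normalized root-mean-square error
#'
#' `sqrt(mean((est - gt)^2))` over the mask, divided by the range
#' (max - min) of the ground truth over the mask. When the ground truth is
#' constant over the mask the divisor falls back to `max(|gt|, eps)` and the
#' result carries attribute `constant_gt = TRUE`. Set
#' `normalization = "mean"` to divide by the ground-truth mean instead.
#'
#' @param est,gt Conformable numeric arrays.
#' @param mask Logical/numeric array; voxels with `mask > 0` are evaluated.
#' @param normalization `"range"` (default) or `"mean"`.
#' @param eps Floor for the constant-truth divisor (default 1e-12).
#' @return Scalar >= 0.
#' @export
normalized_rmse <- function(est, gt, mask, normalization = c("range", "mean"),
                            eps = 1e-12) {
  normalization <- match.arg(normalization)
  if (!all(dim(est) == dim(gt))) stop("est and gt are not conformable")
  sel <- as.vector(mask) > 0
  if (!any(sel)) stop("empty evaluation mask")
  e <- as.vector(est)[sel]
  g <- as.vector(gt)[sel]
  rmse <- sqrt(mean((e - g)^2))
  den <- if (normalization == "range") diff(range(g)) else abs(mean(g))
  constant <- den <= eps
  if (constant) den <- max(abs(g), eps)
  structure(rmse / den, constant_gt = constant)
}

#' Ratio of two methods' normalized RMSE
#'
#' @param rmse_a,rmse_b Scalars (or `method_report` rows) for the same
#'   parameter over the same mask.
#' @return `rmse_a / rmse_b`; a zero denominator gives `Inf` with attribute
#'   `zero_denominator = TRUE`.
#' @export
rmse_ratio <- function(rmse_a, rmse_b) {
  a <- as.numeric(rmse_a); b <- as.numeric(rmse_b)
  if (b == 0) return(structure(Inf, zero_denominator = TRUE))
  a / b
}

#' Alternating b-value test-retest split
#'
#' Sorts the scheme's b-values ascending and assigns odd ranks to half A and
#' even ranks to half B, splitting both the scheme and the data's 4th
#' dimension. Each half must contain a b = 0 measurement for normalization;
#' if one does not, the lowest-b measurement is copied into it and the
#' result is flagged (`b0_reassigned`). Schemes with a repeated b = 0 (the
#' package default) split cleanly into equal halves.
#'
#' @param data 4-D array whose 4th dimension matches the scheme.
#' @param scheme An [acquisition_scheme()] with >= 8 b-values.
#' @return List with `half_a`, `half_b`, each a list `(data, scheme,
#'   indices)`, and `b0_reassigned`.
#' @export
test_retest_split <- function(data, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  b <- scheme$bvalues
  m <- length(b)
  if (m < 8L) stop("need at least 8 b-values to split")
  if (dim(data)[4L] != m) stop("data 4th dimension does not match scheme")
  ord <- order(b)
  ia <- ord[seq(1L, m, by = 2L)]
  ib <- ord[seq(2L, m, by = 2L)]
  reassigned <- FALSE
  for (h in 1:2) {
    idx <- if (h == 1L) ia else ib
    if (!any(b[idx] == 0)) {
      # copy the globally lowest b-value measurement into this half
      lowest <- ord[1L]
      if (h == 1L) ia <- sort(c(ia, lowest)) else ib <- sort(c(ib, lowest))
      reassigned <- TRUE
    }
  }
  mk <- function(idx) list(data = data[, , , idx, drop = FALSE],
                           scheme = acquisition_scheme(b[idx]),
                           indices = idx)
  list(half_a = mk(ia), half_b = mk(ib), b0_reassigned = reassigned)
}

#' Pearson correlation between two parameter maps
#'
#' Product-moment correlation over the masked voxels.
#'
#' @param map_a,map_b Conformable numeric arrays.
#' @param mask Voxels with `mask > 0` enter; needs >= 3.
#' @return Correlation in \[-1, 1\]; `NA` with attribute
#'   `zero_variance = TRUE` when either map is constant over the mask.
#' @export
pearson_r <- function(map_a, map_b, mask) {
  sel <- as.vector(mask) > 0
  if (sum(sel) < 3L) stop("need at least 3 voxels in the mask")
  a <- as.vector(map_a)[sel]
  b <- as.vector(map_b)[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, zero_variance = TRUE))
  stats::cor(a, b)
}

#' Fit every method on every slice of a phantom and tabulate accuracy
#'
#' Runs the requested fitters slice by slice on a [make_phantom()] output
#' and reports the range-normalized RMSE of each parameter map against the
#' simulated ground truth over the tissue mask (label > 0), plus the mean
#' absolute estimate over the background (the no-tissue fluctuation metric).
#' One method failing does not abort the others.
#'
#' @param phantom A `phantom_output`.
#' @param methods Character subset of `c("topopro", "shgo", "segmented",
#'   "bayesian", "nls")`.
#' @param config A [topopro_config()] for the topological fitters.
#' @param baseline_cfg A [baseline_config()] for the reference fitters.
#' @param verbose Progress messages.
#' @return An object of class `method_report`: data.frame with columns
#'   `method`, `slice`, `snr`, `parameter`, `nrmse`, `background_mean`,
#'   plus attribute `maps` (the fitted `parameter_maps` per method).
#' @export
run_benchmark <- function(phantom, methods = c("topopro", "segmented"),
                          config = topopro_config(),
                          baseline_cfg = baseline_config(),
                          verbose = FALSE) {
  stopifnot(inherits(phantom, "phantom_output"))
  methods <- match.arg(methods, c("topopro", "shgo", "segmented", "bayesian", "nls"),
                       several.ok = TRUE)
  scheme <- phantom$spec$scheme
  nz <- dim(phantom$dwi)[3L]
  rows <- list()
  all_maps <- list()
  for (meth in methods) {
    maps <- tryCatch(
      fit_volume_method(phantom$dwi, scheme, mask = phantom$labels > 0,
                        method = meth, config = config,
                        baseline_cfg = baseline_cfg, verbose = verbose),
      error = function(e) {
        warning(sprintf("method %s failed: %s", meth, conditionMessage(e)))
        NULL
      })
    if (is.null(maps)) next
    all_maps[[meth]] <- maps
    for (z in seq_len(nz)) {
      tmask <- phantom$labels[, , z] > 0
      bmask <- !tmask
      for (par in c("f", "D", "Dstar")) {
        gt <- switch(par, f = phantom$gt_f, D = phantom$gt_D,
                     Dstar = phantom$gt_Dstar)[, , z]
        est <- maps[[par]][, , z]
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, slice = z, snr = phantom$spec$snr_per_slice[z],
          parameter = par,
          nrmse = as.numeric(normalized_rmse(est, gt, tmask)),
          background_mean = if (any(bmask)) mean(abs(est[bmask])) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  rep <- do.call(rbind, rows)
  attr(rep, "maps") <- all_maps
  class(rep) <- c("method_report", class(rep))
  rep
}

#' Fit a volume with any of the five methods
#'
#' Dispatcher used by [run_benchmark()] and the command line: the
#' topological fitters go through [fit_volume()]; the per-voxel reference
#' fitters (segmented, Bayesian initialized from segmented, bounded NLS
#' initialized from segmented) are applied voxelwise inside the mask.
#'
#' @param data 4-D array.
#' @param scheme An [acquisition_scheme()].
#' @param mask 3-D mask (default: positive mean b = 0 signal).
#' @param method One of `"topopro"`, `"shgo"`, `"segmented"`, `"bayesian"`,
#'   `"nls"`.
#' @param config,baseline_cfg Fitter configurations.
#' @param noise_floor `"auto"` (default) or `"none"`: background-estimated
#'   magnitude-bias correction, applied identically for every method (see
#'   [fit_volume()]).
#' @param verbose Progress messages.
#' @return A `parameter_maps` object.
#' @export
fit_volume_method <- function(data, scheme, mask = NULL,
                              method = c("topopro", "shgo", "segmented",
                                         "bayesian", "nls"),
                              config = topopro_config(),
                              baseline_cfg = baseline_config(),
                              noise_floor = c("auto", "none"),
                              verbose = FALSE) {
  method <- match.arg(method)
  noise_floor <- match.arg(noise_floor)
  if (method %in% c("topopro", "shgo"))
    return(fit_volume(data, scheme, mask, config, method = method,
                      noise_floor = noise_floor, verbose = verbose))
  dims <- dim(data)
  sp <- dims[1:3]
  if (is.null(mask)) mask <- apply(data[, , , scheme$b0_indices, drop = FALSE], 1:3, mean) > 0
  data <- .apply_noise_floor(data, mask, noise_floor)
  zero <- array(0, sp)
  maps <- list(f = zero, D = zero, Dstar = zero, residual = zero,
               flags = array(0L, sp))
  idx <- which(mask > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]; k <- idx[r, 3L]
    raw <- data[i, j, k, ]
    if (all(raw == 0)) { maps$flags[i, j, k] <- 4L; next }
    yv <- normalize_signal(raw, scheme)
    if (isTRUE(attr(yv, "degenerate"))) { maps$flags[i, j, k] <- 4L; next }
    seg <- fit_segmented(yv, baseline_cfg)
    p <- switch(method,
      segmented = seg,
      bayesian = fit_bayesian(yv, seg, baseline_cfg),
      nls = fit_nls(yv, seg, list(f = baseline_cfg$bounds_f,
                                  D = baseline_cfg$bounds_D,
                                  Dstar = baseline_cfg$bounds_Dstar)))
    maps$f[i, j, k] <- p$f
    maps$D[i, j, k] <- p$D
    maps$Dstar[i, j, k] <- p$Dstar
    maps$residual[i, j, k] <- full_residual(p, yv)
    maps$flags[i, j, k] <- if (isTRUE(attr(p, "degenerate"))) 1L else 0L
    if (verbose && r %% 500L == 0L)
      message(sprintf("fit_volume [%s]: %d / %d voxels", method, r, nrow(idx)))
  }
  structure(c(maps, list(config = config, method = method, mask = mask)),
            class = "parameter_maps")
}
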