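# Two-level topological IVIM fitter.
#
# Level 1 minimizes the variable-projection reduced functional over the
# nonlinear pair s = (D, D*) with the simplicial-homology optimizer; the
# perfusion fraction then follows from the linear subproblem. Level 2
# refines the full three-parameter functional, augmented by a physical
# penalty active in the low-perfusion regime, over a box centred on the
# Level-1 estimate.

#' Configuration of the two-level TopoPro fitter
#'
#' Defaults deliberately use wider boxes than classical fitters: the global
#' optimizer does not rely on tight user-supplied bounds. All rates are in
#' mm2/s.
#'
#' @param bounds_D Search interval for D (default `c(1e-5, 0.02)`).
#' @param bounds_Dstar Search interval for D* (default `c(1e-5, 0.2)`).
#' @param bounds_f Search interval for f (default `c(0, 1)`).
#' @param n_points_level1 Initial Level-1 sampling size (default 64).
#' @param n_points_level2 Initial Level-2 sampling size (default 32).
#' @param penalty_weight Penalty weight lambda >= 0 (default 10). The
#'   effective Level-2 weight is `lambda * residual_level1`, so the penalty
#'   scales with the voxel's noise power and vanishes on noiseless data; the
#'   default makes `lambda * Dstar^2` comparable to the residual's sampling
#'   fluctuations at the upper end of the D* search box, which is what lets
#'   the penalty discriminate within a noise-equivalent valley of solutions.
#' @param penalty_f_threshold Perfusion fraction below which the penalty is
#'   active (default 0.2).
#' @param level2_box_fraction Relative half-width of the Level-2 box around
#'   the Level-1 estimate, as a fraction of each global bound's width
#'   (default 0.5).
#' @param seed Integer seed driving the optimizer's sampling.
#' @return An object of class `topopro_config`.
#' @export
topopro_config <- function(bounds_D = c(1e-5, 0.02),
                           bounds_Dstar = c(1e-5, 0.2),
                           bounds_f = c(0, 1),
                           n_points_level1 = 64L,
                           n_points_level2 = 32L,
                           penalty_weight = 10,
                           penalty_f_threshold = 0.2,
                           level2_box_fraction = 0.5,
                           seed = 0L) {
  cfg <- list(bounds_D = as.numeric(bounds_D), bounds_Dstar = as.numeric(bounds_Dstar),
              bounds_f = as.numeric(bounds_f),
              n_points_level1 = as.integer(n_points_level1),
              n_points_level2 = as.integer(n_points_level2),
              penalty_weight = as.numeric(penalty_weight),
              penalty_f_threshold = as.numeric(penalty_f_threshold),
              level2_box_fraction = as.numeric(level2_box_fraction),
              seed = as.integer(seed))
  if (cfg$bounds_D[1] < 0 || cfg$bounds_Dstar[1] < 0 ||
      cfg$bounds_f[1] < 0 || cfg$bounds_f[2] > 1)
    stop("bounds must satisfy D, D* >= 0 and f within [0, 1]")
  if (cfg$penalty_f_threshold <= 0 || cfg$penalty_f_threshold >= 1)
    stop("penalty_f_threshold must lie strictly inside (0, 1)")
  if (cfg$penalty_weight < 0) stop("penalty_weight must be >= 0")
  structure(cfg, class = "topopro_config")
}

#' Low-perfusion pseudo-diffusion penalty
#'
#' When the perfusion fraction is at or below the threshold, the
#' pseudo-diffusion compartment carries almost no signal and D* is close to
#' unidentifiable (a flat valley of solutions). The penalty
#' `lambda * Dstar^2`, applied only in that regime, breaks the valley's
#' degeneracy by preferring the physically minimal pseudo-diffusion rate.
#' Above the threshold the penalty is exactly zero.
#'
#' @param params An [ivim_params()] (or coercible).
#' @param config A [topopro_config()].
#' @return Scalar >= 0.
#' @export
penalty <- function(params, config = topopro_config()) {
  p <- as_ivim_params(params)
  if (p$f <= config$penalty_f_threshold) config$penalty_weight * p$Dstar^2 else 0
}

#' Normalize a raw decay curve to S/S0
#'
#' Divides by the mean of the b = 0 measurements and clips negative values
#' (noise can push magnitude-combined background signal arbitrarily low
#' after subtraction-free normalization) to zero.
#'
#' @param raw Numeric vector of raw signal values.
#' @param scheme An [acquisition_scheme()].
#' @return A [voxel_signal()], with attributes `degenerate` (TRUE when the
#'   b = 0 mean was not positive) and `clipped` (TRUE when negatives were
#'   clipped).
#' @export
normalize_signal <- function(raw, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  raw <- as.numeric(raw)
  if (length(raw) != length(scheme$bvalues))
    stop("signal length does not match number of b-values")
  s0 <- mean(raw[scheme$b0_indices])
  degenerate <- !is.finite(s0) || s0 <= 0
  y <- if (degenerate) rep(0, length(raw)) else raw / s0
  clipped <- any(y < 0)
  y[y < 0] <- 0
  out <- voxel_signal(y, scheme)
  attr(out, "degenerate") <- degenerate
  attr(out, "clipped") <- clipped
  out
}

#' Level 1: global fit of the reduced (VarPro) functional
#'
#' Minimizes the reduced residual over the (D, D*) box with
#' [shgo_minimize()], then recovers the perfusion fraction from the linear
#' subproblem at the optimum. All refined minima of the reduced surface are
#' retained: a bimodal surface (the compartment-swap valleys) yields two.
#'
#' When several minima (sub-domains) exist, the one seeding Level 2 is
#' chosen by the lowest penalized value: each minimum's reduced residual
#' plus the low-perfusion penalty evaluated at its profiled perfusion
#' fraction, with the same noise-adaptive weight Level 2 uses. On noisy
#' low-perfusion voxels the unpenalized reduced surface routinely has its
#' global minimum at a spurious large D* (the flat-valley failure mode);
#' the penalized choice picks the physically meaningful sub-domain instead.
#'
#' @param y A [voxel_signal()] (normalized: mean b = 0 signal equals 1).
#' @param config A [topopro_config()].
#' @return List with `s_hat` (named `(D, Dstar)`), `f_hat`, `residual`,
#'   `f_robust` (high-b log-linear fraction used by the penalty
#'   classification), `minima` (all refined minima of the reduced
#'   functional, chart-normalized), `n_minima`, `degenerate`.
#' @export
fit_voxel_level1 <- function(y, config = topopro_config()) {
  stopifnot(inherits(y, "voxel_signal"))
  b <- y$scheme$bvalues
  yv <- y$y
  obj <- function(s) .reduced_resid(s[1L], s[2L], yv, b)
  res <- tryCatch(
    shgo_minimize(obj, list(config$bounds_D, config$bounds_Dstar),
                  n_points = config$n_points_level1, seed = config$seed,
                  cache_tag = "level1"),
    error = function(e) NULL)
  if (is.null(res)) {
    # optimizer failure: mono-exponential fallback, f = 0
    dgrid <- seq(config$bounds_D[1], config$bounds_D[2], length.out = 256L)
    rr <- vapply(dgrid, function(D) sum((yv - exp(-b * D))^2), numeric(1))
    Dh <- dgrid[which.min(rr)]
    return(list(s_hat = c(D = Dh, Dstar = Dh), f_hat = 0,
                residual = min(rr), minima = NULL, n_minima = 0L,
                degenerate = TRUE))
  }
  # The reduced functional is exactly symmetric under the compartment swap
  # s = (D, D*) -> (D*, D) with f -> 1 - f; normalize every refined minimum
  # to the physical chart (perfusion fraction <= 0.5) so the sub-domain
  # classification below cannot be evaded by a swapped representation.
  lam_eff <- config$penalty_weight * max(res$value, 0)
  pts <- res$minima$points
  vals <- res$minima$values
  prs <- matrix(0, length(vals), 2L)
  for (i in seq_along(vals)) {
    e_star <- exp(-b * pts[i, 2L]); e_d <- exp(-b * pts[i, 1L])
    pr <- .project_f(e_star, e_d, yv)
    if (pr[1L] > 0.5) {
      pts[i, ] <- pts[i, c(2L, 1L)]
      pr[1L] <- 1 - pr[1L]
    }
    prs[i, ] <- pr
  }
  # sub-domain choice: lowest penalized value across the refined minima,
  # with the noise-adaptive weight lambda * (best unpenalized residual)
  best_i <- 1L
  best_score <- Inf
  for (i in seq_along(vals)) {
    pen <- if (prs[i, 1L] <= config$penalty_f_threshold)
      lam_eff * pts[i, 2L]^2 else 0
    if (vals[i] + pen < best_score) {
      best_score <- vals[i] + pen
      best_i <- i
    }
  }
  s_hat <- pts[best_i, ]
  list(s_hat = c(D = s_hat[1L], Dstar = s_hat[2L]),
       f_hat = prs[best_i, 1L], residual = vals[best_i],
       f_robust = .f_loglinear(yv, b),
       minima = list(points = pts, values = vals),
       n_minima = length(vals),
       degenerate = prs[best_i, 2L] == 1)
}

# Log-linear perfusion-fraction estimate: intercept of the high-b (upper 80%
# of the b range) log-signal regression, f = 1 - exp(intercept). Decoupled
# from the D* valley, so it is a stable classifier for the low-perfusion
# regime on tissue voxels (it is unreliable for fast-decaying fluid voxels,
# whose high-b signal is pure noise — there the VarPro f is stable instead;
# the penalty classification combines both).
.f_loglinear <- function(yv, b) {
  hi <- b >= 0.2 * max(b) & yv > 0
  if (sum(hi) < 3L) return(NA_real_)
  bx <- b[hi]; ly <- log(yv[hi])
  vb <- stats::var(bx)
  if (vb == 0) return(NA_real_)
  slope <- stats::cov(bx, ly) / vb
  icpt <- mean(ly) - slope * mean(bx)
  min(1, max(0, 1 - exp(icpt)))
}

#' Level 2: penalized full-functional refinement
#'
#' Runs the simplicial-homology optimizer on the full three-parameter
#' functional plus the low-perfusion penalty, over a box centred on the
#' Level-1 estimate (half-width `level2_box_fraction` of each global bound's
#' width, intersected with the global bounds). If the refinement does not
#' improve the penalized objective relative to the Level-1 point, the
#' Level-1 point is kept and flagged. The reported residual never includes
#' the penalty term.
#'
#' The penalty enters the objective with the effective weight
#' `penalty_weight * residual_level1`: the Level-1 misfit is a proxy for the
#' voxel's noise power, so the penalty is inert on noiseless or high-SNR
#' voxels (where D* is well determined and must not be biased) and acts at
#' the scale of the noise-induced flat valley on low-SNR voxels (where it
#' selects the physically minimal D* among near-equivalent solutions).
#'
#' @param y A [voxel_signal()].
#' @param init List with `f_hat` and `s_hat` as returned by
#'   [fit_voxel_level1()].
#' @param config A [topopro_config()].
#' @param force_penalty `NA` (default) classifies the voxel from the Level-1
#'   estimates; `TRUE`/`FALSE` overrides the classification (used by the
#'   penalized restart in [fit_voxel_topopro()]).
#' @return An object of class `voxel_fit`: list with `params`
#'   (canonicalized [ivim_params()]), `residual` (unpenalized), `penalized`
#'   (penalized objective), `n_minima_level1`, `degenerate_flag`,
#'   `converged_flag`, `improved_flag`, `penalty_active`.
#' @export
fit_voxel_level2 <- function(y, init, config = topopro_config(),
                             force_penalty = NA) {
  stopifnot(inherits(y, "voxel_signal"))
  b <- y$scheme$bvalues
  yv <- y$y
  lam <- config$penalty_weight * max(init$residual, 0)
  thr <- config$penalty_f_threshold
  # The low-perfusion classification is decided once per voxel, not
  # re-evaluated on each Level-2 candidate (else the optimizer parks just
  # above the threshold with an arbitrarily large D* and evades the
  # penalty). A voxel is classified low-perfusion when either stable
  # estimate says so: the Level-1 VarPro fraction (reliable on fluids) or
  # the high-b log-linear fraction (reliable on tissue).
  pen_active <- if (!is.na(force_penalty)) isTRUE(force_penalty) else {
    (!is.null(init$f_hat) && init$f_hat <= thr) ||
      (!is.null(init$f_robust) && !is.na(init$f_robust) && init$f_robust <= thr)
  }
  obj <- if (pen_active) {
    function(x) {
      sig <- x[1L] * exp(-b * x[3L]) + (1 - x[1L]) * exp(-b * x[2L])
      r <- yv - sig
      sum(r * r) + lam * x[3L]^2
    }
  } else {
    function(x) {
      sig <- x[1L] * exp(-b * x[3L]) + (1 - x[1L]) * exp(-b * x[2L])
      r <- yv - sig
      sum(r * r)
    }
  }
  gb <- rbind(config$bounds_f, config$bounds_D, config$bounds_Dstar)
  ctr <- c(init$f_hat, init$s_hat[1L], init$s_hat[2L])
  half <- config$level2_box_fraction * (gb[, 2] - gb[, 1])
  box <- cbind(pmax(ctr - half, gb[, 1]), pmin(ctr + half, gb[, 2]))
  if (pen_active) {
    # penalty active: D* is in its unidentifiable regime, so the search is
    # not localized around the Level-1 value in that direction
    box[3L, 1L] <- gb[3L, 1L]
  }
  # a single sampling round: Level 2 is a local refinement seeded at the
  # Level-1 optimum, so the sample-doubling invariance rule that matters on
  # the global Level-1 surface buys nothing here
  res <- tryCatch(
    shgo_minimize(obj, list(box[1L, ], box[2L, ], box[3L, ]),
                  n_points = config$n_points_level2, max_iters = 1L,
                  seed = config$seed, cache_tag = "level2"),
    error = function(e) NULL)
  pen_init <- obj(ctr)
  improved <- !is.null(res) && res$value <= pen_init
  x <- if (improved) res$x else ctr
  pen_val <- if (improved) res$value else pen_init
  sig <- x[1L] * exp(-b * x[3L]) + (1 - x[1L]) * exp(-b * x[2L])
  resid <- sum((yv - sig)^2)
  params <- canonicalize(ivim_params(x[1L], x[2L], x[3L]))
  # Unidentifiable-chart collapse rules: a two-compartment label is pure
  # convention when the fit is effectively mono-exponential. Such voxels
  # are reported in the fluid convention (f = 0, single diffusion rate,
  # D* = 0) and flagged, because any D* value there is arbitrary:
  #   f >= 0.9  — the "perfusion" compartment carries ~all signal;
  #   f <= 0.02 — the perfusion compartment carries ~nothing;
  #   D* <= 1.05 D — the rates sit on the swap-symmetry axis.
  mono_collapsed <- TRUE
  if (params$f >= 0.9) {
    params <- ivim_params(0, params$Dstar, 0)
  } else if (params$f <= 0.02) {
    params <- ivim_params(0, params$D, 0)
  } else if (params$Dstar <= 1.05 * params$D) {
    params <- ivim_params(0, (1 - params$f) * params$D + params$f * params$Dstar, 0)
  } else {
    mono_collapsed <- FALSE
  }
  structure(list(params = params, residual = resid, penalized = pen_val,
                 n_minima_level1 = if (is.null(init$n_minima)) NA_integer_ else init$n_minima,
                 degenerate_flag = isTRUE(init$degenerate) || mono_collapsed,
                 converged_flag = !is.null(res),
                 improved_flag = improved,
                 penalty_active = pen_active),
            class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("voxel fit: f = %.4f, D = %.3e, D* = %.3e (residual %.3e)\n",
              x$params$f, x$params$D, x$params$Dstar, x$residual))
  invisible(x)
}

#' Fit one voxel with the full two-level pipeline
#'
#' Level 1 (reduced-functional global fit) followed by Level 2 (penalized
#' full-functional refinement). When an unpenalized Level-2 fit itself lands
#' in or near the low-perfusion regime (perfusion fraction at most the
#' threshold + 0.05), the optimizer is restarted once with the penalty
#' active — the misclassification margin mirrors the regime where the
#' penalty is guaranteed not to change a well-determined fit.
#'
#' @param y A [voxel_signal()].
#' @param config A [topopro_config()].
#' @return A `voxel_fit` (see [fit_voxel_level2()]).
#' @export
fit_voxel_topopro <- function(y, config = topopro_config()) {
  l1 <- fit_voxel_level1(y, config)
  fit <- fit_voxel_level2(y, l1, config)
  if (!fit$penalty_active && config$penalty_weight > 0) {
    pf <- min(fit$params$f, 1 - fit$params$f)
    if (pf <= config$penalty_f_threshold + 0.05) {
      fit <- fit_voxel_level2(y, l1, config, force_penalty = TRUE)
    }
  }
  fit
}

#' Estimate the sum-of-squares noise floor from background voxels
#'
#' Multi-coil magnitude images have a noise floor: for a sum-of-squares
#' combination of `Nc` coils with per-channel Gaussian noise sigma,
#' `E[M^2] = S^2 + 2 Nc sigma^2`. In signal-free background voxels `S = 0`,
#' so the per-slice mean of `M^2` over the background estimates the floor
#' `2 Nc sigma^2` directly, with no need to know `Nc` or sigma separately.
#'
#' @param data 4-D magnitude array.
#' @param background 3-D logical array of signal-free voxels.
#' @return Numeric vector: one floor estimate (squared-signal units) per
#'   slice; `NA` for slices with fewer than 30 background voxels.
#' @export
estimate_noise_floor <- function(data, background) {
  dims <- dim(data)
  vapply(seq_len(dims[3L]), function(z) {
    sel <- as.vector(background[, , z])
    if (sum(sel) < 30L) return(NA_real_)
    sl <- matrix(data[, , z, ], nrow = dims[1L] * dims[2L])
    mean(sl[sel, ]^2)
  }, numeric(1))
}

#' Subtract the noise floor in the power domain
#'
#' `sqrt(max(M^2 - floor, 0))` per slice. Standard magnitude-bias correction
#' before model fitting; the inverse of the bias the sum-of-squares
#' combination introduces.
#'
#' @param data 4-D magnitude array.
#' @param floor_per_slice From [estimate_noise_floor()]; `NA` entries leave
#'   the slice untouched.
#' @return Corrected 4-D array.
#' @export
subtract_noise_floor <- function(data, floor_per_slice) {
  out <- data
  for (z in seq_along(floor_per_slice)) {
    fl <- floor_per_slice[z]
    if (is.na(fl) || fl <= 0) next
    out[, , z, ] <- sqrt(pmax(data[, , z, ]^2 - fl, 0))
  }
  out
}

# Apply the "auto" noise-floor policy: estimate from out-of-mask voxels and
# subtract when a usable background exists.
.apply_noise_floor <- function(data, mask, noise_floor) {
  if (noise_floor == "none") return(data)
  background <- !(mask > 0)
  fl <- estimate_noise_floor(data, background)
  if (all(is.na(fl))) return(data)
  subtract_noise_floor(data, fl)
}

#' Fit a 4-D volume voxel by voxel
#'
#' Normalizes each in-mask decay curve, runs Level 1 and Level 2, and
#' assembles canonical parameter maps. Voxels outside the mask (or with
#' non-positive b = 0 signal) carry zeros in every map. The fit is
#' deterministic for a fixed `config$seed`.
#'
#' @param data 4-D numeric array `(nx, ny, nz, m)`.
#' @param scheme An [acquisition_scheme()] with m b-values.
#' @param mask Optional 3-D array; voxels with `mask > 0` are fit. Default:
#'   voxels whose mean b = 0 signal is positive.
#' @param config A [topopro_config()].
#' @param method One of `"topopro"` (two-level, default), `"shgo"` (direct
#'   simplicial-homology minimization of the full 3-D functional, no VarPro
#'   level and no penalty — the plain global-optimizer reference).
#' @param noise_floor `"auto"` (default) estimates the multi-coil magnitude
#'   noise floor from out-of-mask background voxels and subtracts it in the
#'   power domain before fitting (see [estimate_noise_floor()]); `"none"`
#'   fits the magnitudes as-is. Slices without a usable background are left
#'   untouched.
#' @param verbose Print progress every 500 voxels.
#' @return An object of class `parameter_maps`: list with 3-D arrays `f`,
#'   `D`, `Dstar`, `residual`, integer `flags` (bit 1 degenerate, bit 2
#'   non-converged, bit 4 all-zero voxel), the `config`, and `method`.
#' @export
fit_volume <- function(data, scheme, mask = NULL, config = topopro_config(),
                       method = c("topopro", "shgo"),
                       noise_floor = c("auto", "none"), verbose = FALSE) {
  method <- match.arg(method)
  noise_floor <- match.arg(noise_floor)
  dims <- dim(data)
  if (length(dims) != 4L) stop("data must be a 4-D array")
  if (dims[4L] != length(scheme$bvalues))
    stop(sprintf("4th dimension (%d) does not match number of b-values (%d)",
                 dims[4L], length(scheme$bvalues)))
  sp <- dims[1:3]
  b0 <- scheme$b0_indices
  if (is.null(mask)) {
    mask <- apply(data[, , , b0, drop = FALSE], 1:3, mean) > 0
  }
  if (!all(dim(mask) == sp)) stop("mask dimensions do not match data")
  data <- .apply_noise_floor(data, mask, noise_floor)
  zero <- array(0, sp)
  maps <- list(f = zero, D = zero, Dstar = zero, residual = zero,
               flags = array(0L, sp))
  idx <- which(mask > 0, arr.ind = TRUE)
  memo <- new.env(parent = emptyenv())   # identical decay curves fit once
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]; k <- idx[r, 3L]
    raw <- data[i, j, k, ]
    if (all(raw == 0)) { maps$flags[i, j, k] <- 4L; next }
    key <- paste(raw, collapse = ",")
    fit <- memo[[key]]
    if (is.null(fit)) {
      yv <- normalize_signal(raw, scheme)
      if (isTRUE(attr(yv, "degenerate"))) { maps$flags[i, j, k] <- 4L; next }
      fit <- if (method == "topopro") {
        fit_voxel_topopro(yv, config)
      } else {
        .fit_voxel_shgo3d(yv, config)
      }
      memo[[key]] <- fit
    }
    maps$f[i, j, k] <- fit$params$f
    maps$D[i, j, k] <- fit$params$D
    maps$Dstar[i, j, k] <- fit$params$Dstar
    maps$residual[i, j, k] <- fit$residual
    maps$flags[i, j, k] <- (if (fit$degenerate_flag) 1L else 0L) +
      (if (!fit$converged_flag) 2L else 0L)
    if (verbose && r %% 500L == 0L)
      message(sprintf("fit_volume [%s]: %d / %d voxels", method, r, nrow(idx)))
  }
  structure(c(maps, list(config = config, method = method, mask = mask)),
            class = "parameter_maps")
}

# Plain SHGO on the full 3-D functional: no VarPro level, no penalty. Used
# as the "SHGO" reference method in benchmarks.
.fit_voxel_shgo3d <- function(y, config) {
  b <- y$scheme$bvalues
  yv <- y$y
  obj <- function(x) {
    r <- yv - x[1L] * exp(-b * x[3L]) - (1 - x[1L]) * exp(-b * x[2L])
    sum(r * r)
  }
  res <- tryCatch(
    shgo_minimize(obj, list(config$bounds_f, config$bounds_D, config$bounds_Dstar),
                  n_points = config$n_points_level1, seed = config$seed,
                  cache_tag = "shgo3d"),
    error = function(e) NULL)
  if (is.null(res)) {
    return(structure(list(params = ivim_params(0, 0, 0), residual = sum(yv^2),
                          penalized = NA_real_, n_minima_level1 = NA_integer_,
                          degenerate_flag = TRUE, converged_flag = FALSE,
                          improved_flag = FALSE), class = "voxel_fit"))
  }
  params <- canonicalize(ivim_params(res$x[1L], res$x[2L], res$x[3L]))
  structure(list(params = params, residual = res$value, penalized = res$value,
                 n_minima_level1 = length(res$minima$values),
                 degenerate_flag = FALSE, converged_flag = TRUE,
                 improved_flag = TRUE),
            class = "voxel_fit")
}

#' @export
print.parameter_maps <- function(x, ...) {
  n <- sum(x$mask > 0)
  cat(sprintf("parameter maps (%s): %d x %d x %d, %d voxels fit\n",
              x$method, dim(x$f)[1], dim(x$f)[2], dim(x$f)[3], n))
  invisible(x)
}
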