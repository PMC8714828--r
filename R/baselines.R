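# Reference IVIM fitters: segmented two-stage fitting, random-walk
# Metropolis with a flat prior, and bounded trust-region nonlinear least
# squares.

#' Configuration for the baseline fitters
#'
#' Defaults follow the common clinical setup: b-value threshold 200 s/mm2
#' separating the perfusion and diffusion regimes, and bounds f in
#' \[0, 0.9\], D in \[0, 0.004\], D* in \[0, 0.1\]. MCMC defaults: 5000
#' samples, burn-in 1000, Gaussian proposals with step 2% of each bound's
#' width, single chain.
#'
#' @param b_threshold Segmentation threshold, s/mm2.
#' @param bounds_f,bounds_D,bounds_Dstar Parameter bounds `(lo, hi)`.
#' @param burn_in Discarded Metropolis samples (must be < `n_samples`).
#' @param n_samples Total Metropolis samples.
#' @param proposal_scales Per-parameter proposal standard deviations
#'   `(f, D, Dstar)`; default 2% of each bound's width.
#' @param seed Integer seed for the chain.
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(b_threshold = 200,
                            bounds_f = c(0, 0.9),
                            bounds_D = c(0, 0.004),
                            bounds_Dstar = c(0, 0.1),
                            burn_in = 1000L,
                            n_samples = 5000L,
                            proposal_scales = NULL,
                            seed = 0L) {
  if (burn_in >= n_samples) stop("burn_in must be smaller than n_samples")
  if (is.null(proposal_scales))
    proposal_scales <- 0.02 * c(diff(bounds_f), diff(bounds_D), diff(bounds_Dstar))
  structure(list(b_threshold = b_threshold,
                 bounds_f = as.numeric(bounds_f),
                 bounds_D = as.numeric(bounds_D),
                 bounds_Dstar = as.numeric(bounds_Dstar),
                 burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 proposal_scales = as.numeric(proposal_scales),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

.clip <- function(x, b) min(max(x, b[1L]), b[2L])

#' Segmented (two-stage) IVIM fit
#'
#' Stage 1: ordinary least squares of log(y) on b restricted to
#' b >= threshold, where the perfusion compartment has decayed away; D is
#' the negative slope and f = 1 - exp(intercept). Stage 2: with f and D
#' fixed, a 1-D bounded minimization of the full residual over D* on all
#' points. All parameters are clipped to the configured bounds; bound
#' violations are flagged rather than discarded.
#'
#' @param y A [voxel_signal()].
#' @param config A [baseline_config()].
#' @return An [ivim_params()] with attributes `degenerate` (logical) and
#'   `clipped` (logical).
#' @export
fit_segmented <- function(y, config = baseline_config()) {
  stopifnot(inherits(y, "voxel_signal"))
  b <- y$scheme$bvalues
  yv <- y$y
  hi <- b >= config$b_threshold & yv > 0
  degenerate <- FALSE
  if (sum(hi) < 2L) {
    # not enough usable high-b points: mono-exponential fit on whatever is
    # positive, f = 0
    pos <- yv > 0
    if (sum(pos) >= 2L) {
      co <- stats::coef(stats::lm(log(yv[pos]) ~ b[pos]))
      D <- .clip(-co[[2L]], config$bounds_D)
    } else D <- 0
    p <- ivim_params(0, D, .clip(D, config$bounds_Dstar))
    attr(p, "degenerate") <- TRUE
    attr(p, "clipped") <- FALSE
    return(p)
  }
  co <- stats::coef(stats::lm(log(yv[hi]) ~ b[hi]))
  D_raw <- -co[[2L]]
  f_raw <- 1 - exp(co[[1L]])
  D <- .clip(D_raw, config$bounds_D)
  f <- .clip(f_raw, config$bounds_f)
  clipped <- (D != D_raw) || (f != f_raw)
  # stage 2: 1-D bounded NLS over Dstar with f, D held fixed
  obj <- function(Ds) {
    r <- yv - f * exp(-b * Ds) - (1 - f) * exp(-b * D)
    sum(r * r)
  }
  Ds <- if (f > 0) {
    opt <- stats::optimize(obj, lower = config$bounds_Dstar[1L],
                           upper = config$bounds_Dstar[2L], tol = 1e-10)
    opt$minimum
  } else .clip(D, config$bounds_Dstar)   # no perfusion signal: Dstar undetermined
  p <- ivim_params(f, D, Ds)
  attr(p, "degenerate") <- degenerate
  attr(p, "clipped") <- clipped
  p
}

#' Bayesian IVIM fit (random-walk Metropolis, flat prior)
#'
#' Random-walk Metropolis on (f, D, D*) with a Gaussian likelihood whose
#' noise scale is profiled out: the log-likelihood is
#' `-(m/2) log(RSS(theta))`, the marginal form obtained by maximizing over
#' sigma at each step. The prior is flat on the configured bounds
#' (proposals outside have prior zero and are always rejected). The
#' posterior mean of the retained samples is returned.
#'
#' @param y A [voxel_signal()].
#' @param init An [ivim_params()] starting point (commonly the segmented
#'   fit), inside the bounds.
#' @param config A [baseline_config()].
#' @return An [ivim_params()] (posterior mean, canonicalized) with
#'   attributes `acceptance_rate` and `poor_mixing` (TRUE when acceptance
#'   < 1%).
#' @export
fit_bayesian <- function(y, init, config = baseline_config()) {
  stopifnot(inherits(y, "voxel_signal"))
  init <- as_ivim_params(init)
  b <- y$scheme$bvalues
  yv <- y$y
  m <- length(yv)
  lb <- c(config$bounds_f[1L], config$bounds_D[1L], config$bounds_Dstar[1L])
  ub <- c(config$bounds_f[2L], config$bounds_D[2L], config$bounds_Dstar[2L])
  th <- pmin(pmax(c(init$f, init$D, init$Dstar), lb), ub)
  loglik <- function(t) {
    r <- yv - t[1L] * exp(-b * t[3L]) - (1 - t[1L]) * exp(-b * t[2L])
    -(m / 2) * log(sum(r * r) + 1e-300)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_samples
  sc <- config$proposal_scales
  ll <- loglik(th)
  keep <- matrix(0, n, 3L)
  acc <- 0L
  steps <- matrix(stats::rnorm(3L * n), n, 3L)
  us <- log(stats::runif(n))
  for (i in seq_len(n)) {
    prop <- th + sc * steps[i, ]
    if (all(prop >= lb) && all(prop <= ub)) {   # flat prior support
      llp <- loglik(prop)
      if (us[i] < llp - ll) { th <- prop; ll <- llp; acc <- acc + 1L }
    }
    keep[i, ] <- th
  }
  post <- colMeans(keep[(config$burn_in + 1L):n, , drop = FALSE])
  out <- canonicalize(ivim_params(post[1L], post[2L], post[3L]))
  attr(out, "acceptance_rate") <- acc / n
  attr(out, "poor_mixing") <- (acc / n) < 0.01
  out
}

#' Bounded nonlinear least-squares IVIM fit
#'
#' Levenberg-Marquardt trust-region minimization of the full residual from
#' the given start, with box bounds; the canonical representative is
#' returned.
#'
#' @param y A [voxel_signal()].
#' @param init An [ivim_params()] starting point.
#' @param bounds List with `f`, `D`, `Dstar` bound pairs; defaults to the
#'   [baseline_config()] bounds.
#' @return An [ivim_params()] with attribute `converged`.
#' @export
fit_nls <- function(y, init, bounds = NULL) {
  stopifnot(inherits(y, "voxel_signal"))
  init <- as_ivim_params(init)
  if (is.null(bounds)) {
    cfg <- baseline_config()
    bounds <- list(f = cfg$bounds_f, D = cfg$bounds_D, Dstar = cfg$bounds_Dstar)
  }
  b <- y$scheme$bvalues
  yv <- y$y
  lb <- c(bounds$f[1L], bounds$D[1L], bounds$Dstar[1L])
  ub <- c(bounds$f[2L], bounds$D[2L], bounds$Dstar[2L])
  th0 <- pmin(pmax(c(init$f, init$D, init$Dstar), lb), ub)
  # iteration exhaustion is reported via the `converged` attribute, not as
  # a raw solver warning (stalling is an expected failure mode on the
  # swap-symmetry ridge)
  res <- suppressWarnings(minpack.lm::nls.lm(
    par = th0,
    lower = lb, upper = ub,
    fn = function(t) yv - t[1L] * exp(-b * t[3L]) - (1 - t[1L]) * exp(-b * t[2L])))
  th <- pmin(pmax(res$par, lb), ub)
  out <- canonicalize(ivim_params(th[1L], th[2L], th[3L]))
  attr(out, "converged") <- res$info %in% 1:4
  out
}
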