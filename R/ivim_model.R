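#' Acquisition scheme for an IVIM experiment
#'
#' Bundles the b-value vector of a diffusion-weighted acquisition with the
#' index set of its unweighted (b = 0) measurements. b-values are in s/mm2 so
#' that products b*D with D in mm2/s are dimensionless.
#'
#' @param bvalues Numeric vector of diffusion weightings (s/mm2). Must be
#'   non-negative, contain at least one zero, and have length >= 4 (three
#'   model parameters plus normalization).
#' @return An object of class `acquisition_scheme`: a list with elements
#'   `bvalues` and `b0_indices`.
#' @examples
#' sch <- acquisition_scheme(c(0, 50, 200, 800))
#' sch$b0_indices
#' @export
acquisition_scheme <- function(bvalues) {
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) < 4L)
    stop("an IVIM scheme needs at least 4 b-values (3 parameters + normalization)")
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stop("b-values must be finite and non-negative")
  b0 <- which(bvalues == 0)
  if (length(b0) == 0L)
    stop("scheme must contain at least one b = 0 measurement")
  structure(list(bvalues = bvalues, b0_indices = b0),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("IVIM acquisition scheme: %d b-values in [%g, %g] s/mm2 (%d at b = 0)\n",
              length(x$bvalues), min(x$bvalues), max(x$bvalues),
              length(x$b0_indices)))
  invisible(x)
}

#' Length-m b-value scheme spanning 0-1000 s/mm2
#'
#' Default b-value placement used by the phantom and the examples: one
#' repeated b = 0, a perfusion-sensitive low-b segment linearly spaced over
#' 0-90 s/mm2, and the remainder linearly spaced over 100-1000 s/mm2. For the
#' default m = 54 this gives 2 x b = 0, 8 low-b and 44 high-b values. The
#' repeated b = 0 mirrors common practice and guarantees that an alternating
#' test-retest split leaves one b = 0 in each half.
#'
#' @param m Total number of b-values (>= 8).
#' @return An `acquisition_scheme`.
#' @export
make_bvalues <- function(m = 54L) {
  m <- as.integer(m)
  if (m < 8L) stop("need at least 8 b-values")
  n_low <- max(3L, as.integer(round(m * 10 / 54)))  # low-b count incl. both zeros
  b <- c(0, seq(0, 90, length.out = n_low - 1L),
         seq(100, 1000, length.out = m - n_low))
  acquisition_scheme(b)
}

#' IVIM parameter triple
#'
#' @param f Perfusion (pseudo-diffusion) volume fraction, dimensionless in
#'   \[0, 1\].
#' @param D Tissue diffusion coefficient, mm2/s, >= 0.
#' @param Dstar Pseudo-diffusion coefficient, mm2/s, >= 0. In canonical form
#'   `Dstar >= D` (see [canonicalize()]).
#' @return An object of class `ivim_params` (named list `f`, `D`, `Dstar`).
#' @export
ivim_params <- function(f, D, Dstar) {
  vals <- c(f = f, D = D, Dstar = Dstar)
  if (any(!is.finite(vals))) stop("invalid parameter: non-finite value")
  if (f < 0 || f > 1) stop("invalid parameter: f must lie in [0, 1]")
  if (D < 0 || Dstar < 0) stop("invalid parameter: rates must be >= 0")
  structure(list(f = as.numeric(f), D = as.numeric(D), Dstar = as.numeric(Dstar)),
            class = "ivim_params")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf("IVIM parameters: f = %.4f, D = %.3e mm2/s, D* = %.3e mm2/s\n",
              x$f, x$D, x$Dstar))
  invisible(x)
}

#' A voxel's normalized signal together with its scheme
#'
#' @param y Numeric vector of normalized signal values S/S0, one per b-value.
#' @param scheme An [acquisition_scheme()].
#' @return An object of class `voxel_signal`.
#' @export
voxel_signal <- function(y, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  y <- as.numeric(y)
  if (length(y) != length(scheme$bvalues))
    stop("signal length does not match number of b-values")
  if (any(!is.finite(y))) stop("signal contains non-finite values")
  if (any(y < 0)) stop("normalized signal must be >= 0 (clip before wrapping)")
  structure(list(y = y, scheme = scheme), class = "voxel_signal")
}

#' Bi-exponential IVIM forward signal
#'
#' Evaluates S/S0 = f exp(-b D*) + (1 - f) exp(-b D) at every b-value of the
#' scheme. At b = 0 the model equals 1 exactly.
#'
#' @param params An [ivim_params()] object (or coercible list).
#' @param scheme An [acquisition_scheme()].
#' @return Numeric vector of length `length(scheme$bvalues)`.
#' @examples
#' sch <- acquisition_scheme(c(0, 500, 1000))
#' @export
ivim_signal <- function(params, scheme) {
  p <- as_ivim_params(params)
  b <- scheme$bvalues
  p$f * exp(-b * p$Dstar) + (1 - p$f) * exp(-b * p$D)
}

as_ivim_params <- function(params) {
  if (inherits(params, "ivim_params")) return(params)
  if (is.list(params)) return(ivim_params(params$f, params$D, params$Dstar))
  if (is.numeric(params) && length(params) == 3L)
    return(ivim_params(params[[1]], params[[2]], params[[3]]))
  stop("cannot interpret parameters; expected ivim_params, list or length-3 numeric")
}

#' Design matrix of the separable IVIM model
#'
#' Builds the m x 2 matrix phi(s) whose columns evaluate the two exponential
#' basis functions: column 1 is exp(-b D*) (perfusion compartment), column 2
#' is exp(-b D) (diffusion compartment). Rows at b = 0 are (1, 1).
#'
#' @param s Length-2 numeric `(D, Dstar)`, both >= 0 (mm2/s).
#' @param scheme An [acquisition_scheme()].
#' @return An object of class `design_matrix`: list with `phi` (m x 2 matrix)
#'   and `s`.
#' @export
design_matrix <- function(s, scheme) {
  s <- as.numeric(s)
  if (length(s) != 2L || any(!is.finite(s)) || any(s < 0))
    stop("invalid parameter: s must be two finite non-negative rates (D, Dstar)")
  b <- scheme$bvalues
  phi <- cbind(exp(-b * s[2L]), exp(-b * s[1L]))
  colnames(phi) <- c("perfusion", "diffusion")
  structure(list(phi = phi, s = c(D = s[1L], Dstar = s[2L])),
            class = "design_matrix")
}

# Fast scalar core of the constrained linear solve: model with sum-to-one
# fractions, y - phi2 = (phi1 - phi2) f, solved by 1-D least squares and
# clipped to [0, 1]. Returns c(f, degenerate). Tolerance 1e-12 relative on
# the basis-difference norm plays the role of a pseudo-inverse rank cut.
.project_f <- function(e_star, e_d, y) {
  d <- e_star - e_d
  den <- sum(d * d)
  if (den <= 1e-24 * max(sum(e_star^2), 1)) {
    return(c(0, 1))   # D == Dstar: f unidentifiable on the symmetry axis
  }
  f <- sum((y - e_d) * d) / den
  c(min(1, max(0, f)), 0)
}

#' Perfusion fraction implied by the linear (VarPro) subproblem
#'
#' Given a design matrix phi(s) and a voxel signal, solves the linear
#' subproblem for the compartment fractions under the sum-to-one constraint
#' and returns the perfusion fraction, clipped to \[0, 1\]. Writing the model
#' as y - phi2 = (phi1 - phi2) f reduces the constrained Moore-Penrose
#' solution to a scalar least-squares problem. When the two basis columns
#' coincide (D == D*), f is unidentifiable and 0 is returned with a
#' degeneracy flag.
#'
#' @param phi A [design_matrix()].
#' @param y A [voxel_signal()] or plain numeric vector.
#' @return List with `f` (scalar in \[0, 1\]) and `degenerate` (logical).
#' @export
project_linear <- function(phi, y) {
  stopifnot(inherits(phi, "design_matrix"))
  yv <- if (inherits(y, "voxel_signal")) y$y else as.numeric(y)
  if (length(yv) != nrow(phi$phi)) stop("phi and y are not conformable")
  r <- .project_f(phi$phi[, 1L], phi$phi[, 2L], yv)
  list(f = r[1L], degenerate = r[2L] == 1)
}

# Fast core of the reduced (VarPro) objective; b and y are plain vectors.
.reduced_resid <- function(D, Dstar, y, b) {
  e_star <- exp(-b * Dstar)
  e_d <- exp(-b * D)
  f <- .project_f(e_star, e_d, y)[1L]
  r <- y - f * e_star - (1 - f) * e_d
  sum(r * r)
}

#' Reduced (variable-projection) residual
#'
#' The VarPro objective over the nonlinear parameters only: the squared norm
#' of y minus its projection onto the constrained span of phi(s), i.e. the
#' full residual minimized analytically over f. Only s = (D, D*) remains to
#' be searched.
#'
#' @param s Length-2 numeric `(D, Dstar)`.
#' @param y A [voxel_signal()].
#' @return Scalar squared residual, >= 0. Carries attribute `degenerate`
#'   (logical) when the design matrix was rank-deficient (D == D*).
#' @export
reduced_residual <- function(s, y) {
  stopifnot(inherits(y, "voxel_signal"))
  s <- as.numeric(s)
  if (length(s) != 2L || any(!is.finite(s)) || any(s < 0))
    stop("invalid parameter: s must be two finite non-negative rates")
  b <- y$scheme$bvalues
  e_star <- exp(-b * s[2L])
  e_d <- exp(-b * s[1L])
  pr <- .project_f(e_star, e_d, y$y)
  r <- y$y - pr[1L] * e_star - (1 - pr[1L]) * e_d
  structure(sum(r * r), degenerate = pr[2L] == 1)
}

#' Full IVIM residual
#'
#' Squared l2 norm of the misfit between the voxel signal and the forward
#' model at the given parameter triple.
#'
#' @param params An [ivim_params()] (or coercible).
#' @param y A [voxel_signal()].
#' @return Scalar >= 0.
#' @export
full_residual <- function(params, y) {
  stopifnot(inherits(y, "voxel_signal"))
  r <- y$y - ivim_signal(params, y$scheme)
  sum(r * r)
}

#' Resolve the compartment-swap symmetry
#'
#' The bi-exponential model is invariant under exchanging compartments,
#' (f, D, D*) -> (1 - f, D*, D). `canonicalize` maps any parameter triple to
#' the representative with D* >= D; the predicted signal is unchanged.
#'
#' @param params An [ivim_params()] (or coercible).
#' @return An `ivim_params` with `Dstar >= D`.
#' @examples
#' canonicalize(ivim_params(0.7, 0.04, 0.001))  # -> f = 0.3, D = 0.001, D* = 0.04
#' @export
canonicalize <- function(params) {
  p <- as_ivim_params(params)
  if (p$Dstar < p$D) ivim_params(1 - p$f, p$Dstar, p$D) else p
}
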