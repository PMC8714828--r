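# Simplicial-homology global optimizer.
#
# Pipeline: low-discrepancy sampling of a compact box -> Delaunay complex
# over the samples -> minimizer pool from vertex stars (a vertex whose value
# is <= all neighbours' values maps to a locally convex star domain that
# contains a stationary point) -> bound-constrained derivative-free local
# refinement inside each star's bounding box -> sample doubling until the
# pool cardinality is invariant.

# ---- sampling ---------------------------------------------------------------

# Van der Corput radical inverse in the given base, points i = 1..n.
.vdc <- function(idx, base) {
  out <- numeric(length(idx))
  f <- 1 / base
  i <- idx
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

.halton_bases <- c(2, 3, 5)

# n x d Halton pattern in the open unit box, Cranley-Patterson shifted by a
# seed-derived offset per dimension (deterministic, RNG state restored).
.halton <- function(n, d, seed) {
  shift <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% 2147483647))
    stats::runif(d)
  })
  pts <- vapply(seq_len(d),
                function(j) (.vdc(seq_len(n), .halton_bases[j]) + shift[j]) %% 1,
                numeric(n))
  matrix(pts, nrow = n, ncol = d)
}

#' Sample a compact box with a low-discrepancy point set
#'
#' Returns the 2^d box corners followed by a seeded, shifted Halton sequence
#' filling the interior, `n_points` points in total. For a fixed seed the
#' sequence is nested: the first N points of a larger sample equal the
#' N-point sample, which is what lets the optimizer double its sampling
#' without discarding work. Corners guarantee that the convex hull of the
#' samples is the whole box.
#'
#' @param bounds List of `(lo, hi)` pairs (or a 2-column matrix), one per
#'   dimension.
#' @param n_points Total number of points (>= 2^d + 1).
#' @param seed Integer seed for the Halton shift; identical inputs give
#'   identical point sets.
#' @return `n_points` x d numeric matrix of points inside the box.
#' @export
sample_domain <- function(bounds, n_points, seed = 0L) {
  bm <- .as_bounds(bounds)
  d <- nrow(bm)
  if (n_points < 2^d + 1) stop("n_points too small for corners + interior")
  corners <- as.matrix(expand.grid(lapply(seq_len(d), function(j) bm[j, ])))
  dimnames(corners) <- NULL
  h <- .halton(n_points - nrow(corners), d, seed)
  pts <- rbind(corners, sweep(sweep(h, 2, bm[, 2] - bm[, 1], "*"), 2, bm[, 1], "+"))
  pts
}

.as_bounds <- function(bounds) {
  bm <- if (is.list(bounds)) do.call(rbind, lapply(bounds, as.numeric)) else as.matrix(bounds)
  if (ncol(bm) != 2L) stop("bounds must be (lo, hi) pairs")
  if (any(!is.finite(bm)) || any(bm[, 1] >= bm[, 2]))
    stop("configuration error: each bound must satisfy lo < hi and be finite")
  bm
}

# ---- Delaunay triangulation (Bowyer-Watson, d = 1..3) -----------------------

# Circumcenter (absolute) and squared radius of the simplex with vertex rows
# V[ix, ]; NULL when the vertices are affinely dependent.
.circum <- function(V, ix) {
  d <- ncol(V)
  a1 <- V[ix[1L], ]
  B <- sweep(V[ix[-1L], , drop = FALSE], 2, a1)
  rhs <- 0.5 * rowSums(B * B)
  ctr <- tryCatch(drop(solve(B, rhs)), error = function(e) NULL)
  if (is.null(ctr) || any(!is.finite(ctr))) return(NULL)
  list(c = ctr + a1, r2 = sum(ctr * ctr))
}

# Kuhn decomposition of the unit d-cube into d! simplices, as rows of corner
# patterns (each pattern a binary vector of length d).
.kuhn_simplices <- function(d) {
  perms <- if (d == 1L) list(1L) else if (d == 2L) list(1:2, 2:1) else
    list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  lapply(perms, function(p) {
    pat <- matrix(0L, d + 1L, d)
    for (k in seq_len(d)) pat[(k + 1L):(d + 1L), p[k]] <- 1L
    pat
  })
}

# Bowyer-Watson Delaunay triangulation of points P (rows), d = ncol in 2..3.
# When `corner_idx` maps every binary corner pattern of the bounding box to a
# point index, the triangulation is bootstrapped from an exact decomposition
# of the box (covers the hull exactly, no super-simplex cleanup needed).
# Returns a matrix of simplex vertex indices, or NULL on degeneracy.
.bowyer_watson <- function(P, corner_idx = NULL) {
  d <- ncol(P)
  n <- nrow(P)
  if (!is.null(corner_idx)) {
    V <- P
    nv <- n
    simp <- do.call(rbind, lapply(.kuhn_simplices(d), function(pat) {
      vapply(seq_len(d + 1L), function(r) corner_idx[sum(pat[r, ] * 2^(seq_len(d) - 1L)) + 1L],
             integer(1))
    }))
    insert <- setdiff(seq_len(n), corner_idx)
    offset <- 0L
  } else {
    M <- 30
    super <- matrix(rep(-M, (d + 1) * d), d + 1, d, byrow = TRUE)
    for (j in seq_len(d)) super[j + 1L, j] <- super[j + 1L, j] + 4 * M
    V <- rbind(super, P)
    nv <- nrow(V)
    simp <- matrix(seq_len(d + 1L), 1L, d + 1L)
    insert <- (d + 2L):nv
    offset <- d + 1L
  }
  cc <- matrix(0, nrow(simp), d)
  r2 <- numeric(nrow(simp))
  for (i in seq_len(nrow(simp))) {
    cr <- .circum(V, simp[i, ])
    if (is.null(cr)) return(NULL)
    cc[i, ] <- cr$c
    r2[i] <- cr$r2
  }
  keybase <- as.numeric(nv + 1L)
  for (ip in insert) {
    p <- V[ip, ]
    dif <- sweep(cc, 2, p)
    inside <- rowSums(dif * dif) < r2 * (1 - 1e-9)
    bad <- which(inside)
    if (!length(bad)) bad <- which.min(rowSums(dif * dif) / r2)
    # facets of the cavity: those appearing exactly once among bad simplices
    nb <- length(bad)
    fac <- matrix(0, nb * (d + 1L), d)
    k <- 0L
    for (bi in bad) {
      row <- simp[bi, ]
      for (j in seq_len(d + 1L)) {
        k <- k + 1L
        fac[k, ] <- sort.int(row[-j])
      }
    }
    key <- as.vector(fac %*% keybase^(seq_len(d) - 1))
    m1 <- match(key, key)
    cnt <- tabulate(m1)
    bound <- fac[cnt[m1] == 1L, , drop = FALSE]
    nnew <- nrow(bound)
    if (!nnew) return(NULL)
    newsimp <- cbind(bound, ip)
    newcc <- matrix(0, nnew, d)
    newr2 <- numeric(nnew)
    ok <- rep(TRUE, nnew)
    for (j in seq_len(nnew)) {
      cr <- .circum(V, newsimp[j, ])
      if (is.null(cr)) { ok[j] <- FALSE; next }
      newcc[j, ] <- cr$c
      newr2[j] <- cr$r2
    }
    keep <- setdiff(seq_len(nrow(simp)), bad)
    simp <- rbind(simp[keep, , drop = FALSE], newsimp[ok, , drop = FALSE])
    cc <- rbind(cc[keep, , drop = FALSE], newcc[ok, , drop = FALSE])
    r2 <- c(r2[keep], newr2[ok])
  }
  if (offset > 0L) {
    keep <- rowSums(simp <= offset) == 0L
    simp <- simp[keep, , drop = FALSE] - offset
  }
  if (!nrow(simp)) return(NULL)
  simp
}

# Triangulate normalized points; d = 1 is a sorted chain. When the point set
# contains all corners of its bounding box the triangulation is bootstrapped
# from them (exact hull coverage). Jitter-and-retry on degeneracy
# (deterministic perturbation), then error.
.triangulate <- function(Pu) {
  d <- ncol(Pu)
  if (d == 1L) {
    ord <- order(Pu[, 1L])
    return(cbind(ord[-length(ord)], ord[-1L]))
  }
  corner_idx <- .find_corners(Pu)
  simp <- .bowyer_watson(Pu, corner_idx)
  attempt <- 0L
  while (is.null(simp) && attempt < 3L) {
    attempt <- attempt + 1L
    jit <- .halton(nrow(Pu), d, seed = 1000L + attempt)
    Pj <- Pu + (jit - 0.5) * 1e-7 * attempt
    if (!is.null(corner_idx)) Pj[corner_idx, ] <- Pu[corner_idx, ]
    simp <- .bowyer_watson(Pj, corner_idx)
  }
  if (is.null(simp)) stop("degenerate vertex set: triangulation failed after jitter retries")
  simp
}

# Indices of the 2^d bounding-box corners inside a normalized point set, in
# binary-pattern order; NULL unless every corner is present exactly once.
.find_corners <- function(Pu, tol = 1e-9) {
  d <- ncol(Pu)
  pat <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
  idx <- integer(nrow(pat))
  for (i in seq_len(nrow(pat))) {
    hit <- which(rowSums(abs(sweep(Pu, 2, pat[i, ]))) < tol)
    if (length(hit) != 1L) return(NULL)
    idx[i] <- hit
  }
  if (anyDuplicated(idx)) return(NULL)
  idx
}

# Package-local cache of triangulations of repeated point patterns.
.tri_cache <- new.env(parent = emptyenv())

# ---- complex ----------------------------------------------------------------

#' Build a triangulated complex over sampled vertices
#'
#' Normalizes the vertex set to the unit box (triangulation is computed in
#' normalized coordinates, which makes it invariant to per-axis rescaling of
#' the domain), Delaunay-triangulates it with Bowyer-Watson insertion, and
#' evaluates the objective exactly once per vertex.
#'
#' @param vertices N x d matrix of points (d in 1..3); at least d + 1
#'   affinely independent rows.
#' @param objective Function mapping a length-d numeric to a scalar.
#' @param cache_key Optional string: when the same point pattern (up to the
#'   normalization) is triangulated repeatedly — e.g. one complex per voxel
#'   of a volume — the triangulation is reused from a package-local cache.
#' @return An object of class `triangulated_complex`: list with `vertices`,
#'   `values`, `simplices` (matrix of vertex index rows), `adjacency` (list
#'   of neighbour index vectors).
#' @export
build_complex <- function(vertices, objective, cache_key = NULL) {
  V <- as.matrix(vertices)
  d <- ncol(V)
  if (d > 3L) stop("only dimensions 1..3 are supported")
  if (nrow(V) < d + 1L) stop("need at least d + 1 vertices")
  lo <- apply(V, 2, min)
  hi <- apply(V, 2, max)
  span <- pmax(hi - lo, 1e-300)
  Pu <- sweep(sweep(V, 2, lo), 2, span, "/")
  geo <- NULL
  if (!is.null(cache_key)) geo <- .tri_cache[[cache_key]]
  if (is.null(geo)) {
    simp <- .triangulate(Pu)
    geo <- list(simp = simp, adj = .adjacency(simp, nrow(V)))
    if (!is.null(cache_key)) .tri_cache[[cache_key]] <- geo
  }
  vals <- vapply(seq_len(nrow(V)), function(i) as.numeric(objective(V[i, ])), numeric(1))
  structure(list(vertices = V, values = vals, simplices = geo$simp,
                 adjacency = geo$adj),
            class = "triangulated_complex")
}

.adjacency <- function(simp, n) {
  k <- ncol(simp)
  from <- integer(0); to <- integer(0)
  for (a in seq_len(k)) for (b in seq_len(k)) if (a != b) {
    from <- c(from, simp[, a]); to <- c(to, simp[, b])
  }
  adj <- vector("list", n)
  sp <- split(to, from)
  adj[as.integer(names(sp))] <- lapply(sp, function(v) sort.int(unique.default(v)))
  for (i in seq_len(n)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  adj
}

#' @export
print.triangulated_complex <- function(x, ...) {
  cat(sprintf("triangulated complex: %d vertices, %d simplices in %d-D\n",
              nrow(x$vertices), nrow(x$simplices), ncol(x$vertices)))
  invisible(x)
}

#' Star of a vertex
#'
#' The set of simplices of the complex that contain the given vertex. Its
#' boundary delimits the sub-domain within which a pool vertex's stationary
#' point is sought.
#'
#' @param complex A [build_complex()] result.
#' @param v_i Vertex index.
#' @return Integer vector of simplex row indices into `complex$simplices`.
#' @export
star <- function(complex, v_i) {
  stopifnot(inherits(complex, "triangulated_complex"))
  v_i <- as.integer(v_i)
  if (v_i < 1L || v_i > nrow(complex$vertices)) stop("invalid vertex index")
  which(rowSums(complex$simplices == v_i) > 0L)
}

# ---- minimizer pool ---------------------------------------------------------

#' Extract the minimizer pool of a complex
#'
#' A vertex enters the pool when its objective value is less than or equal to
#' the value at every adjacent vertex. On flat plateaus, equal-valued
#' adjacent pool candidates form connected components and only the
#' lowest-index representative of each component is kept (this prevents the
#' pool from blowing up on valley-shaped surfaces with non-unique minima).
#' Each pool vertex carries the axis-aligned bounding box of its star's
#' vertices, used as explicit bounds for local refinement.
#'
#' @param complex A [build_complex()] result.
#' @return An object of class `minimizer_pool`: list with `minimizers`
#'   (vertex indices), `star_boxes` (list of d x 2 matrices), and `refined`
#'   (empty; filled by [shgo_minimize()]).
#' @export
minimizer_pool <- function(complex) {
  stopifnot(inherits(complex, "triangulated_complex"))
  vals <- complex$values
  n <- length(vals)
  cand <- which(vapply(seq_len(n), function(i) {
    nb <- complex$adjacency[[i]]
    length(nb) > 0L && all(vals[i] <= vals[nb])
  }, logical(1)))
  # plateau dedup: connected components of equal-valued adjacent candidates
  if (length(cand) > 1L) {
    comp <- seq_along(cand)
    idx <- stats::setNames(seq_along(cand), cand)
    find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
    for (a in seq_along(cand)) {
      nb <- complex$adjacency[[cand[a]]]
      nb <- nb[nb %in% cand & vals[nb] == vals[cand[a]]]
      for (b in nb) {
        rb <- find(idx[[as.character(b)]]); ra <- find(a)
        if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_along(cand), find, integer(1))
    cand <- vapply(split(cand, roots), min, numeric(1))
    cand <- sort.int(as.integer(cand))
  }
  boxes <- lapply(cand, function(v) {
    stv <- unique.default(as.vector(complex$simplices[star(complex, v), , drop = FALSE]))
    pts <- complex$vertices[stv, , drop = FALSE]
    cbind(apply(pts, 2, min), apply(pts, 2, max))
  })
  structure(list(minimizers = as.integer(cand), star_boxes = boxes,
                 refined = list()),
            class = "minimizer_pool")
}

# ---- local refinement -------------------------------------------------------

#' Bound-constrained derivative-free local refinement
#'
#' Nelder-Mead style simplex descent in which every candidate point is
#' clipped into the box, so all evaluations stay feasible. Terminates when
#' the value spread of the simplex falls below `tol` or after `max_iter`
#' iterations (returning the best point so far with `converged = FALSE`).
#' The returned value never exceeds the objective at the start point.
#'
#' @param objective Function of a length-d numeric.
#' @param start Starting point, inside the box.
#' @param box_bounds d x 2 matrix (or list of pairs) of box bounds.
#' @param tol Absolute tolerance on the simplex value spread (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @param xtol Relative (to the box width) tolerance on the simplex
#'   diameter; both criteria must hold to declare convergence. The default
#'   targets point accuracy; the optimizer's pool-stage refinements relax it
#'   because only the subsequent polish needs precise arguments.
#' @return List `point`, `value`, `converged`, `n_evals`.
#' @export
local_refine <- function(objective, start, box_bounds, tol = 1e-8,
                         max_iter = 500L, xtol = 1e-6) {
  bm <- .as_bounds(box_bounds)
  d <- nrow(bm)
  lo <- bm[, 1]; hi <- bm[, 2]
  start <- pmin(pmax(as.numeric(start), lo), hi)
  clip <- function(x) {
    w <- x < lo
    if (any(w)) x[w] <- lo[w]
    w <- x > hi
    if (any(w)) x[w] <- hi[w]
    x
  }
  nev <- 0L
  fx <- function(x) { nev <<- nev + 1L; as.numeric(objective(x)) }
  # initial simplex: start plus steps of 5% of box width per axis
  S <- matrix(rep(start, d + 1L), d + 1L, d, byrow = TRUE)
  for (j in seq_len(d)) {
    step <- 0.05 * (bm[j, 2] - bm[j, 1])
    xj <- start[j] + step
    if (xj > bm[j, 2]) xj <- start[j] - step
    S[j + 1L, j] <- xj
  }
  fv <- vapply(seq_len(d + 1L), function(j) fx(S[j, ]), numeric(1))
  width <- pmax(hi - lo, 1e-300)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    iw <- which.max(fv)           # worst
    ib <- which.min(fv)           # best
    if (fv[iw] - fv[ib] < tol) {
      diam <- 0
      for (j in seq_len(d)) {
        cj <- S[, j]
        r <- (max(cj) - min(cj)) / width[j]
        if (r > diam) diam <- r
      }
      if (diam < xtol) break
    }
    fv2 <- fv; fv2[iw] <- -Inf
    isw <- which.max(fv2)         # second worst
    centroid <- (colSums(S) - S[iw, ]) / d
    xr <- clip(centroid + (centroid - S[iw, ]))
    fr <- fx(xr)
    if (fr < fv[ib]) {
      xe <- clip(centroid + 2 * (centroid - S[iw, ]))
      fe <- fx(xe)
      if (fe < fr) { S[iw, ] <- xe; fv[iw] <- fe }
      else { S[iw, ] <- xr; fv[iw] <- fr }
    } else if (fr < fv[isw]) {
      S[iw, ] <- xr; fv[iw] <- fr
    } else {
      xc <- clip(centroid + 0.5 * (S[iw, ] - centroid))
      fc <- fx(xc)
      if (fc < fv[iw]) { S[iw, ] <- xc; fv[iw] <- fc }
      else {
        for (j in seq_len(d + 1L)) if (j != ib) {
          S[j, ] <- clip(S[ib, ] + 0.5 * (S[j, ] - S[ib, ]))
          fv[j] <- fx(S[j, ])
        }
      }
    }
  }
  best <- which.min(fv)
  list(point = as.numeric(S[best, ]), value = fv[best],
       converged = it < max_iter, n_evals = nev)
}

# ---- full SHGO pipeline -----------------------------------------------------

# Refine every pool vertex. Stage 1 honours the star-domain bounds (Theorem-1
# sub-domain). When the stage-1 point is pressed against a star-box face that
# is not a face of the global bounds — i.e. the descent wants to leave the
# star because the star only grazes a basin — refinement continues from there
# under the global bounds, so that pool vertices sharing one basin collapse
# onto the same minimum and deduplicate.
.refine_pool <- function(objective, cx, pool, bm) {
  d <- nrow(bm)
  n <- length(pool$minimizers)
  rp <- matrix(0, n, d)
  rv <- numeric(n)
  width <- bm[, 2] - bm[, 1]
  for (i in seq_len(n)) {
    v <- pool$minimizers[i]
    box <- pool$star_boxes[[i]]
    box[, 1] <- pmax(box[, 1], bm[, 1]); box[, 2] <- pmin(box[, 2], bm[, 2])
    ref <- local_refine(objective, cx$vertices[v, ], box, xtol = 1e-3)
    tol <- 1e-6 * width
    pinned <- (abs(ref$point - box[, 1]) < tol & box[, 1] > bm[, 1] + tol) |
              (abs(ref$point - box[, 2]) < tol & box[, 2] < bm[, 2] - tol)
    if (any(pinned)) {
      ref2 <- local_refine(objective, ref$point, bm, xtol = 1e-3)
      if (ref2$value < ref$value) ref <- ref2
    }
    rp[i, ] <- ref$point
    rv[i] <- min(ref$value, cx$values[v])
  }
  list(points = rp, values = rv)
}

# Merge refined minima within a relative per-dimension radius (scaled by the
# bounds width); keeps the lowest-value representative.
.dedupe_minima <- function(pts, vals, bm, radius = 1e-3) {
  if (!length(vals)) return(list(points = pts, values = vals))
  width <- bm[, 2] - bm[, 1]
  ord <- order(vals)
  keep <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (k in keep) {
      if (all(abs(pts[i, ] - pts[k, ]) <= radius * width)) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  list(points = pts[keep, , drop = FALSE], values = vals[keep])
}

#' Simplicial-homology global minimization
#'
#' Full pipeline: sample the box with a low-discrepancy set, build the
#' Delaunay complex, extract the minimizer pool from vertex stars, refine
#' each pool vertex inside its star's bounding box, and deduplicate the
#' refined minima. The sampling size is doubled and the pipeline repeated
#' until the pool cardinality is unchanged across one doubling and the best
#' value has stopped improving (invariance stopping rule), or `max_iters`
#' rounds are exhausted.
#'
#' @param objective Function of a length-d numeric returning a scalar.
#' @param bounds List of `(lo, hi)` pairs, one per dimension.
#' @param n_points Initial sampling size (default 64).
#' @param max_iters Maximum sampling-doubling rounds (default 4).
#' @param seed Integer; the only source of randomness (Halton shift).
#' @param cache_tag Optional string mixed into the triangulation cache key;
#'   callers fitting many problems over the same box shape share work.
#' @return List with `x` (best point), `value`, `minima` (list with
#'   `points` matrix and `values`, sorted by value), `pool_sizes` (|M| per
#'   round), `n_iterations`.
#' @export
shgo_minimize <- function(objective, bounds, n_points = 64L, max_iters = 4L,
                          seed = 0L, cache_tag = "shgo") {
  bm <- .as_bounds(bounds)
  d <- nrow(bm)
  pool_sizes <- integer(0)
  best_prev <- Inf
  res <- NULL
  for (k in seq_len(max_iters)) {
    N <- n_points * 2^(k - 1L)
    pts <- sample_domain(bm, N, seed)
    key <- paste(cache_tag, d, N, seed, sep = "|")
    cx <- build_complex(pts, objective, cache_key = key)
    if (mean(!is.finite(cx$values)) > 0.5)
      stop("objective non-finite at most sample points: check bounds configuration")
    pool <- minimizer_pool(cx)
    ref <- .refine_pool(objective, cx, pool, bm)
    mins <- .dedupe_minima(ref$points, ref$values, bm)
    pool_sizes <- c(pool_sizes, length(mins$values))
    ordm <- order(mins$values)
    mins <- list(points = mins$points[ordm, , drop = FALSE], values = mins$values[ordm])
    res <- list(x = as.numeric(mins$points[1L, ]), value = mins$values[1L],
                minima = mins, pool_sizes = pool_sizes, n_iterations = k)
    stable <- k > 1L && pool_sizes[k] == pool_sizes[k - 1L] &&
      (best_prev - res$value) < 1e-10
    best_prev <- res$value
    if (stable) break
  }
  # tight final polish of the incumbent (flat valleys need a much smaller
  # value tolerance than the pool-stage refinements)
  pol <- local_refine(objective, res$x, bm, tol = 1e-14, max_iter = 400L,
                      xtol = 1e-7)
  if (pol$value <= res$value) {
    res$x <- pol$point
    res$value <- pol$value
    res$minima$points[1L, ] <- pol$point
    res$minima$values[1L] <- pol$value
  }
  res
}

#' Pool-cardinality invariance diagnostic
#'
#' Runs one sample-complex-pool-refine-dedupe pass at each sampling size and
#' reports the resulting pool cardinalities |M|. On an adequately sampled
#' objective the sequence plateaus at the number of distinct local minima:
#' increasing N further does not increase |M|.
#'
#' @param objective,bounds,seed As in [shgo_minimize()].
#' @param n_sequence Increasing vector of sampling sizes.
#' @return Integer vector of |M|, one per sampling size.
#' @export
pool_invariance_check <- function(objective, bounds, n_sequence, seed = 0L) {
  bm <- .as_bounds(bounds)
  d <- nrow(bm)
  vapply(n_sequence, function(N) {
    pts <- sample_domain(bm, N, seed)
    cx <- build_complex(pts, objective)
    pool <- minimizer_pool(cx)
    ref <- .refine_pool(objective, cx, pool, bm)
    length(.dedupe_minima(ref$points, ref$values, bm)$values)
  }, integer(1))
}
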