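# Analytic test functions with known minima.
double_well <- function(x) (x[1]^2 - 1)^2 + x[2]^2
bowl2 <- function(x) (x[1] - 0.3)^2 + (x[2] - 0.7)^2

test_that("domain sampling is deterministic, contained, and low-discrepancy", {
  b <- list(c(0, 1), c(0, 1))
  p1 <- sample_domain(b, 16, seed = 0)
  p2 <- sample_domain(b, 16, seed = 0)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_domain(b, 16, seed = 1)))
  p <- sample_domain(list(c(-2, 3), c(10, 20)), 100, seed = 4)
  expect_true(all(p[, 1] >= -2 & p[, 1] <= 3))
  expect_true(all(p[, 2] >= 10 & p[, 2] <= 20))
  # nesting: the first N points of a larger sample equal the N-point sample
  expect_identical(sample_domain(b, 64, seed = 2),
                   sample_domain(b, 128, seed = 2)[1:64, ])

  # star-discrepancy estimate over anchored boxes, same estimator for both
  disc <- function(pts) {
    a <- as.matrix(expand.grid(seq(0.1, 1, by = 0.1), seq(0.1, 1, by = 0.1)))
    max(vapply(seq_len(nrow(a)), function(i) {
      abs(mean(pts[, 1] < a[i, 1] & pts[, 2] < a[i, 2]) - a[i, 1] * a[i, 2])
    }, numeric(1)))
  }
  d_lowdisc <- disc(sample_domain(b, 128, seed = 3))
  d_unif <- withr::with_seed(10, {
    mean(replicate(20, disc(matrix(runif(256), 128, 2))))
  })
  expect_lt(d_lowdisc, d_unif)
})

test_that("the complex triangulates the hull and evaluates each vertex once", {
  sq <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  n_evals <- 0L
  counted <- function(x) { n_evals <<- n_evals + 1L; sum(x) }
  cx <- build_complex(sq, counted)
  expect_equal(nrow(cx$simplices), 2L)        # two triangles on one diagonal
  expect_equal(n_evals, 4L)                   # caching contract
  shared <- intersect(cx$simplices[1, ], cx$simplices[2, ])
  expect_length(shared, 2L)                   # they share one edge

  # simplex volumes sum to the hull (= box) volume, 2-D and 3-D
  pts2 <- sample_domain(list(c(0, 1), c(0, 2)), 150, seed = 5)
  cx2 <- build_complex(pts2, function(x) sum(x^2))
  vol2 <- sum(apply(cx2$simplices, 1, function(ix)
    abs(det(cbind(pts2[ix[2], ] - pts2[ix[1], ],
                  pts2[ix[3], ] - pts2[ix[1], ]))) / 2))
  expect_equal(vol2, 2, tolerance = 1e-9)
  pts3 <- sample_domain(list(c(0, 1), c(0, 1), c(0, 3)), 80, seed = 6)
  cx3 <- build_complex(pts3, function(x) sum(x^2))
  vol3 <- sum(apply(cx3$simplices, 1, function(ix)
    abs(det(rbind(pts3[ix[2], ] - pts3[ix[1], ],
                  pts3[ix[3], ] - pts3[ix[1], ],
                  pts3[ix[4], ] - pts3[ix[1], ]))) / 6))
  expect_equal(vol3, 3, tolerance = 1e-9)
})

test_that("vertex stars are exactly the incident simplices and cover the complex", {
  pts <- sample_domain(list(c(0, 1), c(0, 1)), 60, seed = 7)
  cx <- build_complex(pts, function(x) sum(x))
  for (v in c(1L, 10L, 37L)) {
    st <- star(cx, v)
    expect_true(all(apply(cx$simplices[st, , drop = FALSE], 1, function(s) v %in% s)))
    others <- setdiff(seq_len(nrow(cx$simplices)), st)
    expect_false(any(apply(cx$simplices[others, , drop = FALSE], 1,
                           function(s) v %in% s)))
  }
  covered <- sort(unique(unlist(lapply(seq_len(nrow(pts)), function(v) star(cx, v)))))
  expect_identical(covered, seq_len(nrow(cx$simplices)))
  expect_error(star(cx, 10000L), "invalid vertex")
})

test_that("minimizer pool finds local minima of classic surfaces", {
  # 1-D chain: x^2 on 5 points has the single pool vertex at 0
  v1 <- matrix(c(-1, -0.5, 0, 0.5, 1), ncol = 1)
  cx1 <- build_complex(v1, function(x) x[1]^2)
  pool1 <- minimizer_pool(cx1)
  expect_identical(pool1$minimizers, 3L)

  # 16 x 16 grid over [-2, 2]^2: the double well has exactly 2 pool vertices
  g <- seq(-2, 2, length.out = 16)
  grid <- as.matrix(expand.grid(g, g))
  cxg <- build_complex(grid, double_well)
  poolg <- minimizer_pool(cxg)
  expect_equal(length(poolg$minimizers), 2L)
  locs <- grid[poolg$minimizers, , drop = FALSE]
  expect_true(any(locs[, 1] < 0) && any(locs[, 1] > 0))
  expect_true(all(abs(abs(locs[, 1]) - 1) < 0.3 & abs(locs[, 2]) < 0.3))

  # constant surface: plateau deduplicated to connected-component reps
  cxc <- build_complex(sample_domain(list(c(0, 1), c(0, 1)), 40, seed = 8),
                       function(x) 1)
  poolc <- minimizer_pool(cxc)
  expect_identical(poolc$minimizers, 1L)   # one fully connected component
})

test_that("star-box refinement descends within bounds", {
  r <- local_refine(bowl2, c(0, 0), list(c(0, 1), c(0, 1)))
  expect_equal(r$point, c(0.3, 0.7), tolerance = 1e-6)
  expect_true(r$converged)
  # starting at the optimum does not increase the value
  r2 <- local_refine(bowl2, c(0.3, 0.7), list(c(0, 1), c(0, 1)))
  expect_lte(r2$value, bowl2(c(0.3, 0.7)))
  # refinement from each double-well pool vertex hits the analytic minima,
  # and the stage-1 refined point stays inside the star box
  g <- seq(-2, 2, length.out = 16)
  grid <- as.matrix(expand.grid(g, g))
  cx <- build_complex(grid, double_well)
  pool <- minimizer_pool(cx)
  mins <- t(vapply(seq_along(pool$minimizers), function(i) {
    box <- pool$star_boxes[[i]]
    ref <- local_refine(double_well, grid[pool$minimizers[i], ], box)
    expect_true(all(ref$point >= box[, 1] - 1e-12 & ref$point <= box[, 2] + 1e-12))
    ref$point
  }, numeric(2)))
  expect_equal(sort(mins[, 1]), c(-1, 1), tolerance = 1e-5)
  expect_equal(mins[, 2], c(0, 0), tolerance = 1e-5)
})

test_that("shgo finds all minima of the double well deterministically", {
  b <- list(c(-2, 2), c(-2, 2))
  res <- shgo_minimize(double_well, b, n_points = 64, seed = 1)
  expect_equal(res$value, 0, tolerance = 1e-8)
  expect_equal(length(res$minima$values), 2L)
  xs <- sort(res$minima$points[, 1])
  expect_equal(xs, c(-1, 1), tolerance = 1e-3)
  expect_identical(res, shgo_minimize(double_well, b, n_points = 64, seed = 1))
  # objective non-finite almost everywhere is a configuration error
  expect_error(shgo_minimize(function(x) NaN, b, n_points = 16, seed = 1),
               "bounds")
})

test_that("shgo recovers noiseless IVIM rates from the reduced functional", {
  y <- noiseless_voxel(0.349, 0.001, 0.04)
  obj <- function(s) as.numeric(reduced_residual(s, y))
  res <- shgo_minimize(obj, list(c(1e-5, 0.02), c(1e-5, 0.2)),
                       n_points = 64, seed = 0)
  expect_lt(res$value, 1e-10)
  expect_equal(res$x, c(0.001, 0.04), tolerance = 1e-4)
})

test_that("shgo agrees with a dense grid search on seeded 2-D objectives", {
  b <- list(c(0, 1), c(0, 1))
  gx <- seq(0, 1, length.out = 100)
  for (s in 1:3) {
    ctr <- withr::with_seed(100 + s, runif(4))
    fn <- function(x) {
      (x[1] - ctr[1])^2 + (x[2] - ctr[2])^2 +
        0.3 * sin(7 * x[1] + 3 * ctr[3]) * sin(5 * x[2] + 2 * ctr[4])
    }
    res <- shgo_minimize(fn, b, n_points = 64, seed = s)
    grid_vals <- outer(gx, gx, Vectorize(function(a, c2) fn(c(a, c2))))
    gmin <- which(grid_vals == min(grid_vals), arr.ind = TRUE)[1, ]
    cell <- 1 / 99
    expect_lt(max(abs(res$x - c(gx[gmin[1]], gx[gmin[2]]))), 2 * cell)
    expect_lte(res$value, min(grid_vals) + 1e-9)
  }
})

test_that("pool cardinality plateaus as sampling grows (invariance)", {
  b2 <- list(c(-2, 2), c(-2, 2))
  sizes <- c(16, 64, 256, 1024)
  m_dw <- pool_invariance_check(double_well, b2, sizes, seed = 0)
  expect_identical(tail(m_dw, 2), c(2L, 2L))
  m_bowl <- pool_invariance_check(bowl2, list(c(0, 1), c(0, 1)), sizes, seed = 0)
  expect_true(all(m_bowl == 1L))
  # once the known minima are found, growing N does not grow |M|
  k <- which.max(m_dw)
  expect_true(all(diff(m_dw[k:length(m_dw)]) <= 0))
})
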