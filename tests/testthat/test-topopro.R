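test_that("the low-perfusion penalty follows its closed form", {
  cfg <- topopro_config(penalty_weight = 1)
  expect_equal(penalty(ivim_params(0.1, 0.001, 0.05), cfg), 0.0025)
  expect_identical(penalty(ivim_params(0.3, 0.001, 0.05), cfg), 0)
  expect_identical(penalty(ivim_params(0.2, 0.001, 0), cfg), 0)  # boundary + zero
  cfg2 <- topopro_config(penalty_weight = 2.5)
  expect_equal(penalty(ivim_params(0.05, 0.001, 0.1), cfg2), 2.5 * 0.01)
})

test_that("signal normalization divides by the b0 mean and clips", {
  sch <- acquisition_scheme(c(0, 0, 500, 1000))
  y <- normalize_signal(c(100, 102, 50, 36.79), sch)
  expect_equal(y$y[1:2], c(100, 102) / 101)
  expect_equal(y$y[4], 36.79 / 101)
  y2 <- normalize_signal(c(100, 100, -2, 10), sch)
  expect_identical(y2$y[3], 0)
  expect_true(attr(y2, "clipped"))
  y3 <- normalize_signal(c(0, 0, 1, 1), sch)
  expect_true(attr(y3, "degenerate"))
  expect_error(normalize_signal(c(1, 2), sch), "length")
})

test_that("Level 1 recovers noiseless voxels from the reduced functional", {
  cfg <- topopro_config()
  y <- noiseless_voxel(0.349, 0.001, 0.04)
  l1 <- fit_voxel_level1(y, cfg)
  expect_equal(unname(l1$s_hat), c(0.001, 0.04), tolerance = 1e-3)
  expect_equal(l1$f_hat, 0.349, tolerance = 1e-3)
  # pure diffusion voxel
  y0 <- noiseless_voxel(0, 0.0015, 0.05)
  l0 <- fit_voxel_level1(y0, cfg)
  expect_lt(l0$f_hat, 0.02)
  expect_equal(unname(l0$s_hat[1]), 0.0015, tolerance = 0.01)
})

test_that("the bimodal valley regime exposes two reduced-surface minima", {
  # well-separated rates with f = 0.349: one valley at low D, one at high D*
  y <- noiseless_voxel(0.349, 0.005, 0.04, scheme54)
  cfg <- topopro_config(bounds_D = c(1e-5, 0.1), bounds_Dstar = c(1e-5, 0.1))
  l1 <- fit_voxel_level1(y, cfg)
  expect_gte(l1$n_minima, 2L)
})

test_that("Level 2 refines without the penalty distorting converged fits", {
  cfg <- topopro_config()
  y <- noiseless_voxel(0.25, 0.001, 0.02)
  l1 <- fit_voxel_level1(y, cfg)
  l2 <- fit_voxel_level2(y, l1, cfg)
  expect_lte(l2$residual, l1$residual + 1e-12)
  expect_equal(c(l2$params$f, l2$params$D, l2$params$Dstar),
               c(0.25, 0.001, 0.02), tolerance = 1e-4)
  # init at exact truth is a fixed point
  init <- list(f_hat = 0.25, s_hat = c(D = 0.001, Dstar = 0.02),
               residual = full_residual(ivim_params(0.25, 0.001, 0.02), y),
               n_minima = 1L, degenerate = FALSE)
  l2b <- fit_voxel_level2(y, init, cfg)
  expect_equal(c(l2b$params$f, l2b$params$D, l2b$params$Dstar),
               c(0.25, 0.001, 0.02), tolerance = 1e-6)
})

test_that("the penalty shrinks D* on noisy low-perfusion voxels", {
  # construct the failure mode the penalty targets: a noise realization that
  # pushes the unpenalized optimum's D* far up the flat valley
  cfg_pen <- topopro_config()
  cfg_off <- topopro_config(penalty_weight = 0)
  found <- FALSE
  for (seed in 100:160) {
    y <- noisy_voxel(0.1, 0.0008, 0.01, snr = 8, seed = seed)
    fit_off <- fit_voxel_topopro(y, cfg_off)
    if (fit_off$params$Dstar > 0.05 && fit_off$params$f > 0 &&
        fit_off$params$f < 0.9) {
      found <- TRUE
      fit_pen <- fit_voxel_topopro(y, cfg_pen)
      expect_lt(fit_pen$params$Dstar, fit_off$params$Dstar)
      break
    }
  }
  expect_true(found)   # the valley failure mode occurs within the scan
})

test_that("the penalty leaves well-determined high-perfusion fits unchanged", {
  cfg_pen <- topopro_config(penalty_weight = 1)
  cfg_off <- topopro_config(penalty_weight = 0)
  withr::with_seed(21, {
    for (rep in 1:8) {
      f0 <- runif(1, 0.3, 0.45)    # comfortably above threshold + 0.05
      D0 <- runif(1, 8e-4, 1.5e-3)
      Ds0 <- runif(1, 0.02, 0.05)
      y <- voxel_signal(pmax(ivim_signal(ivim_params(f0, D0, Ds0), scheme54) +
                               rnorm(54, 0, 0.01), 0), scheme54)
      a <- fit_voxel_topopro(y, cfg_pen)
      b <- fit_voxel_topopro(y, cfg_off)
      expect_equal(c(a$params$f, a$params$D, a$params$Dstar),
                   c(b$params$f, b$params$D, b$params$Dstar), tolerance = 1e-10)
    }
  })
})

test_that("unpenalized Level 2 never degrades the Level-1 residual", {
  cfg <- topopro_config(penalty_weight = 0)
  withr::with_seed(31, {
    for (rep in 1:10) {
      y <- voxel_signal(pmax(ivim_signal(ivim_params(runif(1, 0.05, 0.4),
                                                     runif(1, 5e-4, 2e-3),
                                                     runif(1, 5e-3, 5e-2)),
                                         scheme54) + rnorm(54, 0, 0.05), 0),
                        scheme54)
      l1 <- fit_voxel_level1(y, cfg)
      l2 <- fit_voxel_level2(y, l1, cfg)
      expect_lte(l2$residual, l1$residual + 1e-12)
    }
  })
})

test_that("noiseless recovery in the well-posed regime is sub-0.5%", {
  cases <- random_params(8, seed = 2)
  cfg <- topopro_config()
  for (i in seq_len(nrow(cases))) {
    y <- noiseless_voxel(cases$f[i], cases$D[i], cases$Dstar[i])
    fit <- fit_voxel_topopro(y, cfg)
    expect_lt(abs(fit$params$f - cases$f[i]) / cases$f[i], 0.005)
    expect_lt(abs(fit$params$D - cases$D[i]) / cases$D[i], 0.005)
    expect_lt(abs(fit$params$Dstar - cases$Dstar[i]) / cases$Dstar[i], 0.005)
  }
})

test_that("volume fitting recovers a noiseless block and respects the mask", {
  sch <- scheme27
  tt <- default_tissue_table()
  data <- array(0, c(4, 4, 1, 27))
  truth <- array(0, c(4, 4, 1, 3))
  k <- 0
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1
    row <- tt[(k %% 4) + 1, ]          # cycle through tissue classes
    truth[i, j, 1, ] <- c(row$f, row$D, row$Dstar)
    data[i, j, 1, ] <- 100 * ivim_signal(ivim_params(row$f, row$D, row$Dstar), sch)
  }
  mask <- array(TRUE, c(4, 4, 1))
  mask[1, 1, 1] <- FALSE
  maps <- fit_volume(data, sch, mask, topopro_config(), noise_floor = "none")
  expect_identical(maps$f[1, 1, 1], 0)       # masked out
  expect_identical(maps$Dstar[1, 1, 1], 0)
  for (i in 1:4) for (j in 1:4) {
    if (!mask[i, j, 1] || truth[i, j, 1, 1] == 0) next   # skip fluids (f = 0)
    expect_equal(maps$f[i, j, 1], truth[i, j, 1, 1], tolerance = 1e-3)
    expect_equal(maps$D[i, j, 1], truth[i, j, 1, 2], tolerance = 1e-3 * truth[i, j, 1, 2] + 1e-6)
    expect_equal(maps$Dstar[i, j, 1], truth[i, j, 1, 3], tolerance = 1e-3 * truth[i, j, 1, 3] + 1e-6)
  }
  # determinism: identical call, identical maps
  maps2 <- fit_volume(data, sch, mask, topopro_config(), noise_floor = "none")
  expect_identical(maps$f, maps2$f)
  expect_identical(maps$Dstar, maps2$Dstar)
  # all-zero voxel inside the mask is flagged and zeroed
  data[2, 2, 1, ] <- 0
  maps3 <- fit_volume(data, sch, mask, topopro_config(), noise_floor = "none")
  expect_identical(maps3$f[2, 2, 1], 0)
  expect_identical(maps3$flags[2, 2, 1], 4L)
})

test_that("reported voxels are canonical unless collapsed to mono-exponential", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      y <- voxel_signal(pmax(ivim_signal(ivim_params(runif(1, 0, 0.4),
                                                     runif(1, 5e-4, 3e-3),
                                                     runif(1, 1e-3, 8e-2)),
                                         scheme27) + rnorm(27, 0, 0.08), 0),
                        scheme27)
      fit <- fit_voxel_topopro(y, topopro_config())
      if (fit$params$Dstar < fit$params$D) {
        expect_true(fit$degenerate_flag)   # mono-exponential collapse
        expect_identical(fit$params$f, 0)
      } else {
        expect_gte(fit$params$Dstar, fit$params$D)
      }
    }
  })
})

test_that("configuration invariants are enforced", {
  expect_error(topopro_config(penalty_f_threshold = 0), "strictly inside")
  expect_error(topopro_config(penalty_f_threshold = 1), "strictly inside")
  expect_error(topopro_config(penalty_weight = -1), ">= 0")
  expect_error(topopro_config(bounds_f = c(-0.1, 1)), "bounds")
  expect_error(topopro_config(bounds_D = c(-1e-3, 0.01)), "bounds")
})

test_that("noise-floor estimation recovers the simulated chi floor", {
  ph <- make_phantom(tiny_phantom_spec(seed = 7))
  fl <- estimate_noise_floor(ph$dwi, ph$labels == 0)
  expect_equal(fl, 2 * ph$spec$n_coils * ph$sigma_per_slice^2, tolerance = 0.05)
  corr <- subtract_noise_floor(ph$dwi, fl)
  # corrected background power is centred near zero
  bg <- ph$labels == 0
  expect_lt(mean((corr[, , 1, ]^2)[bg]), 0.2 * fl)
})
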