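test_that("Shepp-Logan labels follow the analytic ellipse geometry", {
  lab <- shepp_logan_labels(c(64, 64))
  # background outside the outer ellipse: corners and edges are 0
  expect_identical(lab[1, 1], 0L)
  expect_identical(lab[64, 64], 0L)
  expect_identical(lab[1, 64], 0L)
  expect_true(all(lab[, 1] == 0L))
  # exactly six non-background classes at sufficient resolution
  lab256 <- shepp_logan_labels(c(256, 256))
  expect_setequal(setdiff(unique(as.vector(lab256)), 0L), 1:6)
  # analytic membership oracle: recompute the class of sampled grid points
  # from the ellipse equations, independently of the rasterizer
  ell <- topoivim:::.shepp_logan_ellipses()
  cls <- topoivim:::.shepp_logan_classes
  x <- seq(-1, 1, length.out = 256)
  withr::with_seed(13, {
    for (rep in 1:100) {
      i <- sample(256, 1); j <- sample(256, 1)
      expected <- 0L
      for (e in seq_len(nrow(ell))) {
        phi <- ell[e, "phi"] * pi / 180
        dx <- x[i] - ell[e, "x0"]; dy <- x[j] - ell[e, "y0"]
        u <- dx * cos(phi) + dy * sin(phi)
        v <- -dx * sin(phi) + dy * cos(phi)
        if ((u / ell[e, "a"])^2 + (v / ell[e, "b"])^2 <= 1) expected <- cls[e]
      }
      expect_identical(lab256[i, j], expected)
    }
  })
  expect_error(shepp_logan_labels(c(16, 16)), "at least 32")
})

test_that("ground-truth maps are piecewise constant on the labels", {
  lab <- shepp_logan_labels(c(64, 64, 2))
  tt <- default_tissue_table()
  gt <- assign_params(lab, tt)
  for (cl in 1:6) {
    sel <- lab == cl
    if (!any(sel)) next
    expect_length(unique(gt$gt_f[sel]), 1L)
    expect_length(unique(gt$gt_D[sel]), 1L)
    expect_length(unique(gt$gt_Dstar[sel]), 1L)
  }
  expect_lte(length(setdiff(unique(as.vector(gt$gt_D)), 0)), 6L)
  # cavity has no perfusion compartment
  expect_true(all(gt$gt_f[lab == tissue_classes()[["cavity"]]] == 0))
  # swapping two classes in the table swaps their regions exactly
  tt2 <- tt
  tt2[tt2$class == "normal", 2:4] <- tt[tt$class == "csf", 2:4]
  tt2[tt2$class == "csf", 2:4] <- tt[tt$class == "normal", 2:4]
  gt2 <- assign_params(lab, tt2)
  expect_equal(unique(gt2$gt_D[lab == 1]), unique(gt$gt_D[lab == 6]))
  expect_equal(unique(gt2$gt_f[lab == 6]), unique(gt$gt_f[lab == 1]))
  expect_equal(unique(gt2$gt_Dstar[lab == 6]), unique(gt$gt_Dstar[lab == 1]))
  tt_bad <- tt[-2, ]
  expect_error(assign_params(lab, tt_bad), "missing")
})

test_that("noiseless DWI simulation is the voxelwise forward model", {
  lab <- shepp_logan_labels(c(32, 32, 1))
  gt <- assign_params(lab)
  s0 <- array(ifelse(as.vector(lab) > 0, 100, 0), dim(lab))
  dwi <- simulate_dwi_noiseless(gt, scheme27, s0)
  expect_identical(dim(dwi), c(32L, 32L, 1L, 27L))
  expect_equal(dwi[, , , 1, drop = FALSE], array(s0, c(32, 32, 1, 1)))  # b = 0 volume is s0
  i <- which(lab == 1, arr.ind = TRUE)[1, ]
  expect_equal(dwi[i[1], i[2], 1, ],
               100 * ivim_signal(ivim_params(0.10, 8e-4, 0.01), scheme27),
               tolerance = 1e-12)
  # fluid voxels decay mono-exponentially
  j <- which(lab == 6, arr.ind = TRUE)[1, ]
  expect_equal(dwi[j[1], j[2], 1, ], 100 * exp(-scheme27$bvalues * 0.003),
               tolerance = 1e-12)
})

test_that("coil sensitivities are smooth, normalized and reproducible", {
  s <- coil_sensitivity(c(48, 48), n_coils = 8, seed = 3)
  sos <- apply(abs(s)^2, c(1, 2), sum)
  expect_equal(max(abs(sos - 1)), 0, tolerance = 1e-10)
  s1 <- coil_sensitivity(c(48, 48), n_coils = 1, seed = 3)
  expect_equal(max(abs(abs(s1) - 1)), 0, tolerance = 1e-12)
  expect_identical(s, coil_sensitivity(c(48, 48), n_coils = 8, seed = 3))
  expect_false(identical(s, coil_sensitivity(c(48, 48), n_coils = 8, seed = 4)))
})

test_that("sum-of-squares noise hits the target SNR and chi statistics", {
  lab <- shepp_logan_labels(c(48, 48, 1))
  gt <- assign_params(lab)
  s0 <- array(ifelse(as.vector(lab) > 0, 100, 0), dim(lab))
  noiseless <- simulate_dwi_noiseless(gt, scheme27, s0)
  sens <- coil_sensitivity(c(48, 48), 8, seed = 1)
  out <- add_noise_sos(noiseless, sens, snr_per_slice = 10, labels = lab, seed = 2)
  # sigma is the normal-tissue b0 mean over the target SNR by construction
  expect_equal(out$sigma_per_slice,
               mean(noiseless[, , 1, 1][lab[, , 1] == 1]) / 10, tolerance = 1e-12)
  # zero-noise limit: combined magnitudes equal the noiseless signal
  out0 <- add_noise_sos(noiseless, sens, snr_per_slice = 1e12, labels = lab, seed = 2)
  expect_equal(out0$dwi, noiseless, tolerance = 1e-6)
  # background SOS power is chi-square with 2 * n_coils dof
  bg <- as.vector(lab[, , 1] == 0)
  bgvals <- matrix(out$dwi[, , 1, ], ncol = 27)[bg, ]
  stat <- as.vector(bgvals^2) / out$sigma_per_slice^2
  expect_equal(mean(stat), 16, tolerance = 0.05)
  expect_equal(stats::var(stat), 32, tolerance = 0.15)
  # an all-fluid slice cannot calibrate SNR
  lab_bad <- array(6L, dim(lab))
  expect_error(add_noise_sos(noiseless, sens, 10, lab_bad, seed = 1),
               "normal-tissue")
})

test_that("phantom assembly matches its specification", {
  spec <- tiny_phantom_spec(shape = c(32L, 32L, 2L), m = 27L, snr = 20, seed = 9)
  ph <- make_phantom(spec)
  expect_identical(dim(ph$dwi), c(32L, 32L, 2L, 27L))
  expect_true(all(ph$dwi >= 0))
  expect_length(ph$sigma_per_slice, 2L)
  # per-slice sigma decreases as nominal SNR increases
  spec2 <- phantom_spec(shape = c(32L, 32L, 3L), bvalues = make_bvalues(27L),
                        snr_per_slice = c(2, 10, 50), seed = 9)
  ph2 <- make_phantom(spec2)
  expect_true(all(diff(ph2$sigma_per_slice) < 0))
  # byte-identical regeneration under the same seed
  expect_identical(ph$dwi, make_phantom(spec)$dwi)
  # the default specification declares the full-scale geometry
  dspec <- phantom_spec()
  expect_identical(dspec$shape, c(256L, 256L, 5L))
  expect_length(dspec$scheme$bvalues, 54L)
  expect_equal(dspec$snr_per_slice, c(2, 5, 10, 20, 50))
  expect_identical(dspec$n_coils, 8L)
  expect_error(phantom_spec(shape = c(64, 64, 2), snr_per_slice = 10),
               "one SNR per slice")
})
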