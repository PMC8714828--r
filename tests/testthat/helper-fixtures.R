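# Shared fixtures: schemes, voxels and parameter generators, all built in
# code with fixed seeds.

scheme54 <- make_bvalues(54L)
scheme27 <- make_bvalues(27L)

noiseless_voxel <- function(f, D, Dstar, scheme = scheme54) {
  voxel_signal(ivim_signal(ivim_params(f, D, Dstar), scheme), scheme)
}

# Gaussian-noise voxel on the normalized-signal scale (clipped at zero), for
# fitter tests that do not need the full multi-coil chi model.
noisy_voxel <- function(f, D, Dstar, snr, scheme = scheme54, seed = 1L) {
  withr::with_seed(seed, {
    y <- ivim_signal(ivim_params(f, D, Dstar), scheme) + rnorm(length(scheme$bvalues), 0, 1 / snr)
  })
  voxel_signal(pmax(y, 0), scheme)
}

# Random parameter triples in the well-posed IVIM regime.
random_params <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    data.frame(f = runif(n, 0.05, 0.5),
               D = runif(n, 5e-4, 2e-3),
               ratio = runif(n, 5, 40))
  }) |> transform(Dstar = D * ratio)
}

tiny_phantom_spec <- function(shape = c(32L, 32L, 1L), m = 27L, snr = 10,
                              seed = 42L) {
  phantom_spec(shape = shape, bvalues = make_bvalues(m),
               snr_per_slice = rep(snr, shape[3L]), seed = seed)
}
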