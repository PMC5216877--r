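# Shared fixtures: modest grids keep single tests fast; kernels are cached
# here because building them is the only repeated expensive step.

fix_t <- seq(0, 3, by = 0.016)
fix_r <- seq(1.5, 6, by = 0.05)
fix_kern <- dipolar_kernel(fix_t, fix_r)

# longer trace / wider grid for mixtures containing the 4.8 nm fingerprint
long_t <- seq(0, 5, by = 0.016)
wide_r <- seq(1.5, 8, by = 0.05)
long_kern <- dipolar_kernel(long_t, wide_r)

fix_bg <- background_model(k = 0.3, d = 3, lambda = 0.35)

single_gaussian_dist <- function(mu = 3.0, sigma = 0.15, r = fix_r) {
  distance_distribution(r, stats::dnorm(r, mu, sigma))
}

# background-corrected form factor computed with the *true* background,
# for tests that isolate a later stage from background-fit error
true_ff <- function(trace, bg = fix_bg) form_factor(trace, bg)

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
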