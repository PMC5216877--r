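test_that("background fit recovers known parameters on a noiseless trace", {
  d <- single_gaussian_dist()
  tr <- compose_signal(d, fix_bg, fix_t, kern = fix_kern)
  bf <- fit_background(tr, t_start = 1.5)
  expect_lt(abs(bf$k - 0.3) / 0.3, 1e-3)
  expect_lt(abs(bf$d - 3) / 3, 1e-3)
  expect_lt(abs(bf$lambda - 0.35) / 0.35, 1e-3)
})

test_that("pure background (zero modulation depth) is fit exactly", {
  tr <- deer_trace(fix_t, stretched_background(fix_t, 0.2, 1.5))
  expect_warning(bf <- fit_background(tr, t_start = 1.0), "modulation depth")
  expect_lt(abs(bf$k - 0.2), 1e-6)
  expect_lt(abs(bf$d - 1.5), 1e-6)
})

test_that("modulation depth is recovered within 0.02 under noise", {
  # the three-parameter (free-d) background fit needs a long decayed tail
  # to separate lambda from the decay shape
  tg <- seq(0, 5, by = 0.016)
  kern <- dipolar_kernel(tg, fix_r)
  d <- single_gaussian_dist()
  lam_err <- vapply(1:100, function(seed) {
    tr <- simulate_deer_trace(d, fix_bg, noise_sd = 0.005, t_us = tg,
                              seed = seed, kern = kern)
    bf <- suppressWarnings(fit_background(tr, t_start = 2.0))
    bf$lambda - 0.35
  }, numeric(1))
  expect_lt(mean(abs(lam_err)), 0.02)
  expect_lt(abs(mean(lam_err)), 0.02)
})

test_that("background fit preconditions are enforced", {
  d <- single_gaussian_dist()
  tr <- compose_signal(d, fix_bg, fix_t, kern = fix_kern)
  expect_error(fit_background(tr, t_start = -1), "t_start")
  expect_error(fit_background(tr, t_start = max(fix_t) - 0.05),
               "fewer than 10")
  expect_error(fit_background(tr, t_start = 1.5, d_fix = 1.2), "d_fix")
})

test_that("a mis-specified background dimension leaves a systematic tail residual", {
  d <- single_gaussian_dist()
  bg15 <- background_model(k = 0.3, d = 1.5, lambda = 0.35)
  tr <- compose_signal(d, bg15, fix_t, kern = fix_kern)
  wrong <- background_model(k = 0.3, d = 3, lambda = 0.35)
  ff_wrong <- form_factor(tr, wrong)
  ff_right <- form_factor(tr, bg15)
  tail_idx <- fix_t >= 2
  dev_wrong <- max(abs(ff_wrong$f[tail_idx] - ff_right$f[tail_idx]))
  expect_gt(dev_wrong, 0.05)  # far above any numerical noise floor
})

test_that("degenerate lambda gives a flat form factor", {
  bg0 <- background_model(k = 0.4, d = 3, lambda = 1e-12)
  d <- single_gaussian_dist()
  tr <- compose_signal(d, bg0, fix_t, kern = fix_kern)
  ff <- form_factor(tr, bg0)
  expect_close(ff$f, rep(1, length(fix_t)), 1e-9)
})

test_that("Tikhonov inversion recovers a single Gaussian and a delta", {
  d <- single_gaussian_dist(3.5, 0.15)
  tr <- compose_signal(d, fix_bg, fix_t, kern = fix_kern)
  res <- tikhonov_invert(true_ff(tr), fix_kern, alpha = 0.1)
  mode <- res$dist$r[which.max(res$dist$density)]
  expect_lte(abs(mode - 3.5), 0.05 + 1e-9)  # within one grid step

  dd <- distance_distribution(fix_r, as.numeric(abs(fix_r - 4) < 1e-9))
  trd <- compose_signal(dd, fix_bg, fix_t, kern = fix_kern)
  resd <- tikhonov_invert(true_ff(trd), fix_kern, alpha = 1e-3)
  w <- deerquant:::trapz_weights(fix_r)
  mass_near <- sum((w * resd$dist$density)[abs(fix_r - 4) <= 0.1 + 1e-9])
  expect_gte(mass_near, 0.9)
})

test_that("inversion output is non-negative and area-normalized", {
  d <- single_gaussian_dist(3.2, 0.2)
  for (seed in 1:5) {
    tr <- simulate_deer_trace(d, fix_bg, noise_sd = 0.01, t_us = fix_t,
                              seed = seed, kern = fix_kern)
    bf <- suppressWarnings(fit_background(tr, t_start = 1.5, d_fix = 3))
    res <- tikhonov_invert(form_factor(tr, bf), fix_kern, alpha = 1)
    expect_true(all(res$dist$density >= 0))
    w <- deerquant:::trapz_weights(fix_r)
    expect_lt(abs(sum(w * res$dist$density) - 1), 1e-9)
  }
})

test_that("interior solutions match the closed-form regularized solve", {
  # strong regularization keeps the solution strictly positive, so the
  # non-negativity constraint is inactive and the answer must equal the
  # unconstrained normal-equation solution
  d <- distance_distribution(fix_r, stats::dnorm(fix_r, 3.75, 1.0))
  tr <- compose_signal(d, fix_bg, fix_t, kern = fix_kern)
  ff <- true_ff(tr)
  alpha <- 1
  res <- tikhonov_invert(ff, fix_kern, alpha)
  s <- (ff$f - (1 - ff$lambda)) / ff$lambda
  w <- deerquant:::trapz_weights(fix_r)
  Kw <- sweep(fix_kern$K, 2, w, `*`)
  L <- deerquant:::second_difference_operator(length(fix_r))
  p_ls <- solve(crossprod(Kw) + alpha^2 * crossprod(L), crossprod(Kw, s))
  expect_true(all(p_ls > 0))  # interior: oracle comparison is valid
  p_ls <- p_ls / sum(w * p_ls)
  expect_close(res$dist$density, as.vector(p_ls), 1e-8)
})

test_that("residual and smoothness norms are monotone along the alpha grid", {
  d <- single_gaussian_dist(3.5, 0.15)
  tr <- simulate_deer_trace(d, fix_bg, noise_sd = 0.007, t_us = fix_t,
                            seed = 3, kern = fix_kern)
  bf <- suppressWarnings(fit_background(tr, t_start = 1.5, d_fix = 3))
  ff <- form_factor(tr, bf)
  alphas <- 10^seq(-3, 2, length.out = 21)
  res <- lapply(alphas, function(a) tikhonov_invert(ff, fix_kern, a))
  rho <- vapply(res, `[[`, numeric(1), "residual_norm")
  eta <- vapply(res, `[[`, numeric(1), "smoothness_norm")
  expect_true(all(diff(rho) >= -1e-9))
  expect_true(all(diff(eta) <= 1e-9))
})

test_that("L-curve alpha lands within a decade of the oracle alpha", {
  d <- single_gaussian_dist(3.5, 0.25)
  agrid <- 10^seq(-4, 2, length.out = 25)
  for (seed in 1:20) {
    tr <- simulate_deer_trace(d, fix_bg, noise_sd = 0.35 / 50, t_us = fix_t,
                              seed = seed, kern = fix_kern)
    bf <- suppressWarnings(fit_background(tr, t_start = 1.5, d_fix = 3))
    B <- stretched_background(fix_t, bf$k, bf$d)
    ff <- form_factor(tr, bf)
    a_sel <- as.numeric(select_alpha(ff, fix_kern, agrid, weights = B))
    err <- vapply(agrid, function(a) {
      p <- tikhonov_invert(ff, fix_kern, a, weights = B)$dist$density
      sqrt(sum((p - d$density)^2))
    }, numeric(1))
    a_oracle <- agrid[which.min(err)]
    expect_gte(a_sel / a_oracle, 0.1)
    expect_lte(a_sel / a_oracle, 10)
  }
})

test_that("a structureless form factor triggers the degenerate L-curve fallback", {
  f_noise <- form_factor_signal(
    fix_t, 1 + withr::with_seed(1, stats::rnorm(length(fix_t), sd = 0.01)),
    lambda = 0.35)
  expect_warning(a <- select_alpha(f_noise, fix_kern), "degenerate L-curve")
  expect_equal(as.numeric(a), stats::median(10^seq(-4, 2, length.out = 25)))
})

test_that("recovered peak position stays within 0.05 nm at SNR 30", {
  d <- single_gaussian_dist(3.0, 0.15)
  errs <- vapply(1:100, function(seed) {
    tr <- simulate_deer_trace(d, fix_bg, noise_sd = 0.35 / 30, t_us = fix_t,
                              seed = seed, kern = fix_kern)
    bf <- suppressWarnings(fit_background(tr, t_start = 1.5, d_fix = 3))
    B <- stretched_background(fix_t, bf$k, bf$d)
    res <- tikhonov_invert(form_factor(tr, bf), fix_kern, 1, weights = B)
    peak_position(res$dist) - 3.0
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.05)
})
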