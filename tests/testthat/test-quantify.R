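# Fixtures here use the NBD-degenerate-site style fingerprints of a
# heterodimeric exporter: OF state at 3.0 nm, nucleotide-bound IF state
# at 4.8 nm.
quant_of <- c(3.0, 0.25)
quant_if <- c(4.8, 0.35)
quant_bg <- background_model(k = 0.25, d = 3, lambda = 0.35)

mixture_ff <- function(f_of, noise_seed = NULL, noise_sd = 0.01) {
  d <- make_mixture_distribution(f_of, quant_of, quant_if, wide_r)
  if (is.null(noise_seed)) {
    tr <- compose_signal(d, quant_bg, long_t, kern = long_kern)
    form_factor(tr, quant_bg)  # true background: isolates the fit stage
  } else {
    tr <- simulate_deer_trace(d, quant_bg, noise_sd = noise_sd,
                              t_us = long_t, seed = noise_seed,
                              kern = long_kern)
    bf <- suppressWarnings(fit_background(tr, t_start = 2.5, d_fix = 3))
    form_factor(tr, bf)
  }
}

test_that("reference fit recovers a pure OF state and an 85/15 mixture", {
  ref_pure <- fit_reference_state(mixture_ff(1), long_kern)
  expect_gte(ref_pure$area_of, 0.95)

  ref <- fit_reference_state(mixture_ff(0.85), long_kern)
  expect_lt(abs(ref$mu_of - 3.0), 0.1)
  expect_lt(abs(ref$area_of - 0.85), 0.05)
  expect_false(ref$fixed_of)
})

test_that("reference-fit OF area is stable across noise replicates", {
  areas <- vapply(1:50, function(seed) {
    ff <- mixture_ff(0.85, noise_seed = seed)
    B <- stretched_background(long_t, quant_bg$k, quant_bg$d)
    fit_reference_state(ff, long_kern, weights = B)$area_of
  }, numeric(1))
  expect_lt(stats::sd(areas), 0.05)
})

test_that("constrained fit honors the frozen OF component", {
  ref <- fit_reference_state(mixture_ff(0.85), long_kern)

  apo <- fit_constrained_state(mixture_ff(0), long_kern, ref)
  expect_lte(apo$area_of, 0.05)
  expect_true(apo$fixed_of)
  expect_equal(apo$mu_of, ref$mu_of)
  expect_equal(apo$sigma_of, ref$sigma_of)

  half <- fit_constrained_state(mixture_ff(0.5), long_kern, ref)
  expect_gte(half$area_of, 0.45)
  expect_lte(half$area_of, 0.55)
})

test_that("constrained and unconstrained fits agree when truth matches the reference", {
  ff <- mixture_ff(0.85)
  ref <- fit_reference_state(ff, long_kern)
  con <- fit_constrained_state(ff, long_kern, ref)
  expect_lt(abs(con$area_of - ref$area_of), 0.03)
  # nesting: the constrained optimum cannot beat the unconstrained one
  expect_gte(con$rss, ref$rss - 1e-10)
})

test_that("a merged two-Gaussian solution raises a degenerate-fit error", {
  expect_error(
    deerquant:::check_degenerate(3.0, 0.8, 3.1, 0.2),
    "degenerate"
  )
})

test_that("of_fraction is the relative OF area in percent", {
  m <- two_gaussian_model(3, 0.2, 0.5, 4.8, 0.3)
  expect_equal(of_fraction(m), 50)
  expect_equal(of_fraction(two_gaussian_model(3, 0.2, 1, 4.8, 0.3)), 100)
  expect_error(two_gaussian_model(3, 0.2, 1.2, 4.8, 0.3), "area_of")
  expect_equal(m$area_of + m$area_2, 1)
})

test_that("model areas sum to one on the evaluated grid", {
  m <- two_gaussian_model(3, 0.2, 0.3, 4.8, 0.35)
  d <- model_distribution(m, wide_r)
  w <- deerquant:::trapz_weights(wide_r)
  expect_lt(abs(sum(w * d$density) - 1), 1e-9)
})

test_that("rank_conditions orders by mean OF% and is order-invariant", {
  panel <- data.frame(
    condition = rep(c("ATP-Vi-Mg", "apo", "ATP-Mg"), each = 3),
    pair = rep(c("p1", "p2", "p3"), times = 3),
    of_percent = c(88, 91, 90, 4, 6, 5, 48, 52, 50))
  rk <- rank_conditions(panel)
  expect_equal(rk$table$condition, c("apo", "ATP-Mg", "ATP-Vi-Mg"))
  expect_equal(rk$ranking, "apo < ATP-Mg < ATP-Vi-Mg")
  # permuting rows changes nothing
  rk2 <- rank_conditions(panel[sample(nrow(panel)), ])
  expect_equal(rk2$table, rk$table)
  # overlapping dispersions are flagged as ties
  tied <- data.frame(condition = rep(c("a", "b"), each = 2),
                     pair = rep(c("p1", "p2"), 2),
                     of_percent = c(10, 14, 13, 17))
  expect_match(rank_conditions(tied)$ranking, "~", fixed = TRUE)
  # single condition: trivial table
  one <- rank_conditions(data.frame(condition = "apo", pair = "p1",
                                    of_percent = 5))
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$ranking, "apo")
  expect_error(rank_conditions(data.frame()), "non-empty")
})

test_that("recovered OF fractions are monotone in the truth", {
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  ref <- fit_reference_state(mixture_ff(1, noise_seed = 207), long_kern)
  got <- vapply(seq_along(fracs), function(i) {
    ff <- mixture_ff(fracs[i], noise_seed = 300 + i)
    B <- stretched_background(long_t, quant_bg$k, quant_bg$d)
    of_fraction(fit_constrained_state(ff, long_kern, ref, weights = B))
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_lt(max(abs(got - 100 * fracs)), 5)
})
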