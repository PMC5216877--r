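# Constrained two-Gaussian quantification of IF/OF population fractions
# and ranking of nucleotide conditions.

# component density: Gaussian truncated to the grid and renormalized there,
# so the mixture weight is exactly the component's area on the grid
# (avoids edge leakage biasing area ratios).
truncated_gaussian <- function(r, mu, sigma) {
  g <- stats::dnorm(r, mean = mu, sd = sigma)
  a <- trapz_integral(r, g)
  if (a <= 0) stop_input("Gaussian component has no support on the grid")
  g / a
}

two_gaussian_density <- function(r, mu1, sigma1, a1, mu2, sigma2) {
  a1 * truncated_gaussian(r, mu1, sigma1) +
    (1 - a1) * truncated_gaussian(r, mu2, sigma2)
}

#' Two-Gaussian distance-distribution model
#'
#' Mixture of two Gaussians on the distance grid; the component labeled
#' "OF" carries the outward-facing population, and its relative area is the
#' OF fraction. Areas of the two components sum to 1.
#'
#' @param mu_of,sigma_of mean and width (nm) of the OF component.
#' @param area_of relative area of the OF component, in \[0, 1\].
#' @param mu_2,sigma_2 mean and width (nm) of the second (IF) component.
#' @param fixed_of logical: were the OF mean/width held fixed during the fit?
#' @param rss residual sum of squares of the time-domain fit (if any).
#' @return object of class `two_gaussian_model`; `area_2 = 1 - area_of`.
#' @export
two_gaussian_model <- function(mu_of, sigma_of, area_of, mu_2, sigma_2,
                               fixed_of = FALSE, rss = NA_real_) {
  if (!is.finite(area_of) || area_of < 0 || area_of > 1) {
    stop_input("area_of must lie in [0, 1]")
  }
  if (sigma_of <= 0 || sigma_2 <= 0) stop_input("sigmas must be positive")
  structure(list(mu_of = mu_of, sigma_of = sigma_of, area_of = area_of,
                 mu_2 = mu_2, sigma_2 = sigma_2, area_2 = 1 - area_of,
                 fixed_of = fixed_of, rss = rss),
            class = "two_gaussian_model")
}

#' Evaluate a two-Gaussian model as a distance distribution
#'
#' @param model a `two_gaussian_model`.
#' @param r_nm distance grid.
#' @return a `distance_distribution`.
#' @export
model_distribution <- function(model, r_nm) {
  distance_distribution(
    r_nm,
    two_gaussian_density(r_nm, model$mu_of, model$sigma_of, model$area_of,
                         model$mu_2, model$sigma_2),
    normalize = TRUE)
}

# predicted form factor for parameter vector on the kernel grid; lambda is
# the (possibly refitted) modulation depth, dk a residual background tilt
# left over from imperfect background division, v0 an overall scale
# absorbing the renormalization of F by its (noisy) first point.
predict_ff <- function(kern, lambda, mu1, sigma1, a1, mu2, sigma2,
                       dk = 0, v0 = 1) {
  p <- two_gaussian_density(kern$r, mu1, sigma1, a1, mu2, sigma2)
  w <- trapz_weights(kern$r)
  s <- as.vector(kern$K %*% (w * p))
  v0 * ((1 - lambda) + lambda * s) * exp(-dk * kern$t)
}

# longest component mean distance resolvable from a trace of length tmax:
# require the perpendicular dipolar frequency to complete at least one
# period within the trace, r <= (D tmax)^(1/3); components beyond this are
# indistinguishable from a modulation-depth offset and produce edge ghosts.
max_resolvable_r <- function(tmax_us, D = DIPOLAR_CONSTANT_MHZ_NM3) {
  (D * tmax_us)^(1 / 3)
}

check_degenerate <- function(mu1, sigma1, mu2, sigma2) {
  if (abs(mu1 - mu2) < max(sigma1, sigma2) / 2) {
    stop_input(sprintf(
      "degenerate two-Gaussian fit: components merged (|%.3f - %.3f| < %.3f)",
      mu1, mu2, max(sigma1, sigma2) / 2))
  }
}

# time-domain least squares of the two-Gaussian model against a form
# factor. With `nuisance = TRUE` the modulation depth is refitted and a
# residual background tilt plus overall scale are co-estimated; the
# Gaussian parameter bounds (mu1, s1, a1, mu2, s2) are supplied by the
# caller, which pins parameters via degenerate bounds when constraining.
fit_two_gaussian_ls <- function(ff, kern, start, lower, upper,
                                nuisance = TRUE, weights = NULL) {
  if (nuisance) {
    start <- c(start, lam = ff$lambda, dk = 0, v0 = 1)
    lower <- c(lower, lam = 0.05, dk = -0.3, v0 = 0.9)
    upper <- c(upper, lam = 0.95, dk = 0.3, v0 = 1.1)
  }
  if (is.null(weights)) weights <- rep(1, length(ff$f))
  resid_fun <- function(par) {
    lam <- if (nuisance) par[["lam"]] else ff$lambda
    dk <- if (nuisance) par[["dk"]] else 0
    v0 <- if (nuisance) par[["v0"]] else 1
    weights * (ff$f - predict_ff(kern, lam, par[["mu1"]], par[["s1"]],
                                 par[["a1"]], par[["mu2"]], par[["s2"]],
                                 dk = dk, v0 = v0))
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  list(par = fit$par, rss = sum(fit$fvec^2))
}

#' Unconstrained two-Gaussian fit of the reference (vanadate-trapped) state
#'
#' Fits a two-Gaussian distance distribution through the dipolar forward
#' model to a form factor, all five independent parameters free (two means,
#' two widths, one relative area; the areas sum to 1). The larger-area
#' component is labeled OF; an exact area tie is broken in favor of the
#' shorter mean distance (NBD closure shortens distances). The fitted OF
#' mean and width are recorded for reuse as fixed parameters when fitting
#' all other conditions.
#'
#' The fit is run from a small deterministic set of starting points and the
#' best (lowest residual) non-degenerate solution is kept. By default the
#' modulation depth is refitted alongside the Gaussians, together with a
#' residual background tilt and an overall scale; these nuisance
#' parameters absorb the small systematic distortions left by sequential
#' background division (imperfect decay constant, renormalization by a
#' noisy first point) that would otherwise bias the component areas.
#'
#' @param ff a `form_factor` measured on the reference condition.
#' @param kern matching `kernel_matrix`.
#' @param start_mus optional numeric vector of candidate component means
#'   (nm) used to seed the multi-start; defaults to a coarse scan of the
#'   grid interior.
#' @param nuisance logical; co-fit modulation depth, background tilt and
#'   scale (default `TRUE`).
#' @param weights optional per-point residual weights. Noise that is white
#'   on the primary trace is amplified by the background division at late
#'   times, so weighting residuals by the fitted background `B(t)` restores
#'   homoscedasticity; [quantify_panel()] does this automatically.
#' @return a `two_gaussian_model` with `fixed_of = FALSE`.
#' @export
fit_reference_state <- function(ff, kern, start_mus = NULL, nuisance = TRUE,
                                weights = NULL) {
  stopifnot(inherits(ff, "form_factor"), inherits(kern, "kernel_matrix"))
  rmin <- min(kern$r)
  rmax <- min(max(kern$r), max_resolvable_r(max(kern$t)))
  if (is.null(start_mus)) {
    start_mus <- seq(rmin + 0.3, min(rmax, rmin + 5), length.out = 5)
  }
  lower <- c(mu1 = rmin, s1 = 0.03, a1 = 0, mu2 = rmin, s2 = 0.03)
  upper <- c(mu1 = rmax, s1 = 1.5, a1 = 1, mu2 = rmax, s2 = 1.5)
  fits <- list()
  combos <- utils::combn(seq_along(start_mus), 2L)
  for (j in seq_len(ncol(combos))) {
    st <- c(mu1 = start_mus[combos[1, j]], s1 = 0.25, a1 = 0.6,
            mu2 = start_mus[combos[2, j]], s2 = 0.25)
    fits[[j]] <- fit_two_gaussian_ls(ff, kern, st, lower, upper,
                                     nuisance = nuisance, weights = weights)
  }
  # rank starts by residual; keep the best solution whose components are
  # resolved (a merged pair is an uninformative reparameterization of a
  # single Gaussian and cannot define the OF reference)
  fits <- fits[order(vapply(fits, `[[`, numeric(1), "rss"))]
  ok <- vapply(fits, function(f) {
    p <- f$par
    abs(p[["mu1"]] - p[["mu2"]]) >= max(p[["s1"]], p[["s2"]]) / 2
  }, logical(1))
  if (!any(ok)) {
    p <- fits[[1]]$par
    check_degenerate(p[["mu1"]], p[["s1"]], p[["mu2"]], p[["s2"]])
  }
  best <- fits[[which(ok)[1]]]
  p <- best$par
  # larger-area component is the major (OF) one; tie -> shorter distance
  first_is_of <- if (abs(p[["a1"]] - 0.5) > 1e-9) p[["a1"]] > 0.5 else
    p[["mu1"]] <= p[["mu2"]]
  if (first_is_of) {
    two_gaussian_model(p[["mu1"]], p[["s1"]], p[["a1"]],
                       p[["mu2"]], p[["s2"]], fixed_of = FALSE,
                       rss = best$rss)
  } else {
    two_gaussian_model(p[["mu2"]], p[["s2"]], 1 - p[["a1"]],
                       p[["mu1"]], p[["s1"]], fixed_of = FALSE,
                       rss = best$rss)
  }
}

#' Constrained two-Gaussian fit with the OF component frozen
#'
#' Fits a two-Gaussian model to a form factor with the OF mean and width
#' held fixed at the values obtained from the reference state; only the OF
#' relative area and the second (IF) component's mean and width vary. The
#' two areas are constrained to sum to 1.
#'
#' As in [fit_reference_state()], the modulation depth plus a residual
#' background tilt and overall scale are co-fitted by default so that
#' imperfections of the sequential background correction do not leak into
#' the area ratio.
#'
#' @param ff a `form_factor`.
#' @param kern matching `kernel_matrix`.
#' @param fixed a `two_gaussian_model` from [fit_reference_state()]
#'   providing `mu_of` and `sigma_of`.
#' @param start_mus candidate starting means (nm) for the free component.
#' @param nuisance logical; co-fit modulation depth, tilt and scale.
#' @param weights optional per-point residual weights (see
#'   [fit_reference_state()]).
#' @return a `two_gaussian_model` with `fixed_of = TRUE`.
#' @export
fit_constrained_state <- function(ff, kern, fixed, start_mus = NULL,
                                  nuisance = TRUE, weights = NULL) {
  stopifnot(inherits(ff, "form_factor"), inherits(kern, "kernel_matrix"),
            inherits(fixed, "two_gaussian_model"))
  rmin <- min(kern$r)
  rmax <- min(max(kern$r), max_resolvable_r(max(kern$t)))
  if (is.null(start_mus)) {
    start_mus <- seq(rmin + 0.3, min(rmax, rmin + 5), length.out = 5)
  }
  eps <- 1e-12  # pin mu1/s1 at the reference values via degenerate bounds
  lower <- c(mu1 = fixed$mu_of - eps, s1 = fixed$sigma_of - eps, a1 = 0,
             mu2 = rmin, s2 = 0.03)
  upper <- c(mu1 = fixed$mu_of + eps, s1 = fixed$sigma_of + eps, a1 = 1,
             mu2 = rmax, s2 = 1.5)
  best <- NULL
  for (mu0 in start_mus) {
    for (a0 in c(0.3, 0.7)) {
      st <- c(mu1 = fixed$mu_of, s1 = fixed$sigma_of, a1 = a0,
              mu2 = mu0, s2 = 0.25)
      fit <- fit_two_gaussian_ls(ff, kern, st, lower, upper,
                                 nuisance = nuisance, weights = weights)
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
  }
  p <- best$par
  # a pure-OF state legitimately drives area_2 -> 0, where the second
  # component's position is unidentifiable; only flag merged components
  # when both carry appreciable area.
  if (p[["a1"]] > 0.05 && p[["a1"]] < 0.95) {
    check_degenerate(p[["mu1"]], p[["s1"]], p[["mu2"]], p[["s2"]])
  }
  two_gaussian_model(fixed$mu_of, fixed$sigma_of, p[["a1"]],
                     p[["mu2"]], p[["s2"]], fixed_of = TRUE, rss = best$rss)
}

#' Outward-facing population percentage
#'
#' The OF percentage is the relative area of the OF component of the
#' two-Gaussian model, times 100.
#'
#' @param model a `two_gaussian_model`.
#' @return percentage in \[0, 100\].
#' @export
of_fraction <- function(model) {
  stopifnot(inherits(model, "two_gaussian_model"))
  100 * model$area_of
}

#' Rank nucleotide conditions by their OF population
#'
#' Aggregates per-pair OF percentages into a per-condition mean and
#' dispersion (standard deviation across pairs) and orders conditions by
#' increasing mean OF percentage. Adjacent conditions whose means differ by
#' less than the sum of their dispersions are flagged as ties ("~").
#'
#' @param panel data frame with columns `condition`, `pair`, `of_percent`.
#' @return object of class `of_ranking`: `table` (one row per condition,
#'   ascending mean OF%), and `ranking` (a string such as
#'   `"A ~ B < C < D"`).
#' @export
rank_conditions <- function(panel) {
  if (!is.data.frame(panel) || nrow(panel) == 0L) {
    stop_input("panel must be a non-empty data frame")
  }
  need <- c("condition", "pair", "of_percent")
  if (!all(need %in% names(panel))) {
    stop_input("panel needs columns condition, pair, of_percent")
  }
  if (any(panel$of_percent < 0 | panel$of_percent > 100)) {
    stop_input("of_percent must lie in [0, 100]")
  }
  agg <- do.call(rbind, lapply(split(panel, panel$condition), function(d) {
    data.frame(condition = d$condition[1],
               n_pairs = nrow(d),
               mean_of = mean(d$of_percent),
               sd_of = if (nrow(d) > 1L) stats::sd(d$of_percent) else 0,
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$mean_of, agg$condition), , drop = FALSE]
  rownames(agg) <- NULL
  sep <- character(0)
  if (nrow(agg) > 1L) {
    for (i in seq_len(nrow(agg) - 1L)) {
      tied <- (agg$mean_of[i + 1] - agg$mean_of[i]) <=
        (agg$sd_of[i] + agg$sd_of[i + 1])
      sep[i] <- if (tied) "~" else "<"
    }
  }
  ranking <- paste(rbind(agg$condition, c(sep, "")), collapse = " ")
  ranking <- trimws(ranking)
  structure(list(table = agg, ranking = ranking), class = "of_ranking")
}

#' Quantify OF fractions across a condition x pair trace panel
#'
#' Runs the full quantification pipeline on a set of DEER traces: per-trace
#' background fit and form-factor extraction, an unconstrained two-Gaussian
#' reference fit on the designated reference condition of each pair, and
#' constrained fits (OF mean/width frozen at the per-pair reference values)
#' for all other conditions.
#'
#' @param traces named list of `deer_trace` objects whose metadata carries
#'   `condition` and `pair` (e.g. the `traces` element returned by
#'   [simulate_condition_panel()]).
#' @param r_grid distance grid for the kernel.
#' @param reference condition label of the reference (vanadate-trapped)
#'   state.
#' @param t_start_frac background-fit window start, as a fraction of the
#'   trace length.
#' @param d_fix optional fixed background dimension (see
#'   [fit_background()]); default 3 (homogeneous bath).
#' @return data frame with columns `condition`, `pair`, `of_percent`.
#' @export
quantify_panel <- function(traces, r_grid = default_r_grid(),
                           reference = "ATP-Vi-Mg", t_start_frac = 0.5,
                           d_fix = 3) {
  if (!length(traces)) stop_input("no traces supplied")
  conds <- vapply(traces, function(tr) tr$meta$condition, character(1))
  pairs <- vapply(traces, function(tr) tr$meta$pair, character(1))
  if (!reference %in% conds) {
    stop_input("reference condition '", reference, "' not present in panel")
  }
  kern <- dipolar_kernel(traces[[1]]$t, r_grid)
  to_ff <- function(tr) {
    bg <- suppressWarnings(
      fit_background(tr, t_start = t_start_frac * max(tr$t), d_fix = d_fix))
    # weight residuals by B(t): white noise on the primary trace is
    # amplified ~1/B(t) by the background division
    list(ff = form_factor(tr, bg),
         w = stretched_background(tr$t, bg$k, bg$d, strict = FALSE))
  }
  refs <- list()
  for (i in which(conds == reference)) {
    x <- to_ff(traces[[i]])
    refs[[pairs[i]]] <- fit_reference_state(x$ff, kern, weights = x$w)
  }
  out <- NULL
  for (i in seq_along(traces)) {
    ref <- refs[[pairs[i]]]
    if (is.null(ref)) stop_input("no reference trace for pair ", pairs[i])
    model <- if (conds[i] == reference) ref else {
      x <- to_ff(traces[[i]])
      fit_constrained_state(x$ff, kern, ref, weights = x$w)
    }
    out <- rbind(out, data.frame(condition = conds[i], pair = pairs[i],
                                 of_percent = of_fraction(model),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.two_gaussian_model <- function(x, ...) {
  cat(sprintf(
    "<two_gaussian_model>%s OF: mu = %.3f nm, sigma = %.3f nm, area = %.3f | 2nd: mu = %.3f, sigma = %.3f, area = %.3f\n",
    if (x$fixed_of) " [OF fixed]" else "",
    x$mu_of, x$sigma_of, x$area_of, x$mu_2, x$sigma_2, x$area_2))
  invisible(x)
}

#' @export
print.of_ranking <- function(x, ...) {
  cat("<of_ranking>", x$ranking, "\n")
  print(x$table)
  invisible(x)
}
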