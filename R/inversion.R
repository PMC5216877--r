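# Background correction and model-free Tikhonov inversion of DEER traces.

#' Fit the intermolecular background of a primary DEER trace
#'
#' Least-squares fit of `(1 - lambda) exp(-k t^(d/3))` to the tail of the
#' trace (`t >= t_start`), with the homogeneous dimension `d` bounded to
#' \[1.5, 3\]. At long times the intramolecular dipolar oscillation has
#' decayed, so the tail is described by the scaled background alone; the
#' fitted scale yields the modulation depth.
#'
#' For samples with a three-dimensional homogeneous spin bath (detergent
#' solution), `d_fix = 3` removes the decay-dimension degree of freedom;
#' this is recommended whenever broad or long-distance components make the
#' smooth part of the dipolar decay hard to distinguish from a
#' stretched-exponential with free `d`.
#'
#' @param trace a `deer_trace`.
#' @param t_start start of the fit window in us; default 40% of the trace
#'   length.
#' @param d_fix optional fixed homogeneous dimension (e.g. 3); `NULL`
#'   (default) fits `d` freely within \[1.5, 3\].
#' @return a `background_model` with fitted `k`, `d`, `lambda`.
#' @export
fit_background <- function(trace, t_start = 0.4 * max(trace$t),
                           d_fix = NULL) {
  stopifnot(inherits(trace, "deer_trace"))
  if (t_start <= 0 || t_start >= max(trace$t)) {
    stop_input("t_start must lie inside (0, max(t))")
  }
  sel <- trace$t >= t_start
  if (sum(sel) < 10L) stop_input("background fit window has fewer than 10 points")
  tt <- trace$t[sel]
  vv <- trace$v[sel]
  k0 <- max(1e-3, -log(max(vv[length(vv)], 0.05)) / max(tt))
  if (is.null(d_fix)) {
    fit <- minpack.lm::nls.lm(
      par = c(lam = 0.3, k = k0, d = 2.8),
      lower = c(lam = 0, k = 0, d = 1.5),
      upper = c(lam = 0.999, k = 100, d = 3),
      fn = function(p) vv - (1 - p[["lam"]]) * exp(-p[["k"]] * tt^(p[["d"]] / 3)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- fit$par
  } else {
    if (d_fix < 1.5 || d_fix > 3) stop_input("d_fix must lie in [1.5, 3]")
    fit <- minpack.lm::nls.lm(
      par = c(lam = 0.3, k = k0),
      lower = c(lam = 0, k = 0), upper = c(lam = 0.999, k = 100),
      fn = function(p) vv - (1 - p[["lam"]]) * exp(-p[["k"]] * tt^(d_fix / 3)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- c(fit$par, d = d_fix)
  }
  if (cf[["lam"]] < 0.05 || cf[["lam"]] > 0.95) {
    warning(sprintf("fitted modulation depth %.3f outside (0.05, 0.95); unphysical",
                    cf[["lam"]]), call. = FALSE)
  }
  background_model(k = cf[["k"]], d = cf[["d"]], lambda = cf[["lam"]],
                   strict = FALSE)
}

#' Background-correct a DEER trace into a form factor
#'
#' Divides the trace by the fitted background and renormalizes so
#' `F(0) = 1`. The modulation depth of the background model is carried
#' forward for later extraction of the dipolar part.
#'
#' @param trace a `deer_trace`.
#' @param bg a `background_model` (e.g. from [fit_background()]).
#' @return a `form_factor` object.
#' @export
form_factor <- function(trace, bg) {
  stopifnot(inherits(trace, "deer_trace"), inherits(bg, "background_model"))
  b <- stretched_background(trace$t, bg$k, bg$d, strict = FALSE)
  f <- trace$v / b
  f <- f / f[1]
  form_factor_signal(trace$t, f, lambda = bg$lambda, meta = trace$meta)
}

# second-difference (curvature) operator, (n-2) x n
second_difference_operator <- function(n) {
  if (n < 3L) stop_input("need at least 3 grid points")
  L <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) L[i, i + 0:2] <- c(1, -2, 1)
  L
}

#' Model-free Tikhonov inversion of a form factor
#'
#' Extracts the dipolar part `S(t) = (F(t) - (1 - lambda)) / lambda` and
#' solves the non-negative Tikhonov problem
#' \deqn{P = argmin_{P \ge 0} ||K_w P - S||^2 + \alpha^2 ||L_2 P||^2}
#' where `K_w` is the dipolar kernel with trapezoidal quadrature weights
#' folded in and `L_2` the second-difference operator penalizing curvature
#' of the distribution. Non-negativity is enforced exactly by a
#' Lawson-Hanson active-set solve of the stacked augmented system (not by
#' clipping, which would distort the areas used for population fractions).
#' The returned distribution is area-normalized.
#'
#' @param ff a `form_factor`.
#' @param kern a `kernel_matrix` whose time grid matches `ff`.
#' @param alpha positive regularization parameter.
#' @param weights optional per-point residual weights. White noise on the
#'   primary trace becomes heteroscedastic on the form factor (amplified by
#'   1/B(t) at late times); weighting the data residual by the fitted
#'   background restores homoscedasticity and stabilizes the inversion.
#' @return object of class `tikhonov_result`: fields `dist`
#'   (`distance_distribution`), `alpha`, `residual_norm` (`||K_w P - S||`
#'   before normalization, unweighted), `smoothness_norm` (`||L_2 P||`).
#' @export
tikhonov_invert <- function(ff, kern, alpha, weights = NULL) {
  stopifnot(inherits(ff, "form_factor"), inherits(kern, "kernel_matrix"))
  if (!is.finite(alpha) || alpha <= 0) stop_input("alpha must be > 0")
  if (length(kern$t) != length(ff$t) ||
      max(abs(kern$t - ff$t)) > 1e-9) {
    stop_input("kernel time grid does not match form factor")
  }
  if (ff$lambda <= 0) stop_input("form factor has zero modulation depth")
  s <- (ff$f - (1 - ff$lambda)) / ff$lambda
  w <- trapz_weights(kern$r)
  Kw <- sweep(kern$K, 2L, w, `*`)
  L <- second_difference_operator(length(kern$r))
  if (is.null(weights)) weights <- rep(1, length(s))
  if (length(weights) != length(s) || any(weights <= 0)) {
    stop_input("weights must be positive, one per time point")
  }
  A <- rbind(weights * Kw, alpha * L)
  b <- c(weights * s, rep(0, nrow(L)))
  p <- pracma::lsqnonneg(A, b)$x
  p[p < 0] <- 0  # guard against solver round-off at active bounds
  residual_norm <- sqrt(sum((as.vector(Kw %*% p) - s)^2))
  smoothness_norm <- sqrt(sum((as.vector(L %*% p))^2))
  dist <- distance_distribution(kern$r, p, normalize = TRUE)
  structure(list(dist = dist, alpha = alpha,
                 residual_norm = residual_norm,
                 smoothness_norm = smoothness_norm),
            class = "tikhonov_result")
}

#' L-curve selection of the Tikhonov regularization parameter
#'
#' Runs the inversion along a log-spaced grid of `alpha` values and returns
#' the L-curve corner: the `alpha` maximizing the (Menger) curvature of the
#' parametric curve `(log residual_norm, log smoothness_norm)`. If the curve
#' is degenerate (no structure in the data, so the residual barely changes
#' with `alpha`, or curvature cannot be evaluated), the median `alpha` of
#' the grid is returned with a warning.
#'
#' @param ff a `form_factor`.
#' @param kern matching `kernel_matrix`.
#' @param alpha_grid positive, increasing, log-spaced grid of at least 20
#'   candidate values.
#' @param weights optional per-point residual weights (see
#'   [tikhonov_invert()]).
#' @return selected `alpha` (scalar), with attribute `"lcurve"` holding the
#'   per-alpha residual and smoothness norms.
#' @export
select_alpha <- function(ff, kern,
                         alpha_grid = 10^seq(-4, 2, length.out = 25),
                         weights = NULL) {
  if (length(alpha_grid) < 20L) stop_input("alpha_grid needs >= 20 points")
  if (any(alpha_grid <= 0) || any(diff(alpha_grid) <= 0)) {
    stop_input("alpha_grid must be positive and increasing")
  }
  res <- lapply(alpha_grid, function(a)
    tikhonov_invert(ff, kern, a, weights = weights))
  rho <- vapply(res, `[[`, numeric(1), "residual_norm")
  eta <- vapply(res, `[[`, numeric(1), "smoothness_norm")
  lc <- data.frame(alpha = alpha_grid, residual_norm = rho,
                   smoothness_norm = eta)
  x <- log(pmax(rho, .Machine$double.xmin))
  y <- log(pmax(eta, .Machine$double.xmin))
  # a structureless (pure-noise) form factor leaves the residual norm
  # nearly independent of alpha: there is no corner to find
  degenerate <- diff(range(x)) < 0.1 || diff(range(y)) < 1e-2
  kappa <- rep(NA_real_, length(alpha_grid))
  if (!degenerate) {
    # wide three-point stencil damps point-to-point noise on the curve;
    # end points are excluded as corner candidates
    h <- 2L
    for (i in (1L + h):(length(alpha_grid) - h)) {
      kappa[i] <- menger_curvature(x[i - h], y[i - h], x[i], y[i],
                                   x[i + h], y[i + h])
    }
  }
  if (degenerate || all(!is.finite(kappa) | kappa <= 0, na.rm = TRUE)) {
    warning("degenerate L-curve (no corner); falling back to median alpha",
            call. = FALSE)
    a <- stats::median(alpha_grid)
  } else {
    a <- alpha_grid[which.max(replace(kappa, !is.finite(kappa), -Inf))]
  }
  attr(a, "lcurve") <- lc
  a
}

# signed Menger curvature of three points in the plane
menger_curvature <- function(x1, y1, x2, y2, x3, y3) {
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  d12 <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d23 <- sqrt((x3 - x2)^2 + (y3 - y2)^2)
  d13 <- sqrt((x3 - x1)^2 + (y3 - y1)^2)
  den <- d12 * d23 * d13
  if (den == 0) return(NA_real_)
  area2 / den
}

#' @export
print.tikhonov_result <- function(x, ...) {
  cat(sprintf("<tikhonov_result> alpha = %.4g, ||KP - S|| = %.4g, ||L2 P|| = %.4g\n",
              x$alpha, x$residual_norm, x$smoothness_norm))
  print(x$dist)
  invisible(x)
}
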