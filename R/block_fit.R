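# Exponential block-model fits.
#
# Penetration block:  f(t) = A (1 - exp(-t / tau_PB)); A is the average
# number of sperm that still penetrate a fertilized oocyte before its ZP
# becomes impermeable, tau_PB the block time constant.  For fixed tau the
# model is linear in A, so the least-squares problem is profiled down to a
# 1-D minimisation in tau (coarse log-grid + stats::optimize); this is
# deterministic and exact to machine precision on noiseless curves.
#
# Fusion block:  f(t) = a (1 - exp(-t / tau_FB)) with the amplitude a held
# fixed at the observed number of extra fusions per fertilized oocyte.
#
# Confidence intervals are percentile intervals from refitting each
# bootstrap resample curve stored in the count_curve object.

tau_search_grid <- function(t_max, n = 60L) {
  exp(seq(log(min(0.5, t_max / 10)), log(10 * t_max), length.out = n))
}

# profiled RSS of A(1 - exp(-t/tau)) on (t, y); returns c(rss, A)
pb_profile <- function(tau, t, y) {
  g <- 1 - exp(-t / tau)
  denom <- sum(g * g)
  A <- if (denom > 0) max(0, sum(g * y) / denom) else 0
  c(sum((y - A * g)^2), A)
}

fit_saturation_tau <- function(t, y, rss_fun, t_max) {
  grid <- tau_search_grid(t_max)
  rss_g <- vapply(grid, function(tau) rss_fun(tau)[1L], numeric(1L))
  i <- which.min(rss_g)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(ltau) rss_fun(exp(ltau))[1L],
                         lower = log(lo), upper = log(hi), tol = 1e-12)
  tau <- exp(opt$minimum)
  list(tau = tau, rss = opt$objective,
       at_lower = i == 1L && opt$minimum <= log(lo) + 1e-6,
       at_upper = i == length(grid) && opt$minimum >= log(hi) - 1e-6)
}

#' Fit the exponential penetration-block model
#'
#' Unweighted least squares of `f(t) = A (1 - exp(-t / tau_PB))` on the mean
#' count curve of penetrations after the first fertilization.  `A` is the
#' plateau (sperm/oocyte) and `tau_PB` the penetration-block time constant
#' (minutes); the implied initial penetration rate is `A / tau_PB * 60`
#' sperm/oocyte/hour, the derivative of the fit at time zero.  95% CIs are
#' percentile intervals over refits of the bootstrap resample curves stored
#' in the input.
#'
#' @param curve a [count_curve()] with `align = "first_fusion"` and
#'   `counted = "penetration"` (checked unless `check = FALSE`).
#' @param check verify the curve's alignment/counted metadata.
#' @return an object of class `"penetration_block_fit"`: list with `A`,
#'   `tau_PB`, `initial_rate`, `A_ci`, `tau_ci`, `rate_ci`, `rss`,
#'   `tau_identified` (FALSE for a degenerate all-zero curve), `fitted`.
#' @export
fit_penetration_block <- function(curve, check = TRUE) {
  stopifnot(inherits(curve, "count_curve"))
  if (check && !(curve$align == "first_fusion" &&
                 curve$counted == "penetration"))
    stop_fk("fit_penetration_block() expects a first_fusion-aligned penetration curve")
  t <- curve$grid; y <- curve$mean
  if (length(t) < 3L) stop_fk("curve has too few grid points to fit")
  fit1 <- function(y) {
    if (max(y) <= 0) return(c(A = 0, tau = NA_real_, rss = sum(y^2)))
    f <- fit_saturation_tau(t, y, function(tau) pb_profile(tau, t, y),
                            max(t))
    c(A = pb_profile(f$tau, t, y)[2L], tau = f$tau, rss = f$rss)
  }
  est <- fit1(y)
  tau_identified <- !is.na(est[["tau"]])
  boot <- curve$boot_curves
  cis <- matrix(NA_real_, 2L, 3L)
  if (!is.null(boot) && nrow(boot) >= 20L && tau_identified) {
    bs <- t(apply(boot, 1L, fit1))
    rate_b <- bs[, "A"] / bs[, "tau"] * 60
    cis <- vapply(list(bs[, "A"], bs[, "tau"], rate_b),
                  stats::quantile, numeric(2L), probs = c(0.025, 0.975),
                  na.rm = TRUE, names = FALSE)
  }
  A <- est[["A"]]; tau <- est[["tau"]]
  structure(list(
    A = A, tau_PB = tau,
    initial_rate = if (tau_identified) A / tau * 60 else 0,
    A_ci = cis[, 1L], tau_ci = cis[, 2L], rate_ci = cis[, 3L],
    rss = est[["rss"]], tau_identified = tau_identified,
    fitted = if (tau_identified) A * (1 - exp(-t / tau)) else rep(0, length(t)),
    grid = t), class = "penetration_block_fit")
}

#' @export
print.penetration_block_fit <- function(x, ...) {
  cat(sprintf("Penetration-block fit: A = %.3f sperm/oocyte", x$A))
  if (!all(is.na(x$A_ci)))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$A_ci[1L], x$A_ci[2L]))
  if (x$tau_identified) {
    cat(sprintf(", tau_PB = %.1f min", x$tau_PB))
    if (!all(is.na(x$tau_ci)))
      cat(sprintf(" (95%% CI %.1f-%.1f)", x$tau_ci[1L], x$tau_ci[2L]))
    cat(sprintf("\n  implied initial rate %.2f sperm/oocyte/h\n",
                x$initial_rate))
  } else cat(", tau_PB unidentified (flat curve)\n")
  invisible(x)
}

#' Fit the fixed-amplitude fusion-block model
#'
#' One-parameter least squares of `f(t) = amplitude (1 - exp(-t / tau_FB))`
#' on the mean curve of extra fusions after the first fertilization, with
#' the amplitude held fixed at its data-determined value (number of extra
#' fusions per fertilized oocyte), never free.
#'
#' @param curve a [count_curve()] with `align = "first_fusion"` and
#'   `counted = "fusion"` (checked unless `check = FALSE`).
#' @param amplitude extra fusions per fertilized oocyte (> 0).
#' @param check verify the curve's alignment/counted metadata.
#' @return an object of class `"fusion_block_fit"`: list with `amplitude`,
#'   `tau_FB`, `tau_ci`, `rss`, `tau_at_boundary`, `fitted`.
#' @export
fit_fusion_block <- function(curve, amplitude, check = TRUE) {
  stopifnot(inherits(curve, "count_curve"))
  if (check && !(curve$align == "first_fusion" && curve$counted == "fusion"))
    stop_fk("fit_fusion_block() expects a first_fusion-aligned fusion curve")
  if (!is_scalar_num(amplitude) || amplitude <= 0)
    stop_fk("amplitude must be a positive number (got %s)",
            format(amplitude))
  t <- curve$grid; y <- curve$mean
  if (length(t) < 3L) stop_fk("curve has too few grid points to fit")
  fit1 <- function(y)
    fit_saturation_tau(t, y, function(tau)
      sum((y - amplitude * (1 - exp(-t / tau)))^2), max(t))
  f <- fit1(y)
  boot <- curve$boot_curves
  tau_ci <- c(NA_real_, NA_real_)
  if (!is.null(boot) && nrow(boot) >= 20L) {
    taus <- apply(boot, 1L, function(yb) fit1(yb)$tau)
    tau_ci <- stats::quantile(taus, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
  }
  structure(list(amplitude = amplitude, tau_FB = f$tau, tau_ci = tau_ci,
                 rss = f$rss, tau_at_boundary = f$at_lower || f$at_upper,
                 fitted = amplitude * (1 - exp(-t / f$tau)), grid = t),
            class = "fusion_block_fit")
}

#' @export
print.fusion_block_fit <- function(x, ...) {
  cat(sprintf(
    "Fusion-block fit: amplitude %.4f extra fusions/oocyte (fixed), tau_FB = %.2f min",
    x$amplitude, x$tau_FB))
  if (!all(is.na(x$tau_ci)))
    cat(sprintf(" (95%% CI %.2f-%.2f)", x$tau_ci[1L], x$tau_ci[2L]))
  if (x$tau_at_boundary) cat("  [at search boundary]")
  cat("\n")
  invisible(x)
}

#' Fit a constant penetration rate
#'
#' Least-squares slope through the origin of a cumulative penetration-count
#' curve, reported in sperm/oocyte/hour.  This is the baseline
#' zona-pellucida permeability estimated from oocytes that were penetrated
#' but never fertilized, where no penetration block is triggered.
#'
#' @param curve a [count_curve()] (typically the unfertilized cohort,
#'   aligned to the first penetration or not aligned).
#' @return an object of class `"constant_rate_fit"`: list with `rate`
#'   (sperm/oocyte/hour), `rate_ci`, `rss`.
#' @export
fit_constant_rate <- function(curve) {
  stopifnot(inherits(curve, "count_curve"))
  t <- curve$grid; y <- curve$mean
  if (length(t) < 2L) stop_fk("need at least 2 grid points")
  slope <- function(y) if (sum(t * t) > 0) sum(t * y) / sum(t * t) else 0
  b <- slope(y)
  boot <- curve$boot_curves
  ci <- c(NA_real_, NA_real_)
  if (!is.null(boot) && nrow(boot) >= 20L)
    ci <- stats::quantile(apply(boot, 1L, slope), c(0.025, 0.975),
                          names = FALSE) * 60
  structure(list(rate = b * 60, rate_ci = ci,
                 rss = sum((y - b * t)^2)), class = "constant_rate_fit")
}

#' @export
print.constant_rate_fit <- function(x, ...) {
  cat(sprintf("Constant penetration rate: %.3f sperm/oocyte/h", x$rate))
  if (!all(is.na(x$rate_ci)))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$rate_ci[1L], x$rate_ci[2L]))
  cat("\n")
  invisible(x)
}

#' Initial penetration rate implied by a penetration-block fit
#'
#' The derivative at time zero of `A (1 - exp(-t / tau_PB))` is
#' `A / tau_PB`, converted to sperm/oocyte/hour.
#'
#' @param A either a `"penetration_block_fit"` object or the plateau `A`
#'   (sperm/oocyte).
#' @param tau_PB penetration-block time constant in minutes (ignored when
#'   `A` is a fit object).
#' @return implied initial rate in sperm/oocyte/hour.
#' @examples
#' implied_initial_rate(0.97, 48.3)  # ~1.21 sperm/oocyte/h
#' @export
implied_initial_rate <- function(A, tau_PB = NULL) {
  if (inherits(A, "penetration_block_fit")) {
    tau_PB <- A$tau_PB
    A <- A$A
  }
  if (!is_scalar_num(A) || A < 0) stop_fk("A must be a non-negative number")
  if (A == 0) return(0)
  if (!is_scalar_num(tau_PB) || tau_PB <= 0)
    stop_fk("tau_PB must be positive")
  A / tau_PB * 60
}
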