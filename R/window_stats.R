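# Uniform-within-window realization engine and cumulative event-count curves.
#
# Each interval-censored event is assumed to have occurred at a uniformly
# distributed time within its window; curves are Monte Carlo averages over
# many such realizations, with 95% confidence bands from a bootstrap over
# oocytes that shares the window realizations across resamples.

#' Draw uniform realizations of all event times of a chronogram
#'
#' Every penetration and fusion time is drawn uniformly within its window,
#' independently across sperm and realizations.  For a fused sperm whose
#' windows overlap, the (penetration, fusion) pair is drawn uniformly on the
#' part of the window rectangle where fusion >= penetration (by rejection
#' from the product uniform).
#'
#' @param x a [chronogram()].
#' @param n number of realizations.
#' @param seed optional integer seed; the same seed reproduces the same
#'   realizations and leaves the caller's RNG state untouched.
#' @return an object of class `"chron_realization"`: a list with the sperm
#'   table and `pen`, `fus` matrices of dimension `n_sperm x n` (`fus` is
#'   `NA` for non-fused sperm).
#' @export
realize <- function(x, n = 1L, seed = NULL) {
  stopifnot(inherits(x, "chronogram"), n >= 1L)
  s <- x$sperm
  draw <- function() {
    ns <- nrow(s)
    pen <- matrix(numeric(0), 0L, n)
    fus <- matrix(numeric(0), 0L, n)
    if (ns) {
      pen <- matrix(stats::runif(ns * n, s$pen_lower, s$pen_upper), ns, n)
      fus <- matrix(NA_real_, ns, n)
      fi <- which(s$fused)
      if (length(fi)) {
        fus[fi, ] <- matrix(stats::runif(length(fi) * n, s$fus_lower[fi],
                                         s$fus_upper[fi]), length(fi), n)
        # enforce fusion >= penetration where the windows overlap
        for (i in fi) {
          if (s$fus_upper[i] <= s$pen_lower[i]) {
            # single feasible point: both at the shared boundary
            pen[i, ] <- s$pen_lower[i]
            fus[i, ] <- s$fus_upper[i]
            next
          }
          if (s$fus_lower[i] >= s$pen_upper[i]) next  # constraint inactive
          bad <- which(fus[i, ] < pen[i, ])
          guard <- 0L
          while (length(bad)) {
            pen[i, bad] <- stats::runif(length(bad), s$pen_lower[i],
                                        s$pen_upper[i])
            fus[i, bad] <- stats::runif(length(bad), s$fus_lower[i],
                                        s$fus_upper[i])
            bad <- bad[fus[i, bad] < pen[i, bad]]
            guard <- guard + 1L
            if (guard > 10000L)
              stop_fk("sperm %s/%s: feasible region of the joint window is empty",
                      s$oocyte_id[i], s$sperm_id[i])
          }
        }
      }
    }
    list(pen = pen, fus = fus)
  }
  m <- if (is.null(seed)) draw() else
    with_preserved_rng({ set.seed(as.integer(seed)); draw() })
  structure(list(sperm = s, oocytes = x$oocytes, pen = m$pen, fus = m$fus,
                 n = as.integer(n), seed = seed),
            class = "chron_realization")
}

# per-oocyte realization-averaged cumulative count curve.
# Returns matrix M [n_oocytes x n_grid]: M[o, g] = mean over realizations of
# the number of counted events with time in the counting set at grid point g.
# Linearity of the mean lets us pool event times over realizations, tabulate
# once per oocyte, and take a single cumulative sum.
oocyte_mean_curves <- function(r, align, counted, grid_step, t_max) {
  s <- r$sperm
  oo <- r$oocytes
  n_r <- r$n
  grid <- seq(0, t_max, by = grid_step)
  ng <- length(grid)
  M <- matrix(0, nrow(oo), ng,
              dimnames = list(oo$oocyte_id, NULL))
  for (o in seq_len(nrow(oo))) {
    idx <- which(s$oocyte_id == oo$oocyte_id[o])
    if (!length(idx)) next
    pen_o <- r$pen[idx, , drop = FALSE]
    fus_o <- r$fus[idx, , drop = FALSE]
    t_align <- switch(align,
      first_fusion = suppressWarnings(apply(fus_o, 2L, min, na.rm = TRUE)),
      first_penetration = apply(pen_o, 2L, min),
      none = rep(0, n_r))
    if (align == "first_fusion" && any(!is.finite(t_align)))
      stop_fk("oocyte %s has no fused sperm: cannot align to first fusion",
              oo$oocyte_id[o])
    if (counted == "pvs_occupancy") {
      rel_pen <- sweep(pen_o, 2L, t_align)
      rel_fus <- sweep(fus_o, 2L, t_align)
      M[o, ] <- (cum_mean_counts(rel_pen, grid_step, ng, n_r, at_zero = TRUE)
                 - cum_mean_counts(rel_fus, grid_step, ng, n_r,
                                   at_zero = TRUE))
    } else {
      ev <- if (counted == "penetration") pen_o else fus_o
      rel <- sweep(ev, 2L, t_align)
      # events at or before the alignment event are excluded when aligning
      # to an index event (e.g. penetrations counted "after fertilization")
      at_zero <- align == "none"
      M[o, ] <- cum_mean_counts(rel, grid_step, ng, n_r, at_zero = at_zero)
    }
  }
  list(grid = grid, M = M)
}

# mean (over n_r realizations) cumulative count of relative event times on a
# uniform grid 0, step, ..., (ng-1)*step.  at_zero = TRUE counts events with
# rel <= 0 at every grid point (cumulative from the origin); otherwise only
# events with rel > 0 count.
cum_mean_counts <- function(rel, step, ng, n_r, at_zero) {
  rel <- rel[!is.na(rel)]
  base <- if (at_zero) sum(rel <= 0) else 0
  pos <- rel[rel > 0 & rel <= (ng - 1L) * step]
  h <- tabulate(ceiling(pos / step), nbins = ng - 1L)
  (base + c(0, cumsum(h))) / n_r
}

#' Mean cumulative event-count curve with bootstrap confidence band
#'
#' Estimates the average cumulative number of events per oocyte as a function
#' of time since an alignment event, propagating the interval-censoring
#' uncertainty by averaging over uniform window realizations.  The 95%
#' confidence band is a percentile (2.5/97.5) bootstrap over oocytes, each
#' resample evaluated on the same set of window realizations.
#'
#' @param x a [chronogram()].
#' @param align alignment event: `"first_fusion"` (requires every oocyte to
#'   be fertilized), `"first_penetration"`, or `"none"` (absolute time from
#'   insemination).  The alignment time is realized per realization.
#' @param counted `"penetration"`, `"fusion"`, or `"pvs_occupancy"` (realized
#'   penetrants not yet fused at each grid time).  When aligning to an index
#'   event, penetration/fusion events at or before it are excluded — e.g.
#'   with `align = "first_fusion"` the curve counts penetrations after
#'   fertilization, and fusions beyond the first.
#' @param n_realizations number of window realizations (default 1000).
#' @param n_boot number of bootstrap resamples of oocytes (default 1000).
#' @param seed optional integer seed (realizations + bootstrap).
#' @param grid_step grid step in minutes (default 1, the observation
#'   resolution).
#' @param t_max end of the grid, minutes after the alignment event; default
#'   the largest realizable lag `horizon - min(alignment window lower)`.
#' @return an object of class `"count_curve"`: list with `grid`, `mean`,
#'   `ci_low`, `ci_high`, `n_oocytes`, `n_realizations`, `n_boot`, `align`,
#'   `counted`, the per-oocyte realization-averaged curves `oocyte_curves`,
#'   and the bootstrap curves `boot_curves` (used by the model-fitting
#'   functions to propagate uncertainty).
#' @examples
#' ch <- chronogram(data.frame(
#'   oocyte_id = "o1", sperm_id = c("s1", "s2"),
#'   pen_lower = c(50, 50), pen_upper = c(60, 70),
#'   fus_lower = c(60, NA), fus_upper = c(60, NA)))
#' cc <- count_curve(ch, "first_fusion", "penetration",
#'                   n_realizations = 200, n_boot = 50, seed = 1)
#' cc$mean[cc$grid == 10]  # ~0.5: P(pen in (60, 70]) under U[50, 70]
#' @export
count_curve <- function(x, align = c("first_fusion", "first_penetration",
                                     "none"),
                        counted = c("penetration", "fusion",
                                    "pvs_occupancy"),
                        n_realizations = 1000L, n_boot = 1000L, seed = NULL,
                        grid_step = 1, t_max = NULL) {
  stopifnot(inherits(x, "chronogram"))
  align <- match.arg(align)
  counted <- match.arg(counted)
  if (nrow(x$oocytes) == 0L) stop_fk("empty chronogram")
  if (n_realizations < 1L) stop_fk("n_realizations must be >= 1")
  if (align == "first_fusion" && any(x$oocytes$fate != "fertilized"))
    stop_fk("align = 'first_fusion' requires every oocyte to be fertilized (use subset_oocytes())")
  if (align == "first_penetration" && any(x$oocytes$n_sperm == 0L))
    stop_fk("align = 'first_penetration' requires every oocyte to be penetrated")

  if (is.null(t_max)) {
    t_max <- switch(align,
      none = max(x$oocytes$horizon),
      first_penetration = ,
      first_fusion = {
        col <- if (align == "first_fusion") "fus_lower" else "pen_lower"
        amin <- vapply(seq_len(nrow(x$oocytes)), function(o) {
          sdf <- x$sperm[x$sperm$oocyte_id == x$oocytes$oocyte_id[o], ]
          v <- if (align == "first_fusion") sdf[[col]][sdf$fused] else
            sdf[[col]]
          min(v)
        }, numeric(1L))
        max(x$oocytes$horizon - amin)
      })
    t_max <- max(t_max, grid_step)
  }

  seeds <- if (is.null(seed)) c(NA, NA) else derive_seeds(seed, 2L)
  r <- realize(x, n_realizations, seed = if (is.null(seed)) NULL else
    seeds[1L])
  oc <- oocyte_mean_curves(r, align, counted, grid_step, t_max)
  M <- oc$M
  n_oo <- nrow(M)
  mean_curve <- colMeans(M)

  boot_fun <- function() {
    B <- matrix(0, n_boot, ncol(M))
    for (b in seq_len(n_boot)) {
      take <- sample.int(n_oo, n_oo, replace = TRUE)
      B[b, ] <- colMeans(M[take, , drop = FALSE])
    }
    B
  }
  Bm <- if (n_boot >= 1L) {
    if (is.null(seed)) boot_fun() else
      with_preserved_rng({ set.seed(as.integer(seeds[2L])); boot_fun() })
  } else NULL
  if (!is.null(Bm)) {
    qs <- apply(Bm, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    ci_low <- pmin(qs[1L, ], mean_curve)
    ci_high <- pmax(qs[2L, ], mean_curve)
  } else {
    ci_low <- ci_high <- rep(NA_real_, length(mean_curve))
  }

  structure(list(grid = oc$grid, mean = mean_curve, ci_low = ci_low,
                 ci_high = ci_high, n_oocytes = n_oo,
                 n_realizations = as.integer(n_realizations),
                 n_boot = as.integer(n_boot), align = align,
                 counted = counted, grid_step = grid_step,
                 oocyte_curves = M, boot_curves = Bm, seed = seed),
            class = "count_curve")
}

#' @export
print.count_curve <- function(x, ...) {
  cat(sprintf(
    "Count curve: %s aligned to %s; %d oocytes, %d realizations, %d bootstrap resamples\n",
    x$counted, x$align, x$n_oocytes, x$n_realizations, x$n_boot))
  cat(sprintf("  grid: 0..%g min (step %g); final mean %.3f [%.3f, %.3f]\n",
              max(x$grid), x$grid_step, x$mean[length(x$mean)],
              x$ci_low[length(x$mean)], x$ci_high[length(x$mean)]))
  invisible(x)
}

#' @export
as.data.frame.count_curve <- function(x, ...) {
  data.frame(dt_min = x$grid, mean = x$mean, ci_low = x$ci_low,
             ci_high = x$ci_high)
}

#' @export
plot.count_curve <- function(x, ...) {
  args <- list(...)
  ylim <- args$ylim %||% range(c(x$ci_low, x$ci_high, x$mean), na.rm = TRUE)
  plot(x$grid, x$mean, type = "s",
       xlab = sprintf("minutes after %s", gsub("_", " ", x$align)),
       ylab = sprintf("%s per oocyte", gsub("_", " ", x$counted)),
       ylim = ylim)
  if (!all(is.na(x$ci_low))) {
    graphics::lines(x$grid, x$ci_low, lty = 3)
    graphics::lines(x$grid, x$ci_high, lty = 3)
  }
  invisible(x)
}

#' Penetration-to-fusion delay of fertilizing spermatozoa
#'
#' Estimates the probability that a fused spermatozoon had fused with the
#' oolemma within a lag `dt` of its penetration into the PVS, together with
#' the mean penetration-to-fusion delay, by averaging over uniform window
#' realizations.  The 95% CI of the mean delay is a percentile bootstrap over
#' oocytes (delays averaged within oocyte first).
#'
#' @param x a [chronogram()] containing at least one fused sperm.
#' @param n_realizations number of window realizations.
#' @param n_boot bootstrap resamples of oocytes.
#' @param seed optional integer seed.
#' @param grid_step grid step in minutes.
#' @return list with `grid`, `prob` (P(delay <= dt)), `mean_delay`,
#'   `delay_sd` (between-sperm SD, averaged over realizations),
#'   `mean_delay_ci`, `n_sperm`; class `"fusion_delay_curve"`.
#' @export
fusion_delay_curve <- function(x, n_realizations = 1000L, n_boot = 1000L,
                               seed = NULL, grid_step = 1) {
  stopifnot(inherits(x, "chronogram"))
  fi <- which(x$sperm$fused)
  if (!length(fi))
    stop_fk("fusion_delay_curve() requires at least one fused sperm")
  seeds <- if (is.null(seed)) c(NA, NA) else derive_seeds(seed, 2L)
  r <- realize(x, n_realizations, seed = if (is.null(seed)) NULL else
    seeds[1L])
  delays <- r$fus[fi, , drop = FALSE] - r$pen[fi, , drop = FALSE]
  t_max <- max(max(delays), grid_step)
  grid <- seq(0, t_max, by = grid_step)
  # P(delay <= dt), averaged over sperm and realizations
  h <- tabulate(ceiling(pmax(delays, .Machine$double.eps) / grid_step),
                nbins = length(grid) - 1L)
  prob <- (sum(delays <= 0) + c(0, cumsum(h))) / length(delays)

  oo_of <- x$sperm$oocyte_id[fi]
  oo_levels <- unique(oo_of)
  per_oocyte <- vapply(oo_levels, function(oid)
    mean(delays[oo_of == oid, , drop = FALSE]), numeric(1L))
  mean_delay <- mean(per_oocyte)
  delay_sd <- mean(apply(delays, 2L, stats::sd))
  ci <- if (n_boot >= 1L && length(per_oocyte) > 1L) {
    boot_fun <- function()
      replicate(n_boot, mean(per_oocyte[sample.int(length(per_oocyte),
                                                   replace = TRUE)]))
    bm <- if (is.null(seed)) boot_fun() else
      with_preserved_rng({ set.seed(as.integer(seeds[2L])); boot_fun() })
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  } else c(mean_delay, mean_delay)
  structure(list(grid = grid, prob = prob, mean_delay = mean_delay,
                 delay_sd = delay_sd, mean_delay_ci = ci,
                 n_sperm = length(fi), n_realizations = n_realizations),
            class = "fusion_delay_curve")
}

#' @export
print.fusion_delay_curve <- function(x, ...) {
  cat(sprintf(
    "Penetration-to-fusion delay: %.1f min (95%% CI %.1f-%.1f), between-sperm SD %.1f min; %d fused sperm\n",
    x$mean_delay, x$mean_delay_ci[1L], x$mean_delay_ci[2L], x$delay_sd,
    x$n_sperm))
  invisible(x)
}
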