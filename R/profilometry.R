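#' Vertically averaged thickness profile
#'
#' Column-wise mean of a thickness map over a band of rows (default 100,
#' centred), the standard way to beat noise down before fitting fiber
#' profiles.
#'
#' @param map A [thickness_map()] or plain matrix.
#' @param n_rows Band height in rows (>= 1).
#' @param y_center Centre row of the band (default the map centre).
#' @return A tibble of class `thickness_profile` with columns `x_mm`,
#'   `thickness_mm`.
#' @export
extract_profile <- function(map, n_rows = 100L, y_center = NULL) {
  pixel <- attr(map, "pixel_mm") %||% 1
  m <- unclass(map)
  if (is.null(y_center)) y_center <- (nrow(m) + 1L) %/% 2L
  half_lo <- (n_rows - 1L) %/% 2L
  rows <- seq(y_center - half_lo, length.out = n_rows)
  if (min(rows) < 1L || max(rows) > nrow(m))
    stop("row band extends outside the map")
  prof <- colMeans(m[rows, , drop = FALSE])
  structure(tibble(x_mm = map_x(ncol(m), pixel), thickness_mm = prof),
            pixel_mm = pixel,
            class = c("thickness_profile", class(tibble())))
}

#' Ideal fiber chord profile
#'
#' T(x) = d sqrt(1 - 4((x - x0)/d)^2) inside the support, 0 outside; the sum
#' over several fibers if vectors are given.
#'
#' @param x_mm Positions, mm.
#' @param diameters_mm Fiber diameter(s), mm.
#' @param centers_mm Fiber centre(s), mm.
#' @return Thickness values, mm.
#' @export
fiber_theory <- function(x_mm, diameters_mm, centers_mm) {
  stopifnot(length(diameters_mm) == length(centers_mm))
  out <- numeric(length(x_mm))
  for (i in seq_along(diameters_mm)) {
    u <- (x_mm - centers_mm[i]) / diameters_mm[i]
    out <- out + ifelse(abs(u) <= 0.5,
                        diameters_mm[i] * sqrt(pmax(0, 1 - 4 * u^2)), 0)
  }
  out
}

#' Fit a semicircular fiber profile
#'
#' Nonlinear least-squares fit of T(x) = dT sqrt(1 - 4((x - x0)/dx)^2) (zero
#' outside |x - x0| > dx/2) to a measured profile, yielding two diameter
#' estimates: the apex value dT and the support width dx. Initialisation: x0
#' at the profile argmax, dT at the profile maximum, dx from the width above
#' 10% of the maximum; parameters are bounded to keep dT, dx positive and
#' below twice the window width. Background points (model 0) stay in the
#' residual - they carry the width information.
#'
#' @param profile A [extract_profile()] tibble (or any tibble with `x_mm`,
#'   `thickness_mm`).
#' @param window Optional `c(xmin, xmax)` in mm restricting the fit to one
#'   fiber.
#' @return A `fiber_fit` object: list with `d_t_mm`, `d_x_mm`, `x0_mm`,
#'   `r_squared`, `rmse_mm`, `n`, and the `minpack.lm` fit in `$fit`.
#' @export
fit_fiber <- function(profile, window = NULL) {
  d <- tibble(x = profile$x_mm, y = profile$thickness_mm)
  if (!is.null(window)) d <- dplyr::filter(d, .data$x >= window[1],
                                           .data$x <= window[2])
  if (nrow(d) < 5L) stop("fit window contains too few points")
  x0_init <- d$x[which.max(d$y)]
  dt_init <- max(d$y)
  if (dt_init <= 0) stop("profile has no positive apex in the window")
  above <- d$x[d$y > 0.1 * dt_init]
  dx_init <- max(diff(range(above)), 4 * min(diff(sort(unique(d$x)))))
  width <- diff(range(d$x))
  model <- function(p) {
    u <- (d$x - p[3]) / p[2]
    ifelse(abs(u) <= 0.5, p[1] * sqrt(pmax(0, 1 - 4 * u^2)), 0)
  }
  fit <- minpack.lm::nls.lm(
    par = c(dt = dt_init, dx = dx_init, x0 = x0_init),
    fn = function(p) d$y - model(p),
    lower = c(1e-6, 1e-6, min(d$x) - width),
    upper = c(2 * width, 2 * width, max(d$x) + width),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (fit$info %in% c(0, 9))
    stop(sprintf("fiber fit failed to converge: %s", fit$message))
  p <- fit$par
  resid <- d$y - model(p)
  ss_res <- sum(resid^2)
  ss_tot <- sum((d$y - mean(d$y))^2)
  structure(list(d_t_mm = unname(p[1]), d_x_mm = unname(p[2]),
                 x0_mm = unname(p[3]),
                 r_squared = 1 - ss_res / ss_tot,
                 rmse_mm = sqrt(ss_res / nrow(d)), n = nrow(d), fit = fit),
            class = "fiber_fit")
}

#' @export
print.fiber_fit <- function(x, ...) {
  cat(sprintf(paste0("<fiber_fit> dT = %.4f mm, dx = %.4f mm, x0 = %.4f mm, ",
                     "R^2 = %.4f, RMSE = %.4g mm\n"),
              x$d_t_mm, x$d_x_mm, x$x0_mm, x$r_squared, x$rmse_mm))
  invisible(x)
}

#' @export
tidy.fiber_fit <- function(x, ...) {
  tibble(term = c("d_t_mm", "d_x_mm", "x0_mm"),
         estimate = c(x$d_t_mm, x$d_x_mm, x$x0_mm))
}

#' @export
glance.fiber_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, rmse_mm = x$rmse_mm, n = x$n)
}

#' Root-mean-square difference against the ideal profile
#'
#' RMSD = sqrt( mean( (T(x_i) - Texp(x_i))^2 ) ) over all profile points,
#' where T is the ideal chord profile built from the given diameters and
#' centres.
#'
#' @param profile A profile tibble (`x_mm`, `thickness_mm`).
#' @param diameters_mm,centers_mm Ideal fiber parameters.
#' @return RMSD in mm.
#' @export
rmsd_vs_theory <- function(profile, diameters_mm, centers_mm) {
  theory <- fiber_theory(profile$x_mm, diameters_mm, centers_mm)
  sqrt(mean((profile$thickness_mm - theory)^2))
}

#' Signed percent diameter errors
#'
#' (d_fit - d_nominal) / d_nominal * 100 for both diameter estimates of a
#' [fit_fiber()] result.
#'
#' @param fit A `fiber_fit`.
#' @param nominal_mm Nominal diameter, mm (> 0).
#' @return Named vector `c(dd_t_pct, dd_x_pct)`.
#' @export
diameter_errors <- function(fit, nominal_mm) {
  if (nominal_mm <= 0) stop("nominal diameter must be positive")
  c(dd_t_pct = (fit$d_t_mm - nominal_mm) / nominal_mm * 100,
    dd_x_pct = (fit$d_x_mm - nominal_mm) / nominal_mm * 100)
}

#' Fiber diameter ratios
#'
#' d2/d1 and d3/d1 from the fitted apex diameters of three fibers (fiber 1
#' largest by convention). Ratios are scale-invariant and therefore robust to
#' the common multiplicative bias of polychromatic retrieval.
#'
#' @param fits List of three `fiber_fit` objects, fiber 1 first.
#' @return Named vector `c(r21, r31)`.
#' @export
diameter_ratios <- function(fits) {
  stopifnot(length(fits) == 3)
  dt <- vapply(fits, function(f) f$d_t_mm, numeric(1))
  c(r21 = dt[2] / dt[1], r31 = dt[3] / dt[1])
}

#' Thickness-map signal-to-noise ratio
#'
#' Mean thickness in a signal ROI divided by the standard deviation in an
#' equal-sized background ROI. A zero background standard deviation (e.g. a
#' noiseless simulation) returns `Inf`.
#'
#' @param map A [thickness_map()].
#' @param signal_roi,background_roi Regions as `list(row =, col =, size =)`
#'   (top-left corner + side in pixels), equal sizes, disjoint.
#' @return Dimensionless SNR.
#' @export
thickness_snr <- function(map, signal_roi, background_roi) {
  get_roi <- function(roi) {
    rows <- roi$row + seq_len(roi$size) - 1L
    cols <- roi$col + seq_len(roi$size) - 1L
    if (min(rows) < 1L || min(cols) < 1L || max(rows) > nrow(map) ||
        max(cols) > ncol(map))
      stop("ROI extends outside the map")
    unclass(map)[rows, cols]
  }
  if (signal_roi$size != background_roi$size)
    stop("signal and background ROIs must have equal size")
  sig <- get_roi(signal_roi)
  bg <- get_roi(background_roi)
  s <- sd(bg)
  if (s == 0) return(Inf)
  mean(sig) / s
}

#' Region-wise difference report between two thickness maps
#'
#' Compares a recovered map against ground truth: global mean/max absolute
#' differences and, when a region mask (or a `two_material_map` truth, whose
#' material-2-dominant pixels form the mask) is available, mean relative
#' differences per region in percent of the truth's mean thickness there.
#'
#' @param recovered Matrix or [thickness_map()] (for two-material inputs pass
#'   the recovered `two_material_map`; its `t2` is compared).
#' @param truth Same kind of object as `recovered`.
#' @return A tibble with one row per region (`region`, `mean_diff_mm`,
#'   `max_diff_mm`, `mean_rel_pct`).
#' @export
map_difference_report <- function(recovered, truth) {
  two <- inherits(truth, "two_material_map")
  rec <- if (two) unclass(recovered$t2) else unclass(recovered)
  tru <- if (two) unclass(truth$t2) else unclass(truth)
  if (!all(dim(rec) == dim(tru))) stop("maps differ in shape")
  diff <- rec - tru
  regions <- if (two) {
    mask2 <- tru > truth$total_mm / 2
    list(`material-2` = mask2, `material-1` = !mask2,
         global = matrix(TRUE, nrow(tru), ncol(tru)))
  } else {
    list(global = matrix(TRUE, nrow(tru), ncol(tru)))
  }
  purrr::map_dfr(names(regions), function(nm) {
    m <- regions[[nm]]
    ref_mean <- mean(tru[m])
    tibble(region = nm,
           mean_diff_mm = mean(diff[m]),
           max_diff_mm = max(abs(diff[m])),
           mean_rel_pct = if (ref_mean > 0)
             mean(abs(diff[m])) / ref_mean * 100 else NA_real_)
  })
}
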