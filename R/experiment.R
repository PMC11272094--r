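#' Synthetic fiber-study experiment plan
#'
#' Describes the full synthetic twin of the polychromatic fiber study: which
#' retrieval techniques and spectrum strategies to run at which
#' object-detector distances, on what grid, with what spectrum, noise level
#' and seed. Defaults reproduce the reference bench: SOD 600 mm, ODDs
#' 200/300/400 mm, 20 um source, 13.5 um detector pixel, three nylon fibers
#' of 1.02/0.81/0.71 mm, detected 50 kV spectrum, a 3-layer SiC sandpaper
#' diffuser for the speckle technique, and Poisson noise at 5e4 photons per
#' pixel. The TA sample count defaults to 101 (the 1500-sample reference
#' value changes apex thickness by <1e-4 mm on this bench; see the package
#' vignette).
#'
#' @param techniques Subset of `c("PT", "AT", "ST")`.
#' @param averagings Subset of `c("EA", "PA", "TA")`.
#' @param odds_mm Object-detector distances, mm.
#' @param sod_mm Source-object distance, mm.
#' @param source_size_mm,detector_pixel_mm Source size and detector pixel, mm.
#' @param grid_n Image grid side, pixels.
#' @param diameters_mm Three fiber diameters, mm.
#' @param spectrum An [spectrum()]; default [make_synthetic_spectrum()].
#' @param n_ta TA energy-sample count.
#' @param photons Poisson photon budget per pixel, or `NULL` for noiseless.
#' @param mode Forward model, `"tie"` or `"fresnel"`.
#' @param seed Integer seed for diffuser and noise.
#' @return A list of class `experiment_plan`.
#' @export
experiment_plan <- function(techniques = c("PT", "AT", "ST"),
                            averagings = c("EA", "PA", "TA"),
                            odds_mm = c(200, 300, 400), sod_mm = 600,
                            source_size_mm = 0.02, detector_pixel_mm = 0.0135,
                            grid_n = 512, diameters_mm = c(1.02, 0.81, 0.71),
                            spectrum = make_synthetic_spectrum(),
                            n_ta = 101, photons = 5e4, mode = "tie",
                            seed = 1) {
  techniques <- match.arg(techniques, c("PT", "AT", "ST"), several.ok = TRUE)
  averagings <- match.arg(averagings, c("EA", "PA", "TA"), several.ok = TRUE)
  if (length(techniques) == 0 || length(averagings) == 0)
    stop("need at least one technique and one averaging")
  structure(list(techniques = techniques, averagings = averagings,
                 odds_mm = odds_mm, sod_mm = sod_mm,
                 source_size_mm = source_size_mm,
                 detector_pixel_mm = detector_pixel_mm, grid_n = grid_n,
                 diameters_mm = diameters_mm, spectrum = spectrum,
                 n_ta = n_ta, photons = photons, mode = mode, seed = seed),
            class = "experiment_plan")
}

# windows between fibers: midpoints of gaps, extended to profile ends
fiber_windows <- function(centers_mm, diameters_mm, x_range) {
  cuts <- c(x_range[1],
            (centers_mm[-length(centers_mm)] + centers_mm[-1]) / 2,
            x_range[2])
  purrr::map(seq_along(centers_mm), ~ c(cuts[.x], cuts[.x + 1]))
}

# fit the three fibers of a profile; returns list of fiber_fit
fit_three_fibers <- function(profile, centers_mm, diameters_mm) {
  wins <- fiber_windows(centers_mm, diameters_mm, range(profile$x_mm))
  purrr::map(wins, ~ fit_fiber(profile, window = .x))
}

#' Run the synthetic fiber experiment
#'
#' For every (technique, averaging, ODD) cell of the plan: simulate the
#' image pair (shared across cells at the same ODD), retrieve the thickness
#' map, extract the 100-row averaged profile, fit the three fibers, and
#' tabulate both diameter estimates with their signed percent errors, the
#' profile RMSD against the ideal chord profiles, the thickness SNR of fiber
#' 1, and the apex-diameter ratios d2/d1 and d3/d1. Cells that error are
#' recorded with `NA` metrics and the run continues.
#'
#' @param plan An [experiment_plan()].
#' @param csv Optional path; when given the table is also written as CSV.
#' @param verbose Print progress lines.
#' @return A tibble of class `fiber_experiment` with one row per
#'   (technique, averaging, odd, fiber).
#' @export
run_experiment <- function(plan, csv = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  nylon <- toy_material("nylon")
  sic <- toy_material("sic")
  rows <- list()
  for (odd in plan$odds_mm) {
    geom <- geometry(plan$sod_mm, odd, plan$source_size_mm,
                     plan$detector_pixel_mm)
    n <- c(plan$grid_n, plan$grid_n)
    phantom <- three_fiber_phantom(n, geom$object_pixel_mm,
                                   diameters_mm = plan$diameters_mm)
    centers <- attr(phantom, "centers_mm")
    need_plain <- any(plan$techniques %in% c("PT", "AT"))
    need_st <- "ST" %in% plan$techniques
    if (verbose) message(sprintf("ODD %g mm: simulating...", odd))
    pair_plain <- if (need_plain)
      forward_polychromatic(phantom, nylon, plan$spectrum, geom,
                            mode = plan$mode, photons = plan$photons,
                            seed = plan$seed) else NULL
    if (need_st) {
      diff_screen <- make_diffuser(n, geom$object_pixel_mm,
                                   seed = plan$seed + 1)
      pair_st <- forward_polychromatic(phantom, nylon, plan$spectrum, geom,
                                       mode = plan$mode,
                                       diffuser = diff_screen,
                                       diffuser_material = sic,
                                       photons = plan$photons,
                                       seed = plan$seed + 2)
      spectrum_st <- filter_spectrum(plan$spectrum, sic,
                                     diff_screen$n_layers *
                                       diff_screen$particle_mm)
    }
    for (tech in plan$techniques) for (avg in plan$averagings) {
      if (verbose) message(sprintf("  %s-%s", tech, avg))
      cell <- tryCatch({
        if (tech == "ST") {
          cfg <- retrieval_config("ST", avg, geom, spectrum_st, nylon,
                                  n_energy_samples = plan$n_ta)
          tmap <- retrieve_polychromatic(pair_st, cfg)
        } else {
          cfg <- retrieval_config(tech, avg, geom, plan$spectrum, nylon,
                                  n_energy_samples = plan$n_ta)
          tmap <- retrieve_polychromatic(pair_plain, cfg)
        }
        profile <- extract_profile(tmap, n_rows = min(100L, plan$grid_n))
        fits <- fit_three_fibers(profile, centers, plan$diameters_mm)
        rmsd <- rmsd_vs_theory(profile, plan$diameters_mm, centers)
        ratios <- diameter_ratios(fits)
        px <- geom$object_pixel_mm
        roi_sz <- min(50L, plan$grid_n %/% 4L)
        sig_col <- round(centers[1] / px)
        bg_col <- max(1L, round((centers[1] - plan$diameters_mm[1]) / px) -
                        roi_sz - 5L)
        mid <- plan$grid_n %/% 2L
        snr <- thickness_snr(tmap,
                             list(row = mid - roi_sz %/% 2L,
                                  col = sig_col - roi_sz %/% 2L,
                                  size = roi_sz),
                             list(row = mid - roi_sz %/% 2L, col = bg_col,
                                  size = roi_sz))
        purrr::map_dfr(1:3, function(i) {
          err <- diameter_errors(fits[[i]], plan$diameters_mm[i])
          tibble(technique = tech, averaging = avg, odd_mm = odd,
                 fiber = i, nominal_mm = plan$diameters_mm[i],
                 d_t_mm = fits[[i]]$d_t_mm, d_x_mm = fits[[i]]$d_x_mm,
                 dd_t_pct = err[["dd_t_pct"]], dd_x_pct = err[["dd_x_pct"]],
                 r_squared = fits[[i]]$r_squared,
                 rmse_fit_mm = fits[[i]]$rmse_mm,
                 rmsd_mm = rmsd, snr = snr,
                 r21 = ratios[["r21"]], r31 = ratios[["r31"]])
        })
      }, error = function(e) {
        warning(sprintf("cell %s-%s @ ODD %g failed: %s", tech, avg, odd,
                        conditionMessage(e)))
        tibble(technique = tech, averaging = avg, odd_mm = odd, fiber = 1:3,
               nominal_mm = plan$diameters_mm, d_t_mm = NA_real_,
               d_x_mm = NA_real_, dd_t_pct = NA_real_, dd_x_pct = NA_real_,
               r_squared = NA_real_, rmse_fit_mm = NA_real_,
               rmsd_mm = NA_real_, snr = NA_real_, r21 = NA_real_,
               r31 = NA_real_)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fiber_experiment", class(out))
  attr(out, "plan") <- plan
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' @export
glance.fiber_experiment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$technique, .data$averaging,
                    .data$odd_mm),
    max_abs_dd_t_pct = max(abs(.data$dd_t_pct)),
    max_abs_dd_x_pct = max(abs(.data$dd_x_pct)),
    rmsd_mm = .data$rmsd_mm[1], snr = .data$snr[1],
    r21 = .data$r21[1], r31 = .data$r31[1], .groups = "drop")
}
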