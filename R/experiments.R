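# Scripted simulation experiments: perichondrium oxygenation contrast,
# layer-thickness sweeps, saturation and blood-filling sweeps with StO2
# recovery. Every experiment is deterministic given (seed, n_photons) and
# carries provenance metadata (stack hash, config, seeds).

#' Reference simulation grids
#'
#' The packaged sweep designs: per-layer thickness grids in mm, the
#' saturation levels and the blood fractions used by the simulation
#' studies.
#'
#' @return A named list of numeric vectors.
#' @export
paper_grids <- function() {
  list(
    mucosa = c(0.15, 0.25, 0.35, 0.45, 0.55),
    submucosa = c(0.35, 0.45, 0.55, 0.65, 0.75),
    fibrocartilage = c(0.7, 0.85, 1.0, 1.15, 1.3),
    adventitia = c(0.05, 0.075, 0.1, 0.15, 0.2),
    sto2_levels = c(0, 0.25, 0.5, 0.65, 0.8, 1.0),
    blood_fractions = c(0.005, 0.01, 0.02)
  )
}

# Internal: md5 provenance hash of an arbitrary plain-list configuration.
.config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA)), f)
  unname(tools::md5sum(f))
}

.experiment_meta <- function(stack, probe, n_photons, seed) {
  list(
    stack_hash = .config_hash(stack_config(stack)),
    probe = unclass(probe),
    n_photons = n_photons,
    seed = seed
  )
}

#' Perichondrium oxygenation contrast
#'
#' Simulates the six-layer tracheal stack twice — perichondrium fully
#' oxygenated versus fully deoxygenated (packaged absorption rows), all
#' other layers unchanged — and reports the per-wavelength percent
#' difference in detected diffuse reflectance and its mean and standard
#' deviation across the five wavelengths. With adventitial probe placement
#' the perichondrium lies 0.1 mm below the surface and the contrast is
#' large; from the mucosal side it sits 1 mm deep and the contrast nearly
#' vanishes.
#'
#' @param side `"adventitial"` or `"mucosal"` probe placement.
#' @param n_photons Photon budget per wavelength.
#' @param seed Integer seed (shared by the paired runs: common random
#'   numbers).
#' @param probe A [probe_geometry()].
#' @param metric `"relative"` (default): `100 * |Rd_oxy - Rd_deoxy| /
#'   Rd_deoxy` per wavelength; `"normalized"`: `100 * |Rd_oxy - Rd_deoxy| /
#'   mean(Rd)` with the mean over both runs and all wavelengths.
#' @return A list of class `contrast_result`: per-wavelength differences,
#'   `mean_pct`, `sd_pct`, propagated Monte Carlo standard error
#'   `mc_se_pct` of the mean, the two tallies and provenance metadata.
#' @export
perichondrium_contrast <- function(side = c("adventitial", "mucosal"),
                                   n_photons = 1e5, seed = 1,
                                   probe = probe_geometry(),
                                   metric = c("relative", "normalized")) {
  side <- match.arg(side)
  metric <- match.arg(metric)
  cfg <- sim_config(n_photons = n_photons, seed = seed)
  st_oxy <- build_stack("six", probe_side = side, perichondrium = "oxy")
  st_deoxy <- build_stack("six", probe_side = side, perichondrium = "deoxy")
  t_oxy <- simulate_spectrum(st_oxy, probe = probe, config = cfg)
  t_deoxy <- simulate_spectrum(st_deoxy, probe = probe, config = cfg)

  if (metric == "relative") {
    diff_pct <- 100 * abs(t_oxy$Rd - t_deoxy$Rd) / t_deoxy$Rd
    # relative MC error of each percent difference
    se_pct <- 100 * sqrt(t_oxy$Rd_se^2 + t_deoxy$Rd_se^2) / t_deoxy$Rd
  } else {
    denom <- mean(c(t_oxy$Rd, t_deoxy$Rd))
    diff_pct <- 100 * abs(t_oxy$Rd - t_deoxy$Rd) / denom
    se_pct <- 100 * sqrt(t_oxy$Rd_se^2 + t_deoxy$Rd_se^2) / denom
  }

  structure(list(
    side = side,
    metric = metric,
    wavelength_nm = t_oxy$wavelength_nm,
    diff_pct = diff_pct,
    diff_se_pct = se_pct,
    mean_pct = mean(diff_pct),
    sd_pct = sd(diff_pct),
    mc_se_pct = sqrt(sum(se_pct^2)) / length(se_pct),
    tally_oxy = t_oxy,
    tally_deoxy = t_deoxy,
    meta = .experiment_meta(st_oxy, probe, n_photons, seed)
  ), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("Perichondrium oxygenation contrast (%s side, %s metric)\n",
              x$side, x$metric))
  print(data.frame(wavelength_nm = x$wavelength_nm,
                   diff_pct = round(x$diff_pct, 3),
                   mc_se_pct = round(x$diff_se_pct, 3)),
        row.names = FALSE)
  cat(sprintf("mean over wavelengths: %.2f%% (sd %.2f%%, MC se %.2f%%)\n",
              x$mean_pct, x$sd_pct, x$mc_se_pct))
  invisible(x)
}

#' Layer-thickness sweep
#'
#' Simulates the six-layer stack while varying one layer's thickness over
#' a grid (defaults: the packaged per-layer grids of [paper_grids()]),
#' holding every other layer at its default. Returns detected Rd and Td
#' per thickness and wavelength, plus the derived `ln(1/Rd)` attenuation.
#'
#' @param layer `"mucosa"`, `"submucosa"`, `"fibrocartilage"` (total
#'   membrane thickness including the two 0.1 mm perichondrium sheaths) or
#'   `"adventitia"`.
#' @param values Thickness grid in mm; `NULL` uses the packaged grid.
#' @param side Probe side.
#' @param n_photons Photon budget per wavelength.
#' @param seed Integer seed; the same per-wavelength streams are reused at
#'   every grid value (common random numbers), so differences along the
#'   grid are paired comparisons.
#' @param probe A [probe_geometry()].
#' @param perichondrium Perichondrium absorption variant for the sweeps
#'   (default `"oxy"`).
#' @return A list of class `sweep_result` with a long-format `results`
#'   data.frame (`thickness_mm`, `wavelength_nm`, `Rd`, `Td`, `Rd_se`,
#'   `Td_se`, `attenuation`), the grid, and provenance metadata.
#' @export
thickness_sweep <- function(layer, values = NULL,
                            side = c("mucosal", "adventitial"),
                            n_photons = 1e5, seed = 1,
                            probe = probe_geometry(),
                            perichondrium = "oxy") {
  side <- match.arg(side)
  grids <- paper_grids()
  if (!layer %in% c("mucosa", "submucosa", "fibrocartilage", "adventitia")) {
    stop("layer must be one of mucosa, submucosa, fibrocartilage, ",
         "adventitia", call. = FALSE)
  }
  if (is.null(values)) values <- grids[[layer]]
  if (any(values <= 0)) stop("thickness values must be positive",
                             call. = FALSE)

  rows <- list()
  for (i in seq_along(values)) {
    ov <- setNames(list(values[i]), layer)
    st <- build_stack("six", probe_side = side,
                      perichondrium = perichondrium, thickness = ov)
    cfg <- sim_config(n_photons = n_photons, seed = seed)
    tal <- simulate_spectrum(st, probe = probe, config = cfg)
    rows[[i]] <- data.frame(
      thickness_mm = values[i],
      wavelength_nm = tal$wavelength_nm,
      Rd = tal$Rd, Td = tal$Td,
      Rd_se = tal$Rd_se, Td_se = tal$Td_se,
      attenuation = log(1 / tal$Rd)
    )
  }
  st0 <- build_stack("six", probe_side = side, perichondrium = perichondrium)
  structure(list(
    parameter = paste0(layer, "_thickness_mm"),
    layer = layer,
    grid = values,
    side = side,
    results = do.call(rbind, rows),
    meta = .experiment_meta(st0, probe, n_photons, seed)
  ), class = "sweep_result")
}

#' Saturation sweep
#'
#' Simulates reflectance while sweeping the tissue oxygen saturation with
#' the blood fraction fixed (default 1%), blending hemoglobin into every
#' layer's bloodless baseline (`perfused = "all"`, four-layer stack) or
#' into the perichondrium only (`perfused = "perichondrium"`, six-layer
#' stack). Returns the `ln(1/Rd)` attenuation spectra: at 100% saturation
#' they show the oxyhemoglobin double peak at 542/576 nm, at 0% the single
#' deoxyhemoglobin peak at 556 nm.
#'
#' @param levels Saturation levels in \[0, 1\] (default: the packaged
#'   0/25/50/65/80/100% grid).
#' @param side Probe side.
#' @param n_photons Photon budget per wavelength.
#' @param seed Integer seed (common random numbers across levels).
#' @param blood_fraction Blood fraction used for the blending (default
#'   0.01).
#' @param perfused `"all"` or `"perichondrium"`.
#' @param probe A [probe_geometry()].
#' @return A list of class `sweep_result`; `results` has columns
#'   `sto2`, `wavelength_nm`, `Rd`, `Rd_se`, `attenuation`.
#' @export
saturation_sweep <- function(levels = NULL,
                             side = c("mucosal", "adventitial"),
                             n_photons = 1e5, seed = 1,
                             blood_fraction = 0.01,
                             perfused = c("all", "perichondrium"),
                             probe = probe_geometry()) {
  side <- match.arg(side)
  perfused <- match.arg(perfused)
  if (is.null(levels)) levels <- paper_grids()$sto2_levels
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]",
                                         call. = FALSE)
  rows <- list()
  for (i in seq_along(levels)) {
    ps <- perfusion_state(levels[i], blood_fraction)
    st <- if (perfused == "all") {
      build_stack("four", probe_side = side, perfusion = ps)
    } else {
      build_stack("six", probe_side = side,
                  perfusion = list(perichondrium = ps))
    }
    cfg <- sim_config(n_photons = n_photons, seed = seed)
    tal <- simulate_spectrum(st, probe = probe, config = cfg)
    rows[[i]] <- data.frame(
      sto2 = levels[i],
      wavelength_nm = tal$wavelength_nm,
      Rd = tal$Rd, Rd_se = tal$Rd_se,
      attenuation = log(1 / tal$Rd)
    )
  }
  st0 <- if (perfused == "all") build_stack("four", probe_side = side)
         else build_stack("six", probe_side = side)
  structure(list(
    parameter = "sto2",
    grid = levels,
    side = side,
    blood_fraction = blood_fraction,
    perfused = perfused,
    results = do.call(rbind, rows),
    meta = .experiment_meta(st0, probe, n_photons, seed)
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep of %s (%s probe side), %d grid values\n",
              x$parameter, x$side, length(x$grid)))
  cat("grid:", paste(signif(x$grid, 4), collapse = ", "), "\n")
  print(utils::head(x$results, 10), row.names = FALSE)
  if (nrow(x$results) > 10) {
    cat("...", nrow(x$results) - 10, "more rows\n")
  }
  invisible(x)
}

#' Blood-filling sweep with StO2 recovery
#'
#' The end-to-end parameter-recovery experiment: the four-layer tracheal
#' stack is perfused at a fixed true saturation (default 50%) across
#' several blood fractions (default 0.5/1/2%), reflectance spectra are
#' simulated, converted to `ln(1/Rd)` attenuation, and unmixed with
#' [fit_attenuation()] (baseline degree 1). Reports the extracted StO2 per
#' blood fraction and the pooled mean and standard deviation, in percent.
#'
#' @param fractions Blood fractions (default: the packaged 0.5/1/2% grid).
#' @param sto2_true True saturation used in the simulation (default 0.5).
#' @param side Probe side (default `"mucosal"`, the side used for the
#'   saturation-level spectral analysis; see the methods vignette for why
#'   the adventitial-side fit is strongly biased by the adventitia's
#'   baseline absorption shape).
#' @param n_photons Photon budget per wavelength per fraction.
#' @param seed Integer seed.
#' @param probe A [probe_geometry()].
#' @return A list of class `recovery_result`: per-fraction extracted
#'   StO2 (`sto2_hat`), fits, `pooled_mean_pct`, `pooled_sd_pct`, and
#'   provenance metadata.
#' @export
blood_filling_recovery <- function(fractions = NULL, sto2_true = 0.5,
                                   side = c("mucosal", "adventitial"),
                                   n_photons = 1e5, seed = 1,
                                   probe = probe_geometry()) {
  side <- match.arg(side)
  if (is.null(fractions)) fractions <- paper_grids()$blood_fractions
  if (any(fractions < 0)) stop("blood fractions must be nonnegative",
                               call. = FALSE)
  if (sto2_true < 0 || sto2_true > 1) stop("sto2_true must lie in [0, 1]",
                                           call. = FALSE)
  fits <- list()
  sto2_hat <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    ps <- perfusion_state(sto2_true, fractions[i])
    st <- build_stack("four", probe_side = side, perfusion = ps)
    cfg <- sim_config(n_photons = n_photons, seed = seed + 104729 * i)
    tal <- simulate_spectrum(st, probe = probe, config = cfg)
    A <- attenuation_from_reflectance(tal)
    fit <- fit_attenuation(A, poly_degree = 1)
    fits[[i]] <- fit
    sto2_hat[i] <- fit$sto2
  }
  st0 <- build_stack("four", probe_side = side)
  structure(list(
    fractions = fractions,
    sto2_true = sto2_true,
    side = side,
    sto2_hat = sto2_hat,
    fits = fits,
    pooled_mean_pct = 100 * mean(sto2_hat),
    pooled_sd_pct = 100 * sd(sto2_hat),
    meta = .experiment_meta(st0, probe, n_photons, seed)
  ), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("StO2 recovery at true level %.0f%% (%s side)\n",
              100 * x$sto2_true, x$side))
  print(data.frame(blood_fraction = x$fractions,
                   sto2_extracted_pct = round(100 * x$sto2_hat, 2)),
        row.names = FALSE)
  cat(sprintf("pooled: %.1f%% +/- %.1f%%\n",
              x$pooled_mean_pct, x$pooled_sd_pct))
  invisible(x)
}
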