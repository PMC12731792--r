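# Packaged tracheal optical properties and hemoglobin basis spectra.
#
# All coefficients are in cm^-1 on the five-point wavelength grid
# 500/542/556/576/586 nm; layer thicknesses are quoted in mm at the user
# interface and converted to cm once, at stack construction.

.drs_wavelengths <- c(500, 542, 556, 576, 586)

# Per-layer properties. Perichondrium carries two absorption variants
# (fully oxygenated / fully deoxygenated hemoglobin at 1% blood content);
# the cartilage central part is the bloodless base used when blending.
.drs_layers <- list(
  mucosa = list(
    thickness_mm = 0.35,
    mu_a = c(2.9, 3.6, 3.3, 3.5, 3.0),
    mu_s = c(145, 142, 142, 141, 140),
    g    = c(0.71, 0.73, 0.74, 0.75, 0.76)
  ),
  submucosa = list(
    thickness_mm = 0.55,
    mu_a = c(2.2, 2.8, 2.5, 2.7, 2.0),
    mu_s = c(143, 140, 140, 139, 139),
    g    = c(0.69, 0.72, 0.73, 0.74, 0.75)
  ),
  perichondrium = list(
    thickness_mm = 0.1,
    mu_a_oxy   = c(5.42, 6.81, 4.82, 6.84, 4.49),
    mu_a_deoxy = c(5.15, 6.54, 5.89, 6.01, 4.83),
    mu_s = c(127, 120, 120, 120, 119),
    g    = c(0.77, 0.79, 0.80, 0.82, 0.79)
  ),
  cartilage = list(
    thickness_mm = 0.8,
    mu_a = c(2.6, 4.0, 3.0, 3.9, 3.1),
    mu_s = c(127, 120, 120, 120, 119),
    g    = c(0.77, 0.79, 0.80, 0.82, 0.79)
  ),
  adventitia = list(
    thickness_mm = 0.1,
    mu_a = c(2.1, 3.5, 2.8, 3.5, 3.0),
    mu_s = c(80, 78, 77, 75, 72),
    g    = c(0.85, 0.86, 0.87, 0.88, 0.88)
  )
)

# Whole-blood hemoglobin absorption rows as printed in the source table.
# The printed row labels are swapped relative to the canonical Hb/HbO2
# spectral shapes (HbO2 has the 542/576 nm double peak, Hb the single
# 556 nm peak), and only the swapped assignment reproduces the packaged
# perichondrium oxy/deoxy rows as base + 1% blend. `chromophore_table()`
# applies the correction by default.
.drs_hb_rows_printed <- list(
  Hb   = c(112, 285, 185, 297, 142),
  HbO2 = c(112, 258, 292, 215, 176)
)

.drs_refractive_index <- 1.37

#' Reference optical properties of the tracheal layers
#'
#' Returns the packaged per-layer absorption and scattering coefficients,
#' anisotropy factors, default thicknesses and the common refractive index
#' (1.37) on the five-point wavelength grid 500, 542, 556, 576, 586 nm.
#' The perichondrium entry carries two absorption variants, `mu_a_oxy` and
#' `mu_a_deoxy`, corresponding to fully oxygenated and fully reduced
#' hemoglobin at 1% blood content.
#'
#' @param layer Optional layer name (`"mucosa"`, `"submucosa"`,
#'   `"perichondrium"`, `"cartilage"`, `"adventitia"`). When omitted, all
#'   layers are returned.
#' @return A list with elements `wavelengths_nm`, `n`, and `layers` (or the
#'   single requested layer's list of `thickness_mm`, `mu_a` (or
#'   `mu_a_oxy`/`mu_a_deoxy`), `mu_s`, `g`).
#' @examples
#' props <- tracheal_properties("mucosa")
#' props$mu_a[tracheal_properties()$wavelengths_nm == 542]  # 3.6 cm^-1
#' @export
tracheal_properties <- function(layer = NULL) {
  if (is.null(layer)) {
    return(list(
      wavelengths_nm = .drs_wavelengths,
      n = .drs_refractive_index,
      layers = .drs_layers
    ))
  }
  if (!layer %in% names(.drs_layers)) {
    stop("unknown layer '", layer, "'; known layers: ",
         paste(names(.drs_layers), collapse = ", "), call. = FALSE)
  }
  .drs_layers[[layer]]
}

#' Hemoglobin absorption basis on the simulation wavelength grid
#'
#' Per-wavelength whole-blood absorption coefficients (cm^-1 per unit blood
#' fraction) of oxygenated and reduced hemoglobin on the five-point grid.
#' With `corrected = TRUE` (default) the two rows are assigned so that HbO2
#' shows the canonical 542/576 nm double peak and Hb the single 556 nm
#' peak; `corrected = FALSE` returns the rows under their verbatim labels,
#' which are swapped relative to those shapes.
#'
#' @param corrected Apply the row-label correction (default `TRUE`).
#' @return An object of class `chromophore_table`: a list with
#'   `wavelengths_nm`, `mu_a_HbO2`, `mu_a_Hb` and a `corrected` flag.
#' @examples
#' tab <- chromophore_table()
#' tab$mu_a_HbO2  # peaks at 542 and 576 nm
#' @export
chromophore_table <- function(corrected = TRUE) {
  rows <- .drs_hb_rows_printed
  out <- list(
    wavelengths_nm = .drs_wavelengths,
    mu_a_HbO2 = if (corrected) rows$Hb else rows$HbO2,
    mu_a_Hb   = if (corrected) rows$HbO2 else rows$Hb,
    corrected = corrected
  )
  class(out) <- "chromophore_table"
  out
}

#' @export
print.chromophore_table <- function(x, ...) {
  cat("Hemoglobin absorption basis (cm^-1 per unit blood fraction)\n")
  cat(if (x$corrected) "row assignment: corrected\n" else
    "row assignment: verbatim table labels\n")
  print(data.frame(wavelength_nm = x$wavelengths_nm,
                   mu_a_HbO2 = x$mu_a_HbO2, mu_a_Hb = x$mu_a_Hb),
        row.names = FALSE)
  invisible(x)
}

#' Blend a baseline absorption coefficient with hemoglobin
#'
#' Adds the hemoglobin contribution of perfused tissue to a bloodless
#' baseline absorption coefficient:
#' \deqn{\mu_a = \mu_{a,base} + f \,[\, s\,\mu_{a,HbO_2}(\lambda) +
#'   (1-s)\,\mu_{a,Hb}(\lambda)\,]}
#' where `f` is the blood fraction and `s` the hemoglobin oxygen
#' saturation. The result is affine in both `f` and `s`.
#'
#' @param mu_a_base Baseline (bloodless) absorption coefficient, cm^-1.
#' @param sto2 Hemoglobin oxygen saturation, fraction in \[0, 1\].
#' @param blood_fraction Blood content of the tissue, fraction (e.g. 0.01
#'   for 1%).
#' @param wavelength Wavelength(s) in nm; must lie on the table grid.
#' @param table A [chromophore_table()].
#' @return Blended absorption coefficient(s), cm^-1.
#' @examples
#' # cartilage base at 542 nm, 1% blood, fully oxygenated:
#' blend_absorption(4.0, sto2 = 1, blood_fraction = 0.01, wavelength = 542)
#' @export
blend_absorption <- function(mu_a_base, sto2, blood_fraction, wavelength,
                             table = chromophore_table()) {
  if (any(blood_fraction < 0)) {
    stop("blood_fraction must be nonnegative", call. = FALSE)
  }
  if (any(sto2 < 0 | sto2 > 1)) {
    stop("sto2 must lie in [0, 1]", call. = FALSE)
  }
  idx <- match(wavelength, table$wavelengths_nm)
  if (anyNA(idx)) {
    stop("wavelength(s) ", paste(wavelength[is.na(idx)], collapse = ", "),
         " nm not on the chromophore grid", call. = FALSE)
  }
  mu_a_base + blood_fraction *
    (sto2 * table$mu_a_HbO2[idx] + (1 - sto2) * table$mu_a_Hb[idx])
}

#' Saturation/blood-fraction state of a perfused layer
#'
#' @param sto2 Hemoglobin oxygen saturation, fraction in \[0, 1\].
#' @param blood_fraction Blood content, fraction (e.g. 0.005--0.02).
#' @return A list of class `perfusion_state`.
#' @export
perfusion_state <- function(sto2, blood_fraction) {
  if (sto2 < 0 || sto2 > 1) stop("sto2 must lie in [0, 1]", call. = FALSE)
  if (blood_fraction < 0) stop("blood_fraction must be nonnegative",
                               call. = FALSE)
  structure(list(sto2 = sto2, blood_fraction = blood_fraction),
            class = "perfusion_state")
}

#' Build a tracheal tissue stack
#'
#' Assembles the four-layer (mucosa, submucosa, fibrocartilage, adventitia)
#' or six-layer (fibrocartilage split into perichondrium / central part /
#' perichondrium) model of the tracheal wall with the packaged optical
#' properties. Layers are ordered from the illuminated face inward:
#' `probe_side = "adventitial"` reverses the anatomical order so that the
#' adventitia is hit first.
#'
#' Default thicknesses are 0.35 mm (mucosa), 0.55 mm (submucosa), 1 mm
#' (fibrocartilage; 0.1 + 0.8 + 0.1 mm in the six-layer variant) and
#' 0.1 mm (adventitia). In the six-layer variant the perichondrium uses the
#' packaged fully oxygenated or fully deoxygenated absorption row as chosen
#' by `perichondrium`; in the four-layer variant the fibrocartilage layer
#' uses the bloodless cartilage row. `perfusion` blends hemoglobin into the
#' bloodless baseline of the named layers via [blend_absorption()] (for the
#' perichondrium the cartilage row is the baseline).
#'
#' @param variant `"six"` (default) or `"four"`.
#' @param probe_side `"mucosal"` or `"adventitial"`: which face the probe
#'   touches (becomes the first traversed layer).
#' @param perichondrium `"oxy"` or `"deoxy"`: which packaged perichondrium
#'   absorption row to use (six-layer variant; ignored when a perfusion
#'   override replaces it).
#' @param thickness Named list/vector of per-layer thickness overrides in
#'   mm; names among `mucosa`, `submucosa`, `fibrocartilage` (four-layer),
#'   `perichondrium`, `cartilage` (six-layer), `adventitia`. In the
#'   six-layer variant an override named `fibrocartilage` resizes the
#'   central cartilage part, keeping the two 0.1 mm perichondrium sheaths.
#' @param perfusion Either `NULL`, a named list of [perfusion_state()]
#'   objects keyed by layer name, or a single `perfusion_state` to apply to
#'   every layer ("whole-stack" blending on each layer's bloodless
#'   baseline).
#' @param table Chromophore basis used for blending.
#' @return An object of class `tissue_stack`: list of layers (each with
#'   `name`, `thickness_cm`, `mu_a`, `mu_s`, `g` on the wavelength grid),
#'   plus `wavelengths_nm`, `n`, `probe_side`, `variant`.
#' @examples
#' st <- build_stack("six", probe_side = "adventitial")
#' sum(vapply(st$layers, `[[`, numeric(1), "thickness_cm")) * 10  # 2 mm
#' @export
build_stack <- function(variant = c("six", "four"),
                        probe_side = c("mucosal", "adventitial"),
                        perichondrium = c("oxy", "deoxy"),
                        thickness = NULL,
                        perfusion = NULL,
                        table = chromophore_table()) {
  variant <- match.arg(variant)
  probe_side <- match.arg(probe_side)
  perichondrium <- match.arg(perichondrium)

  ref <- .drs_layers
  peri_mu_a <- if (perichondrium == "oxy") ref$perichondrium$mu_a_oxy
               else ref$perichondrium$mu_a_deoxy

  if (variant == "six") {
    layers <- list(
      list(name = "mucosa", thickness_mm = 0.35,
           mu_a = ref$mucosa$mu_a, mu_s = ref$mucosa$mu_s, g = ref$mucosa$g),
      list(name = "submucosa", thickness_mm = 0.55,
           mu_a = ref$submucosa$mu_a, mu_s = ref$submucosa$mu_s,
           g = ref$submucosa$g),
      list(name = "perichondrium_upper", thickness_mm = 0.1,
           mu_a = peri_mu_a, mu_s = ref$perichondrium$mu_s,
           g = ref$perichondrium$g),
      list(name = "cartilage", thickness_mm = 0.8,
           mu_a = ref$cartilage$mu_a, mu_s = ref$cartilage$mu_s,
           g = ref$cartilage$g),
      list(name = "perichondrium_lower", thickness_mm = 0.1,
           mu_a = peri_mu_a, mu_s = ref$perichondrium$mu_s,
           g = ref$perichondrium$g),
      list(name = "adventitia", thickness_mm = 0.1,
           mu_a = ref$adventitia$mu_a, mu_s = ref$adventitia$mu_s,
           g = ref$adventitia$g)
    )
  } else {
    layers <- list(
      list(name = "mucosa", thickness_mm = 0.35,
           mu_a = ref$mucosa$mu_a, mu_s = ref$mucosa$mu_s, g = ref$mucosa$g),
      list(name = "submucosa", thickness_mm = 0.55,
           mu_a = ref$submucosa$mu_a, mu_s = ref$submucosa$mu_s,
           g = ref$submucosa$g),
      list(name = "fibrocartilage", thickness_mm = 1.0,
           mu_a = ref$cartilage$mu_a, mu_s = ref$cartilage$mu_s,
           g = ref$cartilage$g),
      list(name = "adventitia", thickness_mm = 0.1,
           mu_a = ref$adventitia$mu_a, mu_s = ref$adventitia$mu_s,
           g = ref$adventitia$g)
    )
  }
  names(layers) <- vapply(layers, `[[`, character(1), "name")

  # thickness overrides (mm)
  if (!is.null(thickness)) {
    thickness <- as.list(thickness)
    for (nm in names(thickness)) {
      val <- thickness[[nm]]
      if (!is.numeric(val) || val <= 0 || !is.finite(val)) {
        stop("thickness override for '", nm, "' must be a positive number",
             call. = FALSE)
      }
      target <- nm
      if (variant == "six" && nm == "fibrocartilage") {
        # resize the central part; the two 0.1 mm sheaths are anatomical
        central <- val - 2 * 0.1
        if (central <= 0) {
          stop("six-layer fibrocartilage thickness must exceed the two ",
               "0.1 mm perichondrium sheaths", call. = FALSE)
        }
        layers[["cartilage"]]$thickness_mm <- central
        next
      }
      if (variant == "six" && nm == "perichondrium") {
        layers[["perichondrium_upper"]]$thickness_mm <- val
        layers[["perichondrium_lower"]]$thickness_mm <- val
        next
      }
      if (!target %in% names(layers)) {
        stop("thickness override names unknown layer '", nm, "'",
             call. = FALSE)
      }
      layers[[target]]$thickness_mm <- val
    }
  }

  # perfusion blending on the bloodless baselines
  if (!is.null(perfusion)) {
    if (inherits(perfusion, "perfusion_state")) {
      perfusion <- setNames(rep(list(perfusion), length(layers)),
                            names(layers))
    }
    for (nm in names(perfusion)) {
      ps <- perfusion[[nm]]
      if (!inherits(ps, "perfusion_state")) {
        stop("perfusion entries must be perfusion_state objects",
             call. = FALSE)
      }
      keys <- if (nm == "perichondrium" && variant == "six") {
        c("perichondrium_upper", "perichondrium_lower")
      } else nm
      if (!all(keys %in% names(layers))) {
        stop("perfusion override names unknown layer '", nm, "'",
             call. = FALSE)
      }
      for (k in keys) {
        base <- if (startsWith(k, "perichondrium")) ref$cartilage$mu_a
                else layers[[k]]$mu_a
        layers[[k]]$mu_a <- blend_absorption(
          base, ps$sto2, ps$blood_fraction, .drs_wavelengths, table)
      }
    }
  }

  if (probe_side == "adventitial") layers <- rev(layers)
  layers <- lapply(layers, function(l) {
    l$thickness_cm <- l$thickness_mm / 10
    l
  })

  structure(list(
    layers = layers,
    wavelengths_nm = .drs_wavelengths,
    n = .drs_refractive_index,
    probe_side = probe_side,
    variant = variant
  ), class = "tissue_stack")
}

#' @export
print.tissue_stack <- function(x, ...) {
  cat(sprintf("Tracheal tissue stack (%s-layer variant, probe on %s side)\n",
              x$variant, x$probe_side))
  d <- data.frame(
    layer = vapply(x$layers, `[[`, character(1), "name"),
    thickness_mm = vapply(x$layers, `[[`, numeric(1), "thickness_mm")
  )
  print(d, row.names = FALSE)
  cat(sprintf("total thickness: %.3g mm; n = %.2f; grid: %s nm\n",
              sum(d$thickness_mm), x$n,
              paste(x$wavelengths_nm, collapse = "/")))
  invisible(x)
}

#' Total stack thickness in mm
#' @param stack A `tissue_stack`.
#' @return Numeric scalar, mm.
#' @export
stack_thickness <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  sum(vapply(stack$layers, `[[`, numeric(1), "thickness_mm"))
}

#' Export a tissue stack as a plain configuration list
#'
#' Round-trippable plain-list representation (suitable for YAML/JSON) of a
#' stack: one entry per layer with name, thickness in mm and per-wavelength
#' properties.
#'
#' @param stack A `tissue_stack`.
#' @return A nested list.
#' @export
stack_config <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  list(
    variant = stack$variant,
    probe_side = stack$probe_side,
    refractive_index = stack$n,
    wavelengths_nm = stack$wavelengths_nm,
    layers = lapply(unname(stack$layers), function(l) {
      list(name = l$name, thickness_mm = l$thickness_mm,
           mu_a = l$mu_a, mu_s = l$mu_s, g = l$g)
    })
  )
}

# Internal: per-wavelength property vectors for the kernel.
.stack_at_wavelength <- function(stack, wavelength) {
  idx <- match(wavelength, stack$wavelengths_nm)
  if (is.na(idx)) {
    stop("wavelength ", wavelength, " nm not on the stack grid",
         call. = FALSE)
  }
  list(
    mu_a = vapply(stack$layers, function(l) l$mu_a[idx], numeric(1)),
    mu_s = vapply(stack$layers, function(l) l$mu_s[idx], numeric(1)),
    g    = vapply(stack$layers, function(l) l$g[idx], numeric(1)),
    d_cm = vapply(stack$layers, `[[`, numeric(1), "thickness_cm")
  )
}
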