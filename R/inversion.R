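# Attenuation-model inversion: nonnegative hemoglobin unmixing of an
# attenuation spectrum into a polynomial baseline plus Hb/HbO2 amplitudes,
# reporting tissue oxygen saturation StO2 = amp_HbO2 / (amp_HbO2 + amp_Hb).

#' Design matrix for the attenuation model
#'
#' Columns are the polynomial baseline terms in the centered and scaled
#' wavelength `(lambda - mean)/sd` (for conditioning) followed by the two
#' chromophore basis columns, in the fixed order
#' `[1, lambda~, lambda~^2, mu_a_Hb, mu_a_HbO2]` (polynomial terms up to
#' `poly_degree`).
#'
#' @param wavelengths Wavelengths in nm, on the chromophore grid.
#' @param table A [chromophore_table()].
#' @param poly_degree Baseline polynomial degree, 0, 1 or 2.
#' @return A numeric matrix with attributes `center` and `scale` recording
#'   the wavelength transform.
#' @export
build_design_matrix <- function(wavelengths, table = chromophore_table(),
                                poly_degree = 1) {
  if (!poly_degree %in% 0:2) stop("poly_degree must be 0, 1 or 2",
                                  call. = FALSE)
  n <- length(wavelengths)
  if (n < poly_degree + 3) {
    stop("need at least poly_degree + 3 wavelengths for identifiability",
         call. = FALSE)
  }
  idx <- match(wavelengths, table$wavelengths_nm)
  if (anyNA(idx)) stop("wavelength(s) not on the chromophore grid",
                       call. = FALSE)
  ctr <- mean(wavelengths)
  scl <- sd(wavelengths)
  lt <- (wavelengths - ctr) / scl
  poly_cols <- cbind(`(Intercept)` = rep(1, n), lambda = lt,
                     lambda2 = lt^2)[, seq_len(poly_degree + 1), drop = FALSE]
  X <- cbind(poly_cols, mu_a_Hb = table$mu_a_Hb[idx],
             mu_a_HbO2 = table$mu_a_HbO2[idx])
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  attr(X, "poly_degree") <- poly_degree
  X
}

#' Tissue oxygen saturation from chromophore amplitudes
#'
#' `StO2 = amp_HbO2 / (amp_HbO2 + amp_Hb)`.
#'
#' @param amp_HbO2,amp_Hb Nonnegative lumped amplitudes.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) when both
#'   amplitudes are zero — a bloodless spectrum carries no saturation
#'   information.
#' @examples
#' compute_sto2(0.56, 0.44)  # 0.56
#' @export
compute_sto2 <- function(amp_HbO2, amp_Hb) {
  if (amp_HbO2 < 0 || amp_Hb < 0) {
    stop("amplitudes must be nonnegative", call. = FALSE)
  }
  if (amp_HbO2 + amp_Hb == 0) {
    warning("both chromophore amplitudes are zero; StO2 undefined")
    return(NA_real_)
  }
  amp_HbO2 / (amp_HbO2 + amp_Hb)
}

#' Fit the attenuation model to an attenuation spectrum
#'
#' Least-squares fit of
#' `A(lambda) = c0 + c1*lambda + c2*lambda^2 + amp_Hb*mu_a_Hb(lambda) +
#' amp_HbO2*mu_a_HbO2(lambda)`
#' with nonnegativity enforced on the two chromophore amplitudes (physical
#' concentrations) and the baseline coefficients free-signed. The mean
#' photon pathlength and molar-extinction scale are lumped into the
#' amplitudes; the reported `sto2` is invariant to that lump. The
#' nonnegativity-constrained solution is found exactly by enumerating the
#' active sets of the two constraints (four candidate least-squares fits).
#'
#' @param A A `drs_attenuation` (from [attenuation_from_intensities()] or
#'   [attenuation_from_reflectance()]), or a numeric vector paired with
#'   `wavelengths`.
#' @param wavelengths Wavelengths when `A` is numeric.
#' @param table A [chromophore_table()].
#' @param poly_degree Baseline polynomial degree 0--2; default 1 for grids
#'   of at most five wavelengths, 2 otherwise.
#' @return An object of class `drs_fit` with components `coefficients`
#'   (`c0`, `c1`, `c2` on the raw nm scale plus `amp_Hb`, `amp_HbO2`),
#'   `sto2`, `residual_norm`, `degrees_used`, `fitted.values`,
#'   `residuals`, `wavelengths` and `A`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `fitted`, `plot`.
#' @examples
#' tab <- chromophore_table()
#' A <- model_attenuation(tab$wavelengths_nm, c0 = 0.2, amp_Hb = 0.3,
#'                        amp_HbO2 = 0.7)
#' fit <- fit_attenuation(A, wavelengths = tab$wavelengths_nm)
#' fit$sto2  # 0.7
#' @export
fit_attenuation <- function(A, wavelengths = NULL,
                            table = chromophore_table(),
                            poly_degree = NULL) {
  if (inherits(A, "drs_attenuation")) {
    wavelengths <- A$wavelength_nm
    a <- A$A
  } else {
    a <- as.numeric(A)
    if (is.null(wavelengths)) {
      stop("wavelengths must be supplied with a numeric attenuation vector",
           call. = FALSE)
    }
  }
  if (!all(is.finite(a))) stop("attenuation values must be finite",
                               call. = FALSE)
  n <- length(a)
  if (is.null(poly_degree)) poly_degree <- if (n <= 5) 1 else 2
  X <- build_design_matrix(wavelengths, table, poly_degree)
  p <- ncol(X)
  if (n == p) {
    warning("square system: as many parameters as wavelengths; the zero ",
            "residual carries no lack-of-fit information")
  }

  amp_cols <- c(p - 1L, p)  # mu_a_Hb, mu_a_HbO2
  best <- NULL
  for (drop_hb in c(FALSE, TRUE)) {
    for (drop_hbo2 in c(FALSE, TRUE)) {
      keep <- rep(TRUE, p)
      if (drop_hb) keep[amp_cols[1]] <- FALSE
      if (drop_hbo2) keep[amp_cols[2]] <- FALSE
      Xs <- X[, keep, drop = FALSE]
      cf <- tryCatch(qr.coef(qr(Xs), a), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) next
      full <- numeric(p)
      full[keep] <- cf
      if (full[amp_cols[1]] < 0 || full[amp_cols[2]] < 0) next
      fitted <- drop(X %*% full)
      rn <- sqrt(sum((a - fitted)^2))
      if (is.null(best) || rn < best$rn - 1e-12) {
        best <- list(beta = full, fitted = fitted, rn = rn)
      }
    }
  }
  if (is.null(best)) stop("attenuation fit failed", call. = FALSE)

  beta <- best$beta
  amp_hb <- max(0, beta[amp_cols[1]])
  amp_hbo2 <- max(0, beta[amp_cols[2]])

  # back-transform the baseline to raw nm wavelengths
  m <- attr(X, "center"); s <- attr(X, "scale")
  ct <- c(beta[1], if (poly_degree >= 1) beta[2] else 0,
          if (poly_degree >= 2) beta[3] else 0)
  c2 <- ct[3] / s^2
  c1 <- ct[2] / s - 2 * ct[3] * m / s^2
  c0 <- ct[1] - ct[2] * m / s + ct[3] * m^2 / s^2

  sto2 <- if (amp_hb + amp_hbo2 > 0) amp_hbo2 / (amp_hb + amp_hbo2)
          else NA_real_

  structure(list(
    coefficients = c(c0 = unname(c0), c1 = unname(c1), c2 = unname(c2),
                     amp_Hb = unname(amp_hb), amp_HbO2 = unname(amp_hbo2)),
    sto2 = sto2,
    sto2_defined = amp_hb + amp_hbo2 > 0,
    residual_norm = best$rn,
    degrees_used = poly_degree,
    fitted.values = best$fitted,
    residuals = a - best$fitted,
    wavelengths = wavelengths,
    A = a,
    table = table
  ), class = "drs_fit")
}

#' @export
print.drs_fit <- function(x, digits = 4, ...) {
  cat("Attenuation-model fit (polynomial baseline + Hb/HbO2 unmixing)\n")
  cat(sprintf("  %d wavelengths, baseline degree %d\n",
              length(x$wavelengths), x$degrees_used))
  print(round(x$coefficients, digits))
  if (x$sto2_defined) {
    cat(sprintf("  StO2 = %.1f%%   residual norm = %.4g\n",
                100 * x$sto2, x$residual_norm))
  } else {
    cat("  StO2 undefined (bloodless spectrum: both amplitudes zero)\n")
  }
  invisible(x)
}

#' @export
coef.drs_fit <- function(object, ...) object$coefficients

#' @export
residuals.drs_fit <- function(object, ...) object$residuals

#' @export
fitted.drs_fit <- function(object, ...) object$fitted.values

#' Predict model attenuation at new wavelengths
#'
#' @param object A `drs_fit`.
#' @param wavelengths Wavelengths in nm on the chromophore grid (default:
#'   the fitted grid).
#' @param ... Unused.
#' @return Numeric attenuation values.
#' @export
predict.drs_fit <- function(object, wavelengths = NULL, ...) {
  if (is.null(wavelengths)) return(object$fitted.values)
  cf <- object$coefficients
  model_attenuation(wavelengths, cf["c0"], cf["c1"], cf["c2"],
                    cf["amp_Hb"], cf["amp_HbO2"], object$table)
}

#' @export
summary.drs_fit <- function(object, ...) {
  out <- list(
    coefficients = object$coefficients,
    sto2 = object$sto2,
    sto2_defined = object$sto2_defined,
    residual_norm = object$residual_norm,
    degrees_used = object$degrees_used,
    n = length(object$wavelengths),
    rmse = sqrt(mean(object$residuals^2))
  )
  class(out) <- "summary.drs_fit"
  out
}

#' @export
print.summary.drs_fit <- function(x, ...) {
  cat("Attenuation-model fit summary\n")
  cat(sprintf("  n = %d wavelengths, baseline degree %d\n", x$n,
              x$degrees_used))
  print(x$coefficients)
  cat(sprintf("  residual norm %.4g, RMSE %.4g\n", x$residual_norm, x$rmse))
  if (x$sto2_defined) cat(sprintf("  StO2 = %.1f%%\n", 100 * x$sto2))
  else cat("  StO2 undefined\n")
  invisible(x)
}

#' Plot an attenuation fit
#'
#' Observed attenuation points with the fitted model overlaid.
#'
#' @param x A `drs_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
#' @importFrom graphics lines legend points
plot.drs_fit <- function(x, ...) {
  plot(x$wavelengths, x$A, xlab = "wavelength (nm)",
       ylab = "attenuation A", pch = 16, ...)
  ord <- order(x$wavelengths)
  lines(x$wavelengths[ord], x$fitted.values[ord], col = "firebrick")
  legend("topright", legend = c("observed", "fitted"),
         pch = c(16, NA), lty = c(NA, 1), col = c("black", "firebrick"),
         bty = "n")
  invisible(x)
}

#' Export a fit as a JSON-ready list
#'
#' @param fit A `drs_fit`.
#' @param band Optional analysis band recorded alongside the fit.
#' @return A plain list: coefficients, `sto2`, `residual_norm`,
#'   `degrees_used`, `band`, `n_points`.
#' @export
fit_result_list <- function(fit, band = NULL) {
  stopifnot(inherits(fit, "drs_fit"))
  list(
    coefficients = as.list(fit$coefficients),
    sto2 = if (fit$sto2_defined) fit$sto2 else NA,
    sto2_defined = fit$sto2_defined,
    residual_norm = fit$residual_norm,
    degrees_used = fit$degrees_used,
    band = band,
    n_points = length(fit$wavelengths)
  )
}
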