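# Vertical-transition bookkeeping and Gaussian-broadened absorption spectra.

#' Vertical electronic transition
#'
#' One vertical excitation: energy in eV, dimensionless oscillator strength,
#' optional transition-dipole vector in Debye, optional stored wavelength in
#' nm (as printed in a source table; the computed wavelength is always
#' `hc / energy`).
#'
#' @param energy Excitation energy, eV (> 0).
#' @param osc_strength Oscillator strength (>= 0).
#' @param tdm Optional numeric length-3 transition-dipole vector, Debye.
#' @param wavelength Optional stored wavelength, nm.
#' @param context Optional [calc_context()].
#' @return An object of class `qc_transition`.
#' @export
transition <- function(energy, osc_strength, tdm = NULL, wavelength = NULL,
                       context = NULL) {
  stopifnot(is.numeric(energy), length(energy) == 1L, is.finite(energy))
  if (energy <= 0) stop("transition energy must be positive (eV)", call. = FALSE)
  stopifnot(is.numeric(osc_strength), length(osc_strength) == 1L,
            is.finite(osc_strength))
  if (osc_strength < 0) stop("oscillator strength must be non-negative", call. = FALSE)
  if (!is.null(tdm)) {
    tdm <- as.numeric(tdm)
    if (length(tdm) != 3L || any(!is.finite(tdm))) {
      stop("`tdm` must be a finite 3-vector (Debye)", call. = FALSE)
    }
  }
  if (!is.null(wavelength)) {
    stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
    wavelength <- as.numeric(wavelength)
  }
  if (!is.null(context)) stopifnot(inherits(context, "calc_context"))
  structure(list(energy = as.numeric(energy), osc_strength = as.numeric(osc_strength),
                 tdm = tdm, wavelength = wavelength, context = context),
            class = "qc_transition")
}

#' @export
print.qc_transition <- function(x, ...) {
  cat(sprintf("<transition> E = %.3f eV (%.1f nm), f = %.3f%s\n",
              x$energy, ev_to_nm(x$energy), x$osc_strength,
              if (!is.null(x$tdm)) sprintf(", |mu01| = %.3f D", tdm_total(x)) else ""))
  invisible(x)
}

#' Total transition dipole moment
#'
#' Euclidean norm of the transition-dipole vector (the "tot" column next to
#' its x, y, z components).
#'
#' @param t A [transition()] with a `tdm`, or a numeric 3-vector in Debye.
#' @return Norm in Debye.
#' @export
#' @examples
#' tdm_total(c(-20.635, 1.344, 0))  # 20.679
tdm_total <- function(t) {
  v <- if (inherits(t, "qc_transition")) {
    if (is.null(t$tdm)) stop("transition has no transition-dipole vector", call. = FALSE)
    t$tdm
  } else {
    as.numeric(t)
  }
  if (length(v) != 3L) stop("`t` must be (or carry) a 3-vector", call. = FALSE)
  sqrt(sum(v^2))
}

#' Oscillator strength from transition energy and dipole
#'
#' The standard length-gauge relation `f = (2/3) * dE[a.u.] * mu^2[a.u.]`,
#' with the energy and transition dipole converted from eV and Debye.  Used
#' to check the internal consistency of tabulated (E01, f, mu01) triples.
#'
#' @param energy Transition energy, eV (> 0).
#' @param tdm_total Total transition dipole, Debye.
#' @return Dimensionless oscillator strength.
#' @export
#' @examples
#' oscillator_strength_from_tdm(2.249, 19.845)  # ~3.36
oscillator_strength_from_tdm <- function(energy, tdm_total) {
  stopifnot(is.numeric(energy), is.numeric(tdm_total))
  if (any(energy <= 0)) stop("transition energy must be positive (eV)", call. = FALSE)
  (2 / 3) * ev_to_hartree(energy) * debye_to_au(tdm_total)^2
}

#' Consistency report for a transition record
#'
#' Recomputes the oscillator strength from the stored energy and
#' transition-dipole norm, and (when a stored wavelength is present) the
#' wavelength from the energy, and compares both against the stored values
#' at a relative tolerance.
#'
#' @param t A [transition()].
#' @param rel_tol Relative tolerance in (0, 1).
#' @return List of class `transition_validation` with stored/computed values,
#'   per-field relative errors and pass flags, the overall `pass`, and
#'   `failed_fields`.
#' @export
validate_transition <- function(t, rel_tol = 0.01) {
  stopifnot(inherits(t, "qc_transition"))
  if (!is.numeric(rel_tol) || rel_tol <= 0 || rel_tol >= 1) {
    stop("`rel_tol` must lie in (0, 1)", call. = FALSE)
  }
  out <- list(rel_tol = rel_tol, failed_fields = character(0))

  if (!is.null(t$tdm)) {
    f_comp <- oscillator_strength_from_tdm(t$energy, tdm_total(t))
    f_err <- abs(f_comp - t$osc_strength) / max(abs(t$osc_strength), 1e-12)
    out$f <- list(stored = t$osc_strength, computed = f_comp,
                  rel_err = f_err, pass = f_err <= rel_tol)
    if (!out$f$pass) out$failed_fields <- c(out$failed_fields, "osc_strength")
  }

  if (!is.null(t$wavelength)) {
    l_comp <- ev_to_nm(t$energy)
    l_err <- abs(l_comp - t$wavelength) / t$wavelength
    out$wavelength <- list(stored = t$wavelength, computed = l_comp,
                           rel_err = l_err, pass = l_err <= rel_tol)
    if (!out$wavelength$pass) out$failed_fields <- c(out$failed_fields, "wavelength")
  }

  out$pass <- length(out$failed_fields) == 0L
  class(out) <- "transition_validation"
  out
}

#' @export
print.transition_validation <- function(x, ...) {
  cat(sprintf("<transition_validation> %s (rel_tol %.3g)\n",
              if (x$pass) "PASS" else paste("FAIL:", paste(x$failed_fields, collapse = ", ")),
              x$rel_tol))
  invisible(x)
}

#' Spectrum curve
#'
#' A sampled absorption curve: strictly monotone axis (nm or eV) with
#' non-negative intensities.
#'
#' @param axis Numeric grid, strictly monotone.
#' @param intensity Non-negative numeric vector, same length.
#' @param axis_kind `"wavelength"` (nm) or `"energy"` (eV).
#' @return An object of class `spectrum_curve`.
#' @export
spectrum_curve <- function(axis, intensity, axis_kind = c("wavelength", "energy")) {
  axis_kind <- match.arg(axis_kind)
  axis <- as.numeric(axis); intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity) || length(axis) < 2L) {
    stop("`axis` and `intensity` must have equal length >= 2", call. = FALSE)
  }
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) stop("`axis` must be strictly monotone", call. = FALSE)
  if (any(intensity < 0) || any(!is.finite(intensity))) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  structure(list(axis = axis, intensity = intensity, axis_kind = axis_kind),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf("<spectrum_curve> %d points on %s axis [%.4g, %.4g], max intensity %.4g\n",
              length(x$axis), x$axis_kind, min(x$axis), max(x$axis), max(x$intensity)))
  invisible(x)
}

#' @export
as.data.frame.spectrum_curve <- function(x, ...) {
  data.frame(axis = x$axis, intensity = x$intensity)
}

#' Gaussian-broadened absorption spectrum from vertical transitions
#'
#' Convolves the vertical transition energies with Gaussian lineshapes of
#' full width at half maximum `fwhm` (default 0.37 eV), each weighted by its
#' oscillator strength:
#' `I(E) = sum_n f_n * exp(-(E - E_n)^2 / (2 sigma^2))` with
#' `sigma = fwhm / (2 sqrt(2 ln 2))`.
#'
#' Broadening always happens on the energy axis.  For a wavelength-axis
#' curve the grid is mapped pointwise through `E = hc / lambda` and, by
#' default, *not* Jacobian-reweighted, so a single transition peaks exactly
#' at `lambda01 = hc / E01` and the curve matches the usual presentation of
#' TDDFT stick spectra; `jacobian = TRUE` applies the rigorous
#' `dE/dlambda = hc / lambda^2` weight instead.
#'
#' Every transition energy must lie inside the grid (error otherwise); a
#' transition whose `+- 3 fwhm` wing is truncated by the grid only triggers
#' a warning, since wide plotting windows routinely clip the far wings.
#'
#' @param transitions A [transition()] or list of them.
#' @param fwhm Full width at half maximum, eV (> 0).
#' @param from,to,n Grid specification on the `axis` scale (defaults:
#'   300–800 nm, 2000 points).
#' @param axis `"wavelength"` (nm grid) or `"energy"` (eV grid).
#' @param normalize Scale the curve to a maximum of 1 (default `TRUE`).
#' @param jacobian Apply the energy-to-wavelength Jacobian weight
#'   (wavelength axis only).
#' @return A [spectrum_curve()].
#' @export
#' @examples
#' tr <- transition(2.317, 3.403)
#' s <- broaden_spectrum(tr)
#' peak_wavelength(s)  # ~535.1 nm
broaden_spectrum <- function(transitions, fwhm = 0.37, from = NULL, to = NULL,
                             n = 2000L, axis = c("wavelength", "energy"),
                             normalize = TRUE, jacobian = FALSE) {
  axis <- match.arg(axis)
  if (inherits(transitions, "qc_transition")) transitions <- list(transitions)
  if (!is.list(transitions) || length(transitions) == 0L ||
      !all(vapply(transitions, inherits, logical(1), "qc_transition"))) {
    stop("`transitions` must be a non-empty list of transition objects", call. = FALSE)
  }
  stopifnot(is.numeric(fwhm), length(fwhm) == 1L, fwhm > 0)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (is.null(from)) from <- if (axis == "wavelength") 300 else 1.2
  if (is.null(to)) to <- if (axis == "wavelength") 800 else 4.5
  if (!(from < to)) stop("`from` must be smaller than `to`", call. = FALSE)

  grid <- seq(from, to, length.out = n)
  e_grid <- if (axis == "wavelength") nm_to_ev(grid) else grid

  e_n <- vapply(transitions, `[[`, numeric(1), "energy")
  f_n <- vapply(transitions, `[[`, numeric(1), "osc_strength")
  e_lo <- min(e_grid); e_hi <- max(e_grid)
  if (any(e_n < e_lo) || any(e_n > e_hi)) {
    stop(sprintf(
      "grid does not cover the transitions: energies span [%.3f, %.3f] eV, grid [%.3f, %.3f] eV",
      min(e_n), max(e_n), e_lo, e_hi), call. = FALSE)
  }
  if (any(e_n - 3 * fwhm < e_lo) || any(e_n + 3 * fwhm > e_hi)) {
    warning("grid truncates the +-3*FWHM wing of at least one transition",
            call. = FALSE)
  }

  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  intensity <- rep(0, n)
  for (m in seq_along(e_n)) {
    intensity <- intensity + f_n[m] * exp(-(e_grid - e_n[m])^2 / (2 * sigma^2))
  }
  if (axis == "wavelength" && jacobian) {
    intensity <- intensity * unit_constants()$hc_ev_nm / grid^2
  }
  if (normalize && max(intensity) > 0) intensity <- intensity / max(intensity)

  spectrum_curve(grid, intensity, axis_kind = axis)
}

#' Axis position of the spectrum's global maximum
#'
#' Returns the wavelength (nm) or energy (eV) at which the intensity is
#' largest.  Exact ties are broken toward the lower energy (longer
#' wavelength) with a warning; a flat all-zero spectrum is an error.
#'
#' @param s A [spectrum_curve()].
#' @return Axis value of the maximum.
#' @export
peak_wavelength <- function(s) {
  stopifnot(inherits(s, "spectrum_curve"))
  mx <- max(s$intensity)
  if (mx <= 0) stop("flat zero spectrum has no peak", call. = FALSE)
  at <- which(s$intensity == mx)
  if (length(at) > 1L) {
    warning(sprintf("tie between %d grid points at the maximum; choosing the %s",
                    length(at),
                    if (s$axis_kind == "wavelength") "longest wavelength"
                    else "lowest energy"), call. = FALSE)
    at <- if (s$axis_kind == "wavelength") at[which.max(s$axis[at])]
          else at[which.min(s$axis[at])]
  }
  s$axis[at]
}

#' Solvent-induced wavelength shift of a transition
#'
#' `lambda01(solvated) - lambda01(gas)` in nm for the same molecule,
#' functional and basis; positive means a red shift.  Stored wavelengths are
#' used when both transitions carry them, otherwise `hc / E01`.
#'
#' @param gas Transition computed in gas phase.
#' @param solvated Transition computed in a solvent medium.
#' @return Shift in nm (positive = red shift).
#' @export
solvent_shift <- function(gas, solvated) {
  stopifnot(inherits(gas, "qc_transition"), inherits(solvated, "qc_transition"))
  if (!is.null(gas$context) || !is.null(solvated$context)) {
    if (!.same_context(gas$context, solvated$context, c("functional", "basis"))) {
      stop("context mismatch: transitions must share functional and basis",
           call. = FALSE)
    }
    if (!is.null(gas$context) && !identical(gas$context$medium, "gas")) {
      stop("`gas` transition is not tagged with the gas medium", call. = FALSE)
    }
  }
  lam <- function(t) if (!is.null(gas$wavelength) && !is.null(solvated$wavelength))
    t$wavelength else ev_to_nm(t$energy)
  lam(solvated) - lam(gas)
}
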