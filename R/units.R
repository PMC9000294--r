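# Physical constants and unit conversions shared by every module.
# CODATA-derived values; all other files convert through these, never
# through locally repeated literals.
.qc_units <- list(
  hc_ev_nm          = 1239.84193,   # h*c, eV * nm
  ev_per_hartree    = 27.211386,    # eV / hartree
  debye_per_au      = 2.5417464,    # Debye / atomic unit of dipole
  alpha_esu_per_au  = 0.1481847,    # polarizability, 1 a.u. on the 1e-24 esu scale
  beta_esu_per_au   = 8.639418e-3,  # first hyperpolarizability, 1 a.u. on the 1e-30 esu scale
  wavenumber_per_ev = 8065.544      # cm^-1 / eV
)

#' Physical constants used by the toolkit
#'
#' Returns the read-only set of conversion constants every other function in
#' the package routes through: the eV–nm product `hc_ev_nm`, hartree-to-eV,
#' a.u.-to-Debye for dipoles, the esu reporting scales for the polarizability
#' (10^-24 esu) and first hyperpolarizability (10^-30 esu), and the
#' eV-to-wavenumber factor.
#'
#' Note the Gaussian broadening default of 0.37 eV corresponds to
#' 2984.3 cm^-1, not the round 3000 cm^-1 it is often quoted alongside; the
#' 0.37 eV figure is treated as authoritative throughout (see the package
#' vignette).
#'
#' @return Named list of positive numeric constants.
#' @export
#' @examples
#' unit_constants()$hc_ev_nm
unit_constants <- function() .qc_units

.check_numeric <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
}

#' Convert photon energy in eV to wavelength in nm
#'
#' Uses lambda = hc / E with hc = 1239.84193 eV nm, the relation tying a
#' vertical transition energy E01 to its absorption wavelength lambda01.
#'
#' @param energy Photon energy in eV; must be strictly positive.
#' @return Wavelength in nm.
#' @export
#' @examples
#' ev_to_nm(2.317)  # ~535.1 nm
ev_to_nm <- function(energy) {
  .check_numeric(energy, "energy")
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop("`energy` must be finite and strictly positive (eV)", call. = FALSE)
  }
  .qc_units$hc_ev_nm / energy
}

#' Convert wavelength in nm to photon energy in eV
#'
#' Inverse of [ev_to_nm()].
#'
#' @param wavelength Wavelength in nm; strictly positive.
#' @return Energy in eV.
#' @export
nm_to_ev <- function(wavelength) {
  .check_numeric(wavelength, "wavelength")
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    stop("`wavelength` must be finite and strictly positive (nm)", call. = FALSE)
  }
  .qc_units$hc_ev_nm / wavelength
}

#' Convert energy in eV to wavenumbers
#'
#' @param energy Energy in eV (any finite value; 0 maps to 0).
#' @return Wavenumber in cm^-1.
#' @export
#' @examples
#' ev_to_wavenumber(0.37)  # 2984.3 cm^-1
ev_to_wavenumber <- function(energy) {
  .check_numeric(energy, "energy")
  if (any(!is.finite(energy))) stop("`energy` must be finite", call. = FALSE)
  energy * .qc_units$wavenumber_per_ev
}

#' Convert a dipole moment between Debye and atomic units
#'
#' 1 a.u. of electric dipole = 2.5417464 Debye.
#'
#' @param dipole Dipole moment (Debye for `debye_to_au`, a.u. for
#'   `au_to_debye`).
#' @return Converted dipole moment.
#' @export
debye_to_au <- function(dipole) {
  .check_numeric(dipole, "dipole")
  dipole / .qc_units$debye_per_au
}

#' @rdname debye_to_au
#' @export
au_to_debye <- function(dipole) {
  .check_numeric(dipole, "dipole")
  dipole * .qc_units$debye_per_au
}

#' Convert energy between hartree and eV
#'
#' @param energy Energy (hartree for `hartree_to_ev`, eV for `ev_to_hartree`).
#' @return Converted energy.
#' @export
hartree_to_ev <- function(energy) {
  .check_numeric(energy, "energy")
  energy * .qc_units$ev_per_hartree
}

#' @rdname hartree_to_ev
#' @export
ev_to_hartree <- function(energy) {
  .check_numeric(energy, "energy")
  energy / .qc_units$ev_per_hartree
}

#' Convert (hyper)polarizability values from atomic units to esu scales
#'
#' Polarizabilities are reported on the 10^-24 esu scale
#' (1 a.u. = 0.1481847 x 10^-24 esu) and first hyperpolarizabilities on the
#' 10^-30 esu scale (1 a.u. = 8.639418 x 10^-3 x 10^-30 esu), matching the
#' conventional column headers "alpha (10^-24 esu)" and "beta (10^-30 esu)".
#'
#' @param value Numeric value(s) in atomic units.
#' @param kind One of `"polarizability"` or `"hyperpolarizability"`.
#' @return Value on the corresponding esu reporting scale.
#' @export
#' @examples
#' tensor_au_to_esu(1, "polarizability")        # 0.1481847
#' tensor_au_to_esu(1000, "polarizability")     # 148.18
tensor_au_to_esu <- function(value, kind = c("polarizability", "hyperpolarizability")) {
  .check_numeric(value, "value")
  kind <- match.arg(kind)
  if (kind == "polarizability") value * .qc_units$alpha_esu_per_au
  else value * .qc_units$beta_esu_per_au
}

#' @rdname tensor_au_to_esu
#' @export
tensor_esu_to_au <- function(value, kind = c("polarizability", "hyperpolarizability")) {
  .check_numeric(value, "value")
  kind <- match.arg(kind)
  if (kind == "polarizability") value / .qc_units$alpha_esu_per_au
  else value / .qc_units$beta_esu_per_au
}
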