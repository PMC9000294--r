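# Frontier-orbital bookkeeping: HOMO/LUMO gap, Koopmans estimates, and
# cross-functional / cis-trans comparisons.

#' Frontier-orbital summary
#'
#' HOMO and LUMO energies in eV (negative for bound orbitals) under a
#' calculation context.  A record with `homo >= lumo` is physically
#' suspect; it is flagged via the `"suspect"` attribute rather than
#' rejected or silently repaired.
#'
#' @param homo HOMO energy, eV.
#' @param lumo LUMO energy, eV.
#' @param context Optional [calc_context()].
#' @return An object of class `electronic_summary`.
#' @export
electronic_summary <- function(homo, lumo, context = NULL) {
  stopifnot(is.numeric(homo), length(homo) == 1L, is.finite(homo),
            is.numeric(lumo), length(lumo) == 1L, is.finite(lumo))
  if (!is.null(context)) stopifnot(inherits(context, "calc_context"))
  out <- structure(list(homo = as.numeric(homo), lumo = as.numeric(lumo),
                        context = context),
                   class = "electronic_summary")
  attr(out, "suspect") <- homo >= lumo
  out
}

#' @export
print.electronic_summary <- function(x, ...) {
  cat(sprintf("<electronic_summary> HOMO %.3f eV, LUMO %.3f eV, gap %.3f eV%s\n",
              x$homo, x$lumo, x$lumo - x$homo,
              if (isTRUE(attr(x, "suspect"))) " [suspect: HOMO >= LUMO]" else ""))
  invisible(x)
}

#' HOMO–LUMO gap
#'
#' `lumo - homo` in eV.  When `homo >= lumo` the gap is still returned but
#' carries a `"warning"` attribute describing the anomaly.
#'
#' @param s An [electronic_summary()].
#' @return Gap in eV (possibly with a `"warning"` attribute).
#' @export
#' @examples
#' homo_lumo_gap(electronic_summary(-6.360, -1.853))  # 4.507
homo_lumo_gap <- function(s) {
  stopifnot(inherits(s, "electronic_summary"))
  gap <- s$lumo - s$homo
  if (s$homo >= s$lumo) {
    attr(gap, "warning") <- sprintf(
      "HOMO (%.3f eV) >= LUMO (%.3f eV): non-positive gap returned as-is",
      s$homo, s$lumo)
  }
  gap
}

#' Koopmans estimates of ionization potential and electron affinity
#'
#' To first approximation the ionization potential is `-E(HOMO)` and the
#' electron affinity `-E(LUMO)`.
#'
#' @param s An [electronic_summary()].
#' @return Named numeric vector `c(ip = , ea = )` in eV.
#' @export
#' @examples
#' koopmans_estimates(electronic_summary(-5.221, -3.073))
koopmans_estimates <- function(s) {
  stopifnot(inherits(s, "electronic_summary"))
  c(ip = -s$homo, ea = -s$lumo)
}

#' Gap ordering across functionals
#'
#' Sorts one molecule/medium's per-functional summaries by gap and checks
#' whether the ordering follows increasing Hartree–Fock exchange
#' contribution, B3LYP < M06 < CAM-B3LYP.  Ties within `tie_tol` fail the
#' check and are reported.
#'
#' @param records Named list of [electronic_summary()], one per functional;
#'   names (or contexts) must cover `expected` exactly once each.
#' @param expected Expected gap ordering, smallest first.
#' @param tie_tol Gaps closer than this (eV) count as tied.
#' @return List with `ordering` (functionals sorted by gap), `gaps`, `pass`,
#'   and `ties` (character description, empty if none).
#' @export
functional_gap_ordering <- function(records,
                                    expected = c("B3LYP", "M06", "CAM-B3LYP"),
                                    tie_tol = 0.001) {
  stopifnot(is.list(records))
  labels <- names(records)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(records, function(r) {
      if (is.null(r$context)) NA_character_ else r$context$functional
    }, character(1))
  }
  if (anyNA(labels)) stop("each record needs a functional label", call. = FALSE)
  missing <- setdiff(expected, labels)
  if (length(missing)) {
    stop(sprintf("missing functional(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("duplicate functional records", call. = FALSE)
  gaps <- vapply(records, function(r) as.numeric(homo_lumo_gap(r)), numeric(1))
  names(gaps) <- labels
  ord <- labels[order(gaps)]
  sorted <- sort(gaps)
  tie_pairs <- which(diff(sorted) <= tie_tol)
  ties <- if (length(tie_pairs)) {
    sprintf("tie between %s and %s (gaps within %.3f eV)",
            names(sorted)[tie_pairs], names(sorted)[tie_pairs + 1L], tie_tol)
  } else character(0)
  pass <- identical(ord, expected) && length(ties) == 0L
  list(ordering = ord, gaps = gaps, pass = pass, ties = ties)
}

#' Cis vs trans gap comparison
#'
#' Signed gap difference `gap(cis) - gap(trans)` for two summaries at the
#' same functional/basis/medium; the flag is `TRUE` when the cis conformer's
#' gap is the larger one (the expected behaviour: the all-trans conformer is
#' energetically more stable and has the smaller gap).
#'
#' @param cis,trans [electronic_summary()] objects with matching contexts.
#' @return List with `difference` (eV) and `cis_higher` flag.
#' @export
cis_trans_gap_comparison <- function(cis, trans) {
  stopifnot(inherits(cis, "electronic_summary"), inherits(trans, "electronic_summary"))
  if (!is.null(cis$context) || !is.null(trans$context)) {
    if (!.same_context(cis$context, trans$context)) {
      stop("context mismatch: cis and trans records must share functional/basis/medium",
           call. = FALSE)
    }
  }
  d <- as.numeric(homo_lumo_gap(cis)) - as.numeric(homo_lumo_gap(trans))
  list(difference = d, cis_higher = d > 0)
}
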