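# Readers/writers: XYZ geometries, qcsum/1 JSON summary records, and the
# packaged reference benchmark tables.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

.known_dielectrics <- c(gas = 1.00, chloroform = 4.71)

#' Calculation context metadata
#'
#' Tags a result with the level of theory and medium it was obtained at.
#' The medium is metadata only — no solvation model is evaluated here; the
#' dielectric defaults to 1.00 for `"gas"` and 4.71 for `"chloroform"`.
#'
#' @param functional Exchange-correlation functional label, e.g. `"B3LYP"`,
#'   `"CAM-B3LYP"`, `"M06"`.
#' @param basis Basis-set label, e.g. `"6-31+G(d,p)"`.
#' @param medium Medium label; `"gas"` and `"chloroform"` carry known
#'   dielectrics, any other label requires `dielectric`.
#' @param dielectric Relative permittivity; inferred for known media.
#' @return An object of class `calc_context`.
#' @export
#' @examples
#' calc_context("CAM-B3LYP", "6-31+G(d,p)", "chloroform")
calc_context <- function(functional = NA_character_, basis = NA_character_,
                         medium = "gas", dielectric = NULL) {
  stopifnot(is.character(medium), length(medium) == 1L)
  if (is.null(dielectric)) {
    if (medium %in% names(.known_dielectrics)) {
      dielectric <- unname(.known_dielectrics[[medium]])
    } else {
      stop(sprintf("unknown medium '%s': supply `dielectric` explicitly", medium),
           call. = FALSE)
    }
  }
  if (medium %in% names(.known_dielectrics) &&
      abs(dielectric - .known_dielectrics[[medium]]) > 1e-9) {
    stop(sprintf("medium '%s' implies dielectric %.2f, got %.4f",
                 medium, .known_dielectrics[[medium]], dielectric), call. = FALSE)
  }
  structure(
    list(functional = as.character(functional), basis = as.character(basis),
         medium = medium, dielectric = as.numeric(dielectric)),
    class = "calc_context"
  )
}

#' @export
print.calc_context <- function(x, ...) {
  cat(sprintf("<calc_context> %s/%s in %s (eps = %.2f)\n",
              x$functional, x$basis, x$medium, x$dielectric))
  invisible(x)
}

.same_context <- function(a, b, fields = c("functional", "basis", "medium")) {
  if (is.null(a) || is.null(b)) return(FALSE)
  all(vapply(fields, function(f) identical(a[[f]], b[[f]]), logical(1)))
}

## ---- XYZ ------------------------------------------------------------------

#' Read a molecular geometry from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `element x y z` line per atom (coordinates in Angstrom).  The comment line
#' may carry `key=value` metadata; `label=` and `medium=` are recognised and
#' stored on the returned geometry.
#'
#' @param path Path to an XYZ file.
#' @return A [molecule_geometry()] object.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error: fewer than 2 lines", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n <= 0L) {
    stop("XYZ parse error at line 1: atom count must be a positive integer",
         call. = FALSE)
  }
  if (length(lines) < 2L + n) {
    stop(sprintf("XYZ parse error: declared %d atoms but only %d body lines",
                 n, max(0L, length(lines) - 2L)), call. = FALSE)
  }
  extra <- lines[seq_len(length(lines) - 2L - n) + 2L + n]
  if (length(extra) && any(nzchar(trimws(extra)))) {
    stop(sprintf("XYZ parse error: declared %d atoms but found extra body lines", n),
         call. = FALSE)
  }

  comment <- lines[2L]
  meta <- .parse_key_values(comment)

  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (a in seq_len(n)) {
    ln <- 2L + a
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L) {
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ln),
           call. = FALSE)
    }
    if (!tok[1L] %in% .element_symbols) {
      stop(sprintf("XYZ parse error at line %d: unknown element '%s'", ln, tok[1L]),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)) || any(!is.finite(xyz))) {
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln),
           call. = FALSE)
    }
    elements[a] <- tok[1L]
    coords[a, ] <- xyz
  }

  ctx <- NULL
  if (!is.null(meta[["medium"]])) ctx <- calc_context(medium = meta[["medium"]])
  molecule_geometry(elements, coords,
                    label = if (is.null(meta[["label"]])) "" else meta[["label"]],
                    context = ctx)
}

.parse_key_values <- function(line) {
  out <- list()
  for (tok in strsplit(trimws(line), "\\s+")[[1L]]) {
    if (grepl("=", tok, fixed = TRUE)) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
      if (length(kv) == 2L && nzchar(kv[1L])) out[[kv[1L]]] <- kv[2L]
    }
  }
  out
}

#' Write a molecular geometry to an XYZ file
#'
#' Inverse of [read_xyz()]; the label and medium (when present) are stored as
#' `key=value` pairs on the comment line so that a write/read round trip
#' preserves them.
#'
#' @param geom A [molecule_geometry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geom, path) {
  stopifnot(inherits(geom, "molecule_geometry"))
  n <- length(geom$elements)
  comment <- character(0)
  if (nzchar(geom$label)) comment <- c(comment, paste0("label=", geom$label))
  if (!is.null(geom$context)) comment <- c(comment, paste0("medium=", geom$context$medium))
  body <- sprintf("%-2s %18.12f %18.12f %18.12f",
                  geom$elements, geom$coords[, 1L], geom$coords[, 2L], geom$coords[, 3L])
  writeLines(c(as.character(n), paste(comment, collapse = " "), body), path)
  invisible(path)
}

## ---- qcsum/1 records ------------------------------------------------------

.energy_to_ev <- function(value, unit, what) {
  if (is.null(unit)) stop(sprintf("qcsum schema error: %s is missing its unit tag", what), call. = FALSE)
  switch(unit,
         eV = value,
         hartree = hartree_to_ev(value),
         stop(sprintf("qcsum schema error: unknown energy unit '%s' for %s", unit, what),
              call. = FALSE))
}

.dipole_to_debye <- function(value, unit, what) {
  if (is.null(unit)) stop(sprintf("qcsum schema error: %s is missing its unit tag", what), call. = FALSE)
  switch(unit,
         debye = value,
         au = au_to_debye(value),
         stop(sprintf("qcsum schema error: unknown dipole unit '%s' for %s", unit, what),
              call. = FALSE))
}

.require_au <- function(unit, what) {
  if (is.null(unit)) stop(sprintf("qcsum schema error: %s is missing its unit tag", what), call. = FALSE)
  if (!identical(unit, "au")) {
    stop(sprintf("qcsum schema error: %s must be tagged 'au', got '%s'", what, unit),
         call. = FALSE)
  }
}

#' Quantum-chemistry summary record
#'
#' Container for the post-processable content of one calculation: an optional
#' [electronic_summary()], an optional [nlo_tensor_set()], and an optional
#' list of [transition()] objects, under one [calc_context()].  At least one
#' section must be present.
#'
#' @param label Molecule label.
#' @param context A [calc_context()].
#' @param electronic Optional [electronic_summary()].
#' @param nlo Optional [nlo_tensor_set()].
#' @param transitions Optional list of [transition()] objects.
#' @return An object of class `qc_record`.
#' @export
qc_record <- function(label, context, electronic = NULL, nlo = NULL,
                      transitions = NULL) {
  stopifnot(inherits(context, "calc_context"))
  if (is.null(electronic) && is.null(nlo) && is.null(transitions)) {
    stop("qc_record needs at least one of electronic, nlo, transitions", call. = FALSE)
  }
  if (!is.null(electronic)) stopifnot(inherits(electronic, "electronic_summary"))
  if (!is.null(nlo)) stopifnot(inherits(nlo, "nlo_tensor_set"))
  if (!is.null(transitions)) {
    stopifnot(is.list(transitions),
              all(vapply(transitions, inherits, logical(1), "qc_transition")))
  }
  structure(
    list(label = as.character(label), context = context,
         electronic = electronic, nlo = nlo, transitions = transitions),
    class = "qc_record"
  )
}

#' Read a qcsum/1 summary record
#'
#' The qcsum/1 schema is a small JSON dialect for engine-agnostic exchange of
#' post-processable quantities.  Every numeric block carries an explicit unit
#' tag (`"eV"`/`"hartree"` for energies, `"au"`/`"debye"` for dipoles, `"au"`
#' for tensors); on read, all values are converted to the package's canonical
#' internal units — eV for orbital and transition energies, atomic units for
#' the NLO tensors, Debye for transition dipoles.  Missing sections stay
#' absent; a missing or unknown unit tag, or a tensor of the wrong shape, is
#' a schema error.
#'
#' @param path Path to a qcsum/1 JSON file.
#' @return A [qc_record()].
#' @export
read_qc_record <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(x$format, "qcsum/1")) {
    stop("qcsum schema error: missing or unsupported 'format' (expected \"qcsum/1\")",
         call. = FALSE)
  }
  ctx <- calc_context(
    functional = if (is.null(x$context$functional)) NA_character_ else x$context$functional,
    basis = if (is.null(x$context$basis)) NA_character_ else x$context$basis,
    medium = if (is.null(x$context$medium)) "gas" else x$context$medium,
    dielectric = x$context$dielectric
  )

  electronic <- NULL
  if (!is.null(x$electronic)) {
    e <- x$electronic
    electronic <- electronic_summary(
      homo = .energy_to_ev(e$homo$value, e$homo$unit, "electronic$homo"),
      lumo = .energy_to_ev(e$lumo$value, e$lumo$unit, "electronic$lumo"),
      context = ctx
    )
  }

  nlo <- NULL
  if (!is.null(x$nlo)) {
    b <- x$nlo
    .require_au(b$mu$unit, "nlo$mu")
    .require_au(b$alpha$unit, "nlo$alpha")
    .require_au(b$beta$unit, "nlo$beta")
    mu <- as.numeric(b$mu$value)
    if (length(mu) != 3L) stop("qcsum schema error: nlo$mu must be a 3-vector", call. = FALSE)
    alpha <- .as_matrix33(b$alpha$value, "nlo$alpha")
    beta <- .parse_beta_value(b$beta$value)
    nlo <- nlo_tensor_set(mu, alpha, beta, context = ctx)
  }

  transitions <- NULL
  if (!is.null(x$transitions)) {
    transitions <- lapply(seq_along(x$transitions), function(i) {
      tr <- x$transitions[[i]]
      what <- sprintf("transitions[[%d]]", i)
      tdm <- NULL
      if (!is.null(tr$tdm)) {
        tdm <- .dipole_to_debye(as.numeric(tr$tdm$value), tr$tdm$unit,
                                paste0(what, "$tdm"))
        if (length(tdm) != 3L) {
          stop(sprintf("qcsum schema error: %s$tdm must be a 3-vector", what),
               call. = FALSE)
        }
      }
      transition(
        energy = .energy_to_ev(tr$energy$value, tr$energy$unit, paste0(what, "$energy")),
        osc_strength = tr$osc_strength,
        tdm = tdm,
        wavelength = if (is.null(tr$wavelength)) NULL else tr$wavelength$value,
        context = ctx
      )
    })
  }

  qc_record(label = if (is.null(x$label)) "" else x$label, context = ctx,
            electronic = electronic, nlo = nlo, transitions = transitions)
}

.as_matrix33 <- function(v, what) {
  if (is.list(v)) {
    if (length(v) != 3L || any(vapply(v, length, integer(1)) != 3L)) {
      stop(sprintf("qcsum schema error: %s must be 3x3", what), call. = FALSE)
    }
    v <- do.call(rbind, lapply(v, as.numeric))
  }
  if (!is.matrix(v) || !all(dim(v) == c(3L, 3L))) {
    stop(sprintf("qcsum schema error: %s must be 3x3", what), call. = FALSE)
  }
  storage.mode(v) <- "double"
  v
}

.parse_beta_value <- function(v) {
  if (is.array(v) && length(dim(v)) == 3L) {
    if (!all(dim(v) == 3L)) stop("qcsum schema error: nlo$beta array must be 3x3x3", call. = FALSE)
    return(v)
  }
  if (is.list(v) && !is.null(names(v)) && length(names(v)) > 0L) {
    return(unlist(v))  # Kleinman-unique named components
  }
  # jsonlite renders a 3x3x3 JSON nesting as a list of 3x3 matrices
  if (is.list(v) && length(v) == 3L &&
      all(vapply(v, function(m) is.matrix(m) && all(dim(m) == c(3L, 3L)), logical(1)))) {
    arr <- array(0, c(3L, 3L, 3L))
    for (i in 1:3) arr[i, , ] <- v[[i]]
    return(arr)
  }
  stop("qcsum schema error: nlo$beta must be a 3x3x3 array or named Kleinman components",
       call. = FALSE)
}

#' Write a qcsum/1 summary record
#'
#' Serialises a [qc_record()] to the qcsum/1 JSON schema in canonical units
#' (eV, a.u., Debye) with explicit unit tags.  `read_qc_record()` of the
#' result reproduces the record.
#'
#' @param record A [qc_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_record <- function(record, path) {
  stopifnot(inherits(record, "qc_record"))
  out <- list(format = "qcsum/1", label = record$label,
              context = record$context[c("functional", "basis", "medium", "dielectric")])
  if (!is.null(record$electronic)) {
    out$electronic <- list(
      homo = list(value = record$electronic$homo, unit = "eV"),
      lumo = list(value = record$electronic$lumo, unit = "eV")
    )
  }
  if (!is.null(record$nlo)) {
    n <- record$nlo
    out$nlo <- list(
      mu = list(value = n$mu, unit = "au"),
      alpha = list(value = n$alpha, unit = "au"),
      beta = list(value = lapply(1:3, function(i) n$beta[i, , ]), unit = "au")
    )
  }
  if (!is.null(record$transitions)) {
    out$transitions <- lapply(record$transitions, function(tr) {
      o <- list(energy = list(value = tr$energy, unit = "eV"),
                osc_strength = tr$osc_strength)
      if (!is.null(tr$tdm)) o$tdm <- list(value = tr$tdm, unit = "debye")
      if (!is.null(tr$wavelength)) o$wavelength <- list(value = tr$wavelength, unit = "nm")
      o
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- packaged reference tables -------------------------------------------

#' Load a packaged reference benchmark table
#'
#' Transcriptions of published DFT/TDDFT benchmark values for the four
#' achiote dyes (bixin, isobixin, norbixin, isonorbixin) at the B3LYP,
#' CAM-B3LYP and M06 functionals with the 6-31+G(d,p) basis set:
#'
#' * `"bla"` — total bond-length alternation (Angstrom), gas + chloroform,
#'   24 rows;
#' * `"electronic"` — HOMO/LUMO/gap (eV), chloroform, 12 rows.  One row
#'   (isonorbixin/CAM-B3LYP) carries a sign misprint in its published LUMO;
#'   the table keeps the printed value and adds `lumo_corrected` plus an
#'   `erratum` flag (the printed gap requires the negative sign);
#' * `"nlo"` — dipole moment (Debye), mean polarizability (10^-24 esu) and
#'   beta-vector (10^-30 esu), gas + chloroform, 24 rows;
#' * `"transitions"` — S0->S1 vertical energy (eV), wavelength (nm),
#'   oscillator strength and transition-dipole components/total (Debye),
#'   gas + chloroform, 24 rows.
#'
#' Values are stored exactly as printed; these tables are fixtures and trend
#' targets, not recomputable outputs (the underlying raw tensors and
#' wavefunctions are not published).
#'
#' @param table One of `"bla"`, `"electronic"`, `"nlo"`, `"transitions"`.
#' @return A data frame keyed by molecule, functional, basis, medium.
#' @export
#' @examples
#' head(load_reference_table("electronic"))
load_reference_table <- function(table = c("bla", "electronic", "nlo", "transitions")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, "_table.csv"), package = "polyeneQC",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("erratum" %in% names(df)) df$erratum <- as.logical(df$erratum)
  df
}

#' Canonical synthetic backbone path fixture
#'
#' Returns the packaged conjugation path for the 18-carbon synthetic polyene
#' analogue (9 double, 8 single bonds), matching the default output of
#' [gen_polyene()].
#'
#' @return A [conjugation_path()].
#' @export
reference_backbone_path <- function() {
  read_path_file(system.file("extdata", "polyene_c18_backbone.path",
                             package = "polyeneQC", mustWork = TRUE))
}
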