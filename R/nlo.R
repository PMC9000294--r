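# Scalar nonlinear-optical invariants from raw tensors.
#
# The three experimentally quoted scalars are the dipole magnitude
# mu = |mu_vec|, the mean polarizability alpha-bar = tr(alpha)/3, and the
# beta-vector projection of the first hyperpolarizability,
# beta_vec = sum_i beta_i mu_i / |mu| with beta_i = sum_k beta_ikk.

.beta_axis <- c("x", "y", "z")

# canonical name of a Kleinman-unique component: sorted index letters
.beta_component_name <- function(i, j, k) {
  paste(sort(c(.beta_axis[i], .beta_axis[j], .beta_axis[k])), collapse = "")
}

.kleinman_names <- c("xxx", "xxy", "xxz", "xyy", "xyz", "xzz",
                     "yyy", "yyz", "yzz", "zzz")

# Expand 10 named Kleinman-unique components to the full 3x3x3 array.
.expand_kleinman <- function(v) {
  nm <- names(v)
  nm_sorted <- vapply(strsplit(nm, ""), function(s) paste(sort(s), collapse = ""),
                      character(1))
  if (anyNA(v) || is.null(nm) || !all(nm_sorted %in% .kleinman_names) ||
      anyDuplicated(nm_sorted)) {
    stop("Kleinman beta components must be uniquely named from {xxx, xxy, ..., zzz}",
         call. = FALSE)
  }
  full <- setdiff(.kleinman_names, nm_sorted)
  vals <- stats::setNames(rep(0, 10L), .kleinman_names)
  vals[nm_sorted] <- as.numeric(v)
  arr <- array(0, c(3L, 3L, 3L))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    arr[i, j, k] <- vals[[.beta_component_name(i, j, k)]]
  }
  arr
}

# Max deviation of a 3x3x3 array from full (Kleinman) index-permutation
# symmetry, relative to the largest component.
.kleinman_violation <- function(beta) {
  scale <- max(abs(beta), 1e-300)
  dev <- 0
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    dev <- max(dev, max(abs(beta - aperm(beta, p))))
  }
  dev / scale
}

#' NLO tensor set
#'
#' Dipole vector, 3x3 polarizability and first-hyperpolarizability input for
#' the scalar invariants, all in atomic units.  `beta` is accepted either as
#' a full 3x3x3 array or as named Kleinman-unique components (names are
#' index triples such as `"xxx"`, `"xyy"`, `"xyz"`; omitted components are
#' zero), which are expanded over index permutations.  Only the i-kk
#' contractions are ever consumed.  Kleinman symmetry is not enforced: a
#' full array violating it beyond a relative 1e-6 triggers a warning and the
#' formula is still evaluated as written.
#'
#' @param mu Numeric length-3 dipole vector, a.u.
#' @param alpha Numeric 3x3 polarizability, a.u.; must be symmetric to a
#'   relative 1e-8.
#' @param beta 3x3x3 array or named Kleinman components, a.u.
#' @param context Optional [calc_context()].
#' @return An object of class `nlo_tensor_set` (beta stored as the full
#'   array).
#' @export
nlo_tensor_set <- function(mu, alpha, beta, context = NULL) {
  mu <- as.numeric(mu)
  if (length(mu) != 3L || any(!is.finite(mu))) {
    stop("`mu` must be a finite 3-vector (a.u.)", call. = FALSE)
  }
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(3L, 3L)) || any(!is.finite(alpha))) {
    stop("`alpha` must be a finite 3x3 matrix (a.u.)", call. = FALSE)
  }
  asym <- max(abs(alpha - t(alpha)))
  if (asym > 1e-8 * max(abs(alpha), 1e-300)) {
    stop("`alpha` is not symmetric (relative asymmetry above 1e-8)", call. = FALSE)
  }
  if (is.numeric(beta) && !is.array(beta) && !is.null(names(beta))) {
    beta <- .expand_kleinman(beta)
  } else if (is.array(beta) && length(dim(beta)) == 3L && all(dim(beta) == 3L)) {
    if (any(!is.finite(beta))) stop("`beta` entries must be finite", call. = FALSE)
    viol <- .kleinman_violation(beta)
    if (viol > 1e-6) {
      warning(sprintf(
        "beta violates Kleinman symmetry (relative deviation %.2e); evaluating as written",
        viol), call. = FALSE)
    }
  } else {
    stop("`beta` must be a 3x3x3 array or named Kleinman-unique components",
         call. = FALSE)
  }
  if (!is.null(context)) stopifnot(inherits(context, "calc_context"))
  structure(list(mu = mu, alpha = alpha, beta = beta, context = context),
            class = "nlo_tensor_set")
}

#' @export
print.nlo_tensor_set <- function(x, ...) {
  cat(sprintf("<nlo_tensor_set> mu %.4f D, alpha-bar %.4f x 1e-24 esu, beta_vec %s\n",
              dipole_magnitude(x), mean_polarizability(x),
              if (sqrt(sum(x$mu^2)) > 0) sprintf("%.4f x 1e-30 esu", beta_vec(x))
              else "(undefined: zero dipole)"))
  invisible(x)
}

# beta_i = sum_k beta_ikk for i = x, y, z
.beta_contraction <- function(beta) {
  vapply(1:3, function(i) beta[i, 1L, 1L] + beta[i, 2L, 2L] + beta[i, 3L, 3L],
         numeric(1))
}

#' Dipole moment magnitude
#'
#' Euclidean norm of the dipole vector, reported in Debye by default.
#'
#' @param t An [nlo_tensor_set()].
#' @param units `"debye"` (default) or `"au"`.
#' @return Dipole magnitude.
#' @export
dipole_magnitude <- function(t, units = c("debye", "au")) {
  stopifnot(inherits(t, "nlo_tensor_set"))
  units <- match.arg(units)
  m <- sqrt(sum(t$mu^2))
  if (units == "debye") au_to_debye(m) else m
}

#' Mean (average linear) polarizability
#'
#' `tr(alpha) / 3`, reported on the 10^-24 esu scale by default.
#'
#' @param t An [nlo_tensor_set()].
#' @param units `"esu"` (10^-24 esu scale, default) or `"au"`.
#' @return Mean polarizability.
#' @export
mean_polarizability <- function(t, units = c("esu", "au")) {
  stopifnot(inherits(t, "nlo_tensor_set"))
  units <- match.arg(units)
  a <- sum(diag(t$alpha)) / 3
  if (units == "esu") tensor_au_to_esu(a, "polarizability") else a
}

#' Beta-vector projection of the first hyperpolarizability
#'
#' Evaluates `beta_vec = sum_i beta_i mu_i / |mu|` with
#' `beta_i = beta_ixx + beta_iyy + beta_izz` — the component of the
#' contracted hyperpolarizability vector along the dipole direction —
#' reported on the 10^-30 esu scale by default.  Undefined for a zero
#' dipole.
#'
#' @param t An [nlo_tensor_set()] with a non-zero dipole.
#' @param units `"esu"` (10^-30 esu scale, default) or `"au"`.
#' @return Beta-vector value (signed).
#' @export
beta_vec <- function(t, units = c("esu", "au")) {
  stopifnot(inherits(t, "nlo_tensor_set"))
  units <- match.arg(units)
  mu_norm <- sqrt(sum(t$mu^2))
  if (mu_norm == 0) {
    stop("beta_vec undefined: zero dipole gives no projection direction",
         call. = FALSE)
  }
  b <- .beta_contraction(t$beta)
  val <- sum(b * t$mu) / mu_norm
  if (units == "esu") tensor_au_to_esu(val, "hyperpolarizability") else val
}

#' Trend report over an NLO benchmark table
#'
#' Scans a complete reference table (4 molecules x 3 functionals x 2 media,
#' columns `mu`, `alpha`, `betavec`) for the expected functional and solvent
#' trends: for each molecule/medium/quantity, whether CAM-B3LYP gives the
#' smallest value (higher HF exchange, higher BLA, weaker response), and for
#' each molecule/functional/quantity whether chloroform enhances the value
#' over gas phase.  Exceptions are listed, not hidden.
#'
#' @param fixture Data frame with columns `molecule`, `functional`, `medium`,
#'   `mu`, `alpha`, `betavec`.
#' @return List with data frames `cam_minimum` (per molecule/medium/quantity:
#'   minimal functional + `cam_is_min` flag), `solvent_effect` (per
#'   molecule/functional/quantity: `chloroform_larger` flag), and
#'   `exceptions` (rows of `cam_minimum` where CAM-B3LYP is not minimal).
#' @export
#' @examples
#' rep <- nlo_trend_report(load_reference_table("nlo"))
#' rep$exceptions
nlo_trend_report <- function(fixture) {
  needed <- c("molecule", "functional", "medium", "mu", "alpha", "betavec")
  if (!is.data.frame(fixture) || !all(needed %in% names(fixture))) {
    stop(sprintf("fixture must have columns: %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  mols <- unique(fixture$molecule)
  media <- unique(fixture$medium)
  funs <- c("B3LYP", "CAM-B3LYP", "M06")
  want <- expand.grid(molecule = mols, functional = funs, medium = media,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$molecule, d$functional, d$medium)
  if (!all(key(want) %in% key(fixture))) {
    stop("incomplete fixture: need every molecule x functional x medium combination",
         call. = FALSE)
  }

  quantities <- c("mu", "alpha", "betavec")
  cam <- do.call(rbind, lapply(quantities, function(q) {
    do.call(rbind, lapply(mols, function(m) {
      do.call(rbind, lapply(media, function(md) {
        sub <- fixture[fixture$molecule == m & fixture$medium == md &
                         fixture$functional %in% funs, ]
        vals <- stats::setNames(sub[[q]], sub$functional)
        data.frame(molecule = m, medium = md, quantity = q,
                   min_functional = names(vals)[which.min(vals)],
                   cam_is_min = names(vals)[which.min(vals)] == "CAM-B3LYP",
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  solv <- NULL
  if (all(c("gas", "chloroform") %in% media)) {
    solv <- do.call(rbind, lapply(quantities, function(q) {
      do.call(rbind, lapply(mols, function(m) {
        do.call(rbind, lapply(funs, function(fn) {
          g <- fixture[fixture$molecule == m & fixture$functional == fn &
                         fixture$medium == "gas", q]
          c_ <- fixture[fixture$molecule == m & fixture$functional == fn &
                          fixture$medium == "chloroform", q]
          data.frame(molecule = m, functional = fn, quantity = q,
                     gas = g, chloroform = c_,
                     chloroform_larger = c_ > g, stringsAsFactors = FALSE)
        }))
      }))
    }))
  }

  list(cam_minimum = cam,
       solvent_effect = solv,
       exceptions = cam[!cam$cam_is_min, , drop = FALSE])
}
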