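# Synthetic-data generators: polyene-like geometries with prescribed bond
# lengths and torsions, internally consistent transition records, and NLO
# tensors hitting prescribed scalar invariants.  Everything needed to
# exercise the pipeline without a quantum-chemistry engine.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rotation_about_axis <- function(axis, degrees) {
  u <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic polyene backbone with prescribed BLA
#'
#' Builds a planar zig-zag all-carbon chain with `n_double` double bonds and
#' `n_double - 1` intervening single bonds (so the default `n_double = 9`
#' mirrors the nine-C=C conjugation path of the achiote dyes), exact
#' prescribed bond lengths, and 120-degree in-plane angles.  Controlled
#' out-of-plane twists can be injected at chosen bonds, and Gaussian
#' coordinate jitter added on top.  Hydrogens and termini are deliberately
#' omitted: the BLA and torsion operations only ever touch the declared
#' backbone path.
#'
#' With no jitter, `compute_bla()` on the result recovers
#' `r_single - r_double` exactly (mean-difference convention) and
#' `max_backbone_torsion()` recovers the largest injected twist.
#'
#' @param n_double Number of C=C bonds (>= 2).
#' @param r_single,r_double Bond lengths in Angstrom, each in (0.5, 3).
#' @param torsions Optional list of `c(bond_index, degrees)` twists; the
#'   1-based bond index `b` must satisfy `2 <= b <= n_bonds - 1` so the twist
#'   is measurable on a 4-atom window.
#' @param noise_sd Standard deviation of isotropic coordinate jitter,
#'   Angstrom (>= 0).
#' @param seed Optional integer seed (required for reproducible jitter).
#' @param label,medium Metadata stored on the geometry.
#' @return List with `geometry` ([molecule_geometry()]) and `path`
#'   ([conjugation_path()]); bond `k` joins atoms `k` and `k + 1`, odd bonds
#'   are double.
#' @export
#' @examples
#' g <- gen_polyene(9, 1.44, 1.36)
#' compute_bla(g$geometry, g$path)  # 0.08
gen_polyene <- function(n_double = 9L, r_single = 1.44, r_double = 1.36,
                        torsions = NULL, noise_sd = 0, seed = NULL,
                        label = "synthetic-polyene", medium = "gas") {
  n_double <- as.integer(n_double)
  if (is.na(n_double) || n_double < 2L) stop("`n_double` must be >= 2", call. = FALSE)
  for (r in c(r_single, r_double)) {
    if (!is.numeric(r) || r <= 0.5 || r >= 3.0) {
      stop("bond lengths must lie in (0.5, 3.0) Angstrom", call. = FALSE)
    }
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  n_atoms <- 2L * n_double
  n_bonds <- n_atoms - 1L
  bond_class <- rep(c("double", "single"), length.out = n_bonds)
  bond_len <- ifelse(bond_class == "double", r_double, r_single)

  # zig-zag in the xy plane: bond direction alternates +-30 deg off x
  theta <- ifelse(seq_len(n_bonds) %% 2L == 1L, 30, -30) * pi / 180
  steps <- cbind(bond_len * cos(theta), bond_len * sin(theta), 0)
  coords <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))

  if (!is.null(torsions)) {
    if (is.numeric(torsions) && length(torsions) == 2L) torsions <- list(torsions)
    for (tw in torsions) {
      if (length(tw) != 2L) stop("each torsion must be c(bond_index, degrees)", call. = FALSE)
      b <- as.integer(tw[1L]); deg <- as.numeric(tw[2L])
      if (is.na(b) || b < 2L || b > n_bonds - 1L) {
        stop(sprintf("torsion bond index must lie in [2, %d]", n_bonds - 1L),
             call. = FALSE)
      }
      axis <- coords[b + 1L, ] - coords[b, ]
      rot <- .rotation_about_axis(axis, deg)
      idx <- (b + 2L):n_atoms
      pivot <- coords[b + 1L, ]
      coords[idx, ] <- sweep(sweep(coords[idx, , drop = FALSE], 2L, pivot) %*% t(rot),
                             2L, pivot, `+`)
    }
  }

  if (noise_sd > 0) {
    coords <- coords + .with_seed(seed, matrix(stats::rnorm(3L * n_atoms, sd = noise_sd),
                                               n_atoms, 3L))
  }

  list(
    geometry = molecule_geometry(rep("C", n_atoms), coords, label = label,
                                 context = calc_context(medium = medium)),
    path = conjugation_path(seq_len(n_bonds), seq_len(n_bonds) + 1L, bond_class)
  )
}

#' Generate an internally consistent transition record
#'
#' Builds a [transition()] whose oscillator strength is computed from the
#' length-gauge relation (see [oscillator_strength_from_tdm()]) and whose
#' stored wavelength is `hc / energy`, so [validate_transition()] passes at
#' machine precision.
#'
#' @param energy Excitation energy, eV (> 0).
#' @param tdm_direction Direction of the transition dipole (any non-zero
#'   3-vector; normalised internally).  A zero direction is only allowed for
#'   `tdm_magnitude = 0`.
#' @param tdm_magnitude Total transition dipole, Debye (>= 0).
#' @param context Optional [calc_context()].
#' @return A [transition()].
#' @export
#' @examples
#' tr <- gen_transition(2.249, c(1, 0, 0), 19.845)
#' tr$osc_strength  # ~3.36
gen_transition <- function(energy, tdm_direction = c(1, 0, 0), tdm_magnitude,
                           context = NULL) {
  stopifnot(is.numeric(tdm_magnitude), length(tdm_magnitude) == 1L,
            tdm_magnitude >= 0)
  dir <- as.numeric(tdm_direction)
  if (length(dir) != 3L || any(!is.finite(dir))) {
    stop("`tdm_direction` must be a finite 3-vector", call. = FALSE)
  }
  nrm <- sqrt(sum(dir^2))
  if (nrm == 0) {
    if (tdm_magnitude > 0) {
      stop("zero `tdm_direction` with non-zero magnitude", call. = FALSE)
    }
    tdm <- c(0, 0, 0)
  } else {
    tdm <- dir / nrm * tdm_magnitude
  }
  transition(energy = energy,
             osc_strength = oscillator_strength_from_tdm(energy, tdm_magnitude),
             tdm = tdm,
             wavelength = ev_to_nm(energy),
             context = context)
}

#' Generate NLO tensors with prescribed scalar invariants
#'
#' Constructs an [nlo_tensor_set()] whose derived scalars hit the requested
#' targets exactly: the dipole vector points along a random unit vector with
#' the prescribed magnitude; the polarizability is the isotropic tensor
#' matching the trace target plus a random traceless symmetric part; the
#' hyperpolarizability is a random Kleinman-symmetric tensor whose
#' fully-symmetric i11-components are adjusted so the contracted vector
#' `beta_i = sum_k beta_ikk` equals the target projection along the dipole
#' plus a random orthogonal component.  Different seeds give different
#' tensors with identical invariants.
#'
#' @param mu_target Dipole magnitude, Debye (> 0).
#' @param alpha_target Mean polarizability on the 10^-24 esu scale.
#' @param betavec_target Beta-vector on the 10^-30 esu scale (signed).
#' @param seed Optional integer seed for reproducibility.
#' @param context Optional [calc_context()].
#' @return An [nlo_tensor_set()].
#' @export
#' @examples
#' t <- gen_nlo_tensors(5.81, 116.14, 122.65, seed = 1)
#' c(dipole_magnitude(t), mean_polarizability(t), beta_vec(t))
gen_nlo_tensors <- function(mu_target, alpha_target, betavec_target,
                            seed = NULL, context = NULL) {
  stopifnot(is.numeric(mu_target), length(mu_target) == 1L)
  if (mu_target <= 0) stop("`mu_target` must be positive (Debye)", call. = FALSE)
  stopifnot(is.numeric(alpha_target), length(alpha_target) == 1L,
            is.numeric(betavec_target), length(betavec_target) == 1L)

  .with_seed(seed, {
    u <- stats::rnorm(3L)
    u <- u / sqrt(sum(u^2))
    mu_au <- debye_to_au(mu_target) * u

    trace_au <- 3 * tensor_esu_to_au(alpha_target, "polarizability")
    S <- matrix(stats::rnorm(9L), 3L, 3L)
    S <- (S + t(S)) / 2
    S <- S - diag(rep(sum(diag(S)) / 3, 3L))          # traceless symmetric noise
    alpha <- diag(rep(trace_au / 3, 3L)) + 0.1 * abs(trace_au) * S

    b_target_au <- tensor_esu_to_au(betavec_target, "hyperpolarizability")
    w <- stats::rnorm(3L)
    w <- w - sum(w * u) * u                           # orthogonal to the dipole
    b_vec <- b_target_au * u + abs(b_target_au) * w   # contraction target

    # random Kleinman-symmetric part: symmetrise over index permutations
    raw <- array(stats::rnorm(27L, sd = max(abs(b_target_au), 1) * 0.1), c(3L, 3L, 3L))
    beta <- array(0, c(3L, 3L, 3L))
    for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
      beta <- beta + aperm(raw, p)
    }
    beta <- beta / 6
    # adjust the symmetric {i,1,1} components so beta_i hits b_vec exactly;
    # the {i,1,1} multiset only enters beta_i's own contraction
    resid <- b_vec - .beta_contraction(beta)
    beta[1L, 1L, 1L] <- beta[1L, 1L, 1L] + resid[1L]
    for (i in 2:3) {
      beta[i, 1L, 1L] <- beta[i, 1L, 1L] + resid[i]
      beta[1L, i, 1L] <- beta[1L, i, 1L] + resid[i]
      beta[1L, 1L, i] <- beta[1L, 1L, i] + resid[i]
    }

    nlo_tensor_set(mu_au, alpha, beta, context = context)
  })
}
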