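# Shared oracles and generators for the test suite.  These stay independent
# of the implementation paths they check.

# Uniform-ish random proper rotation matrix (QR of a Gaussian matrix with
# the sign fix, determinant +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Rank-3 tensor rotation beta'_{abc} = R_ai R_bj R_ck beta_{ijk}, by loops.
rotate_rank3 <- function(beta, R) {
  out <- array(0, c(3, 3, 3))
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
      s <- s + R[a, i] * R[b, j] * R[cc, k] * beta[i, j, k]
    }
    out[a, b, cc] <- s
  }
  out
}

# Same rotation via mode-wise matrix products (fast enough for 1000 draws);
# cross-checked against rotate_rank3 in the tests.
rotate_rank3_fast <- function(beta, R) {
  b <- array(R %*% matrix(beta, 3, 9), c(3, 3, 3))
  b <- aperm(array(R %*% matrix(aperm(b, c(2, 1, 3)), 3, 9), c(3, 3, 3)), c(2, 1, 3))
  b <- aperm(array(R %*% matrix(aperm(b, c(3, 1, 2)), 3, 9), c(3, 3, 3)), c(2, 3, 1))
  b
}

# Independent evaluation of the beta-vector projection in atomic units:
# explicit triple loop over the definition, no shared code with beta_vec().
brute_force_beta_vec_au <- function(mu, beta) {
  total <- 0
  mu_norm <- sqrt(sum(mu^2))
  for (i in 1:3) {
    beta_i <- 0
    for (k in 1:3) beta_i <- beta_i + beta[i, k, k]
    total <- total + beta_i * mu[i]
  }
  total / mu_norm
}

# Minimal well-formed water XYZ text.
water_xyz_lines <- function() {
  c("3",
    "label=water medium=gas",
    "O 0.000000 0.000000 0.117300",
    "H 0.000000 0.757200 -0.469200",
    "H 0.000000 -0.757200 -0.469200")
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".xyz", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A fully populated synthetic qc_record for round-trip and pipeline tests.
make_synthetic_record <- function(label = "synthetic", functional = "B3LYP",
                                  medium = "gas", seed = 42) {
  ctx <- calc_context(functional, "6-31+G(d,p)", medium)
  qc_record(
    label, ctx,
    electronic = electronic_summary(-5.221, -3.073, context = ctx),
    nlo = gen_nlo_tensors(5.81, 116.14, 122.65, seed = seed, context = ctx),
    transitions = list(gen_transition(2.249, c(1, 0.05, 0), 19.845, context = ctx))
  )
}
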