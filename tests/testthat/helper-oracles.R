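# Independent oracles used across the suite.

# Central finite difference of the strain energy w.r.t. the entries of F:
# the brute-force nominal stress the analytic implementation must match.
fd_nominal <- function(F, params, h = 1e-6) {
  a0 <- params$fiber_dir
  P <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy(kinematics(Fp, a0 = a0), params) -
                  strain_energy(kinematics(Fm, a0 = a0), params)) / (2 * h)
  }
  P
}

# Random admissible deformation gradient with J inside [0.95, 1.05].
rand_F <- function(spread = 0.06) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, 0, spread), 3, 3)
    J <- det(F)
    if (J > 0.95 && J < 1.05) return(F)
  }
}

# Exhaustive Mann-Whitney concordance: loop over every (injury,
# non-injury) pair, ties counted 1/2.
auc_pairwise <- function(scores, outcome) {
  s1 <- scores[outcome == 1]; s0 <- scores[outcome == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# Rotation matrix about an arbitrary axis (Rodrigues).
rot3 <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

brain_rows <- function() material_registry()[
  c("subcortical_white_matter", "corpus_callosum", "brainstem",
    "gray_matter")]
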