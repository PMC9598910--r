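# Shared fixtures and independent oracles.

s1_material <- function(kappa0 = NULL) {
  row <- specimen_parameters("S1")
  material_params(mu0 = row$mu0, k1_mus = row$k1_mus, k2_mus = row$k2_mus,
                  k1_sm = row$k1_sm, k2_sm = row$k2_sm, kappa0 = kappa0)
}
s1_damage <- function() as_damage_params(specimen_parameters("S1"))

noise_free_protocol <- function(...) {
  rig_protocol(noise_rel = 0, force_floor = 0, ...)
}

table1_truth <- function(specimen) {
  row <- specimen_parameters(specimen)
  unlist(row[c("k1_mus", "k2_mus", "k1_sm", "k2_sm",
               "tau0_lm", "gf_lm", "tau0_cm", "gf_cm", "tau0_sm", "gf_sm")])
}

# Independent finite-difference oracle: Cauchy stress from the energy,
# sigma = J^-1 (d psi / d F) F^T by central differences. Damage factors held
# fixed (effective-stress form differentiates at frozen D).
fd_cauchy <- function(F, mat, damage = c(lm = 0, cm = 0, sm = 0),
                      fibers = fiber_set(mat$alpha_deg), h = 1e-6) {
  psi_of <- function(Fm) strain_energy(deformation(Fm, fibers), mat, damage)$total
  dPdF <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F
      Fm <- F
      Fp[i, j] <- Fp[i, j] + h
      Fm[i, j] <- Fm[i, j] - h
      dPdF[i, j] <- (psi_of(Fp) - psi_of(Fm)) / (2 * h)
    }
  }
  (dPdF %*% t(F)) / det(F)
}

# Random deformation gradient with principal stretches in [lo, hi];
# even draws get in-plane rotations on both sides.
rand_F <- function(rotated = TRUE, lo = 0.85, hi = 1.6) {
  s <- stats::runif(3, lo, hi)
  rot <- function(a) {
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  if (rotated) {
    rot(stats::runif(1, 0, 2 * pi)) %*% diag(s) %*% rot(stats::runif(1, 0, 2 * pi))
  } else {
    diag(s)
  }
}

rel_frob <- function(a, b) {
  norm(a - b, "F") / max(norm(a, "F"), 1e-12)
}
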