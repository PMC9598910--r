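# Lean vectorized forward pass for diagonal incompressible biaxial paths.
# Single source of truth for the curve-level model: run_path() and the
# fitting objective both call this. Returns plain numeric vectors.
forward_biaxial <- function(mat, dmg, lambda_L, lambda_C) {
  a <- mat$alpha_deg * pi / 180
  c2 <- cos(a)^2
  s2 <- sin(a)^2
  L2 <- lambda_L^2
  C2 <- lambda_C^2
  lz2 <- 1 / (L2 * C2)
  I4_sm <- c2 * L2 + s2 * C2

  psi_lm <- psi_fiber(L2, mat$k1_mus, mat$k2_mus)
  psi_cm <- psi_fiber(C2, mat$k1_mus, mat$k2_mus)
  psi_sm <- 2 * psi_fiber(I4_sm, mat$k1_sm, mat$k2_sm)
  tau_lm <- sqrt(2 * psi_lm)
  tau_cm <- sqrt(2 * psi_cm)
  tau_sm <- sqrt(2 * psi_sm)

  if (is.null(dmg)) {
    n <- length(tau_lm)
    D_lm <- D_cm <- D_sm <- numeric(n)
  } else {
    evolve <- function(tau, k) {
      tau_max <- cummax(pmax(tau, dmg$tau0[[k]]))
      damage_value(tau_max, dmg$tau0[[k]], dmg$A[[k]])
    }
    D_lm <- evolve(tau_lm, "lm")
    D_cm <- evolve(tau_cm, "cm")
    D_sm <- evolve(tau_sm, "sm")
  }

  dpm_L <- psi_prime(L2, mat$k1_mus, mat$k2_mus)
  dpm_C <- psi_prime(C2, mat$k1_mus, mat$k2_mus)
  dps <- psi_prime(I4_sm, mat$k1_sm, mat$k2_sm)

  list(
    sigma_LL = mat$mu0 * (L2 - lz2) + (1 - D_lm) * 2 * dpm_L * L2 +
      (1 - D_sm) * 4 * dps * c2 * L2,
    sigma_CC = mat$mu0 * (C2 - lz2) + (1 - D_cm) * 2 * dpm_C * C2 +
      (1 - D_sm) * 4 * dps * s2 * C2,
    tau_lm = tau_lm, tau_cm = tau_cm, tau_sm = tau_sm,
    D_lm = D_lm, D_cm = D_cm, D_sm = D_sm
  )
}
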