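#' HGO fiber strain energy and its derivative
#'
#' Single-family exponential fiber potential
#' `psi(I4_bar) = k1 / (2 k2) * (exp(k2 (I4_bar - 1)^2) - 1)` and its
#' derivative with respect to `I4_bar`,
#' `psi'(I4_bar) = k1 (I4_bar - 1) exp(k2 (I4_bar - 1)^2)`.
#' Fibers do not support compression: both are identically zero for
#' `I4_bar < 1`. For `k2 = 0` the quadratic limit `k1/2 (I4_bar - 1)^2`
#' is used.
#'
#' @param I4_bar Modified fourth invariant(s) (squared isochoric fiber
#'   stretch).
#' @param k1 Stress-like constant (MPa).
#' @param k2 Dimensionless exponent (>= 0).
#' @return Energy density (MPa) or its derivative (MPa), vectorized over
#'   `I4_bar`.
#' @examples
#' psi_prime(1.2, k1 = 0.0030, k2 = 10.6781)  # ~9.197e-4 MPa
#' psi_prime(0.9, 1, 1)                       # 0: tension-only
#' @export
psi_fiber <- function(I4_bar, k1, k2) {
  x <- pmax(I4_bar - 1, 0)
  if (k2 < 1e-12) k1 / 2 * x^2 else k1 / (2 * k2) * (exp(k2 * x^2) - 1)
}

#' @rdname psi_fiber
#' @export
psi_prime <- function(I4_bar, k1, k2) {
  x <- pmax(I4_bar - 1, 0)
  k1 * x * exp(k2 * x^2)
}

#' Strain-energy breakdown of a deformation state
#'
#' Evaluates the decoupled strain-energy function: volumetric penalty
#' `kappa0/2 (J - 1)^2` (zero in incompressible mode), isochoric neo-Hookean
#' matrix `mu0/2 (I1_bar - 3)`, the undamaged per-fiber muscular terms
#' (`lm` from `a01`, `cm` from `a02`) and the pooled undamaged submucosal
#' term (sum over `a03` and `a04`), plus the damage-weighted total
#' `psi_vol + psi_iso + sum_k (1 - D_k) psi_k`.
#'
#' @param def A [deformation()].
#' @param mat A [material_params()]. The fiber angle of `def$fibers` is used
#'   as-is; construct `def` with `fiber_set(mat$alpha_deg)` for consistency.
#' @param damage Named damage scalars `c(lm =, cm =, sm =)` in `[0, 1]`.
#' @return A list with `psi_vol`, `psi_iso`, `psi_lm`, `psi_cm`, `psi_sm`
#'   (undamaged layer energies, MPa) and `total` (damage-weighted, MPa).
#' @examples
#' mat <- as_material_params(specimen_parameters("S1"))
#' strain_energy(deformation(diag(c(1.2, 1.2, 1 / 1.44))), mat)
#' @export
strain_energy <- function(def, mat, damage = c(lm = 0, cm = 0, sm = 0)) {
  damage <- check_damage_scalars(damage)
  psi_vol <- if (is.null(mat$kappa0)) 0 else mat$kappa0 / 2 * (def$J - 1)^2
  psi_iso <- mat$mu0 / 2 * (def$I1_bar - 3)
  psi_lm <- psi_fiber(def$I4_bar[["a01"]], mat$k1_mus, mat$k2_mus)
  psi_cm <- psi_fiber(def$I4_bar[["a02"]], mat$k1_mus, mat$k2_mus)
  psi_sm <- psi_fiber(def$I4_bar[["a03"]], mat$k1_sm, mat$k2_sm) +
    psi_fiber(def$I4_bar[["a04"]], mat$k1_sm, mat$k2_sm)
  total <- psi_vol + psi_iso +
    (1 - damage[["lm"]]) * psi_lm +
    (1 - damage[["cm"]]) * psi_cm +
    (1 - damage[["sm"]]) * psi_sm
  list(psi_vol = psi_vol, psi_iso = psi_iso,
       psi_lm = psi_lm, psi_cm = psi_cm, psi_sm = psi_sm, total = total)
}
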