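#' Analytic Cauchy stress with per-layer damage
#'
#' Pushes the second Piola-Kirchhoff stress of the decoupled strain-energy
#' function forward to the current configuration:
#' \deqn{\sigma = p I + \frac{\mu_0}{J}\left(\bar B - \frac{\bar I_1}{3} I\right)
#'   + \sum_i (1 - D_{k(i)}) \frac{2}{J}\,\bar\psi'(\bar I_{4,i})
#'     \left(\bar A_i - \frac{\bar I_{4,i}}{3} I\right),}
#' where `A_bar_i = F_bar a0i (F_bar a0i)^T` is the isochoric spatial
#' structural tensor. The Kachanov factor `(1 - D)` applies `lm` to `a01`,
#' `cm` to `a02` and a single shared `sm` to both submucosal fibers; the
#' volumetric and matrix terms are never damaged.
#'
#' The hydrostatic pressure is `p = kappa0 (J - 1)` in penalty mode. In
#' incompressible mode (`mat$kappa0` is `NULL`) the constraint pressure is
#' indeterminate and must be supplied via `pressure` (the plane-stress
#' solvers fix it from `sigma_zz = 0`).
#'
#' @param def A [deformation()].
#' @param mat A [material_params()].
#' @param damage Named damage scalars `c(lm =, cm =, sm =)` in `[0, 1]`.
#' @param pressure Hydrostatic pressure (MPa) overriding the penalty value;
#'   required in incompressible mode.
#' @return An object of class `stress_tensor`: list with the symmetric 3 x 3
#'   `sigma` (MPa), `pressure`, and `components` (list of 3 x 3 matrices
#'   `vol`, `iso`, `lm`, `cm`, `sm` that sum to `sigma`; fiber components
#'   carry their damage factor).
#' @examples
#' mat <- as_material_params(specimen_parameters("S1"))
#' d <- deformation(diag(c(1.2, 1.2, 1 / 1.44)), fiber_set(mat$alpha_deg))
#' cauchy_stress(d, mat, pressure = 0)
#' @export
cauchy_stress <- function(def, mat, damage = c(lm = 0, cm = 0, sm = 0),
                          pressure = NULL) {
  damage <- check_damage_scalars(damage)
  J <- def$J
  I3 <- diag(3)
  if (is.null(pressure)) {
    if (is.null(mat$kappa0)) {
      stop("Incompressible material: supply `pressure` (or use the plane-stress solvers).",
           call. = FALSE)
    }
    pressure <- mat$kappa0 * (J - 1)
  }
  sig_vol <- pressure * I3
  sig_iso <- mat$mu0 / J * (def$B_bar - def$I1_bar / 3 * I3)

  F_bar <- J^(-1 / 3) * def$F
  dirs <- def$fibers$directions
  fiber_dev <- function(nm, k1, k2) {
    I4 <- def$I4_bar[[nm]]
    a_bar <- drop(F_bar %*% dirs[nm, ])
    2 / J * psi_prime(I4, k1, k2) * (tcrossprod(a_bar) - I4 / 3 * I3)
  }
  sig_lm <- (1 - damage[["lm"]]) * fiber_dev("a01", mat$k1_mus, mat$k2_mus)
  sig_cm <- (1 - damage[["cm"]]) * fiber_dev("a02", mat$k1_mus, mat$k2_mus)
  sig_sm <- (1 - damage[["sm"]]) *
    (fiber_dev("a03", mat$k1_sm, mat$k2_sm) +
       fiber_dev("a04", mat$k1_sm, mat$k2_sm))

  sigma <- sig_vol + sig_iso + sig_lm + sig_cm + sig_sm
  structure(
    list(sigma = sigma, pressure = pressure,
         components = list(vol = sig_vol, iso = sig_iso,
                           lm = sig_lm, cm = sig_cm, sm = sig_sm)),
    class = "stress_tensor"
  )
}

#' @export
print.stress_tensor <- function(x, ...) {
  cat("<stress_tensor> (MPa), p =", signif(x$pressure, 6), "\n")
  print(signif(x$sigma, 6))
  invisible(x)
}
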