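#' Equivalent strain of a collagenous layer
#'
#' The damage-driving variable is the energy norm
#' `tau = sqrt(2 * psi_bar)` of the *undamaged* deviatoric layer energy,
#' with units MPa^1/2.
#'
#' @param psi_bar Undamaged layer strain energy (MPa), >= 0. Vectorized.
#' @return Equivalent strain(s) in MPa^1/2.
#' @examples
#' equivalent_strain(0.005)  # 0.1
#' @export
equivalent_strain <- function(psi_bar) {
  if (any(!is.finite(psi_bar)) || any(psi_bar < 0)) {
    stop("Layer energy must be finite and >= 0.", call. = FALSE)
  }
  sqrt(2 * psi_bar)
}

#' Exponent of the exponential damage evolution law
#'
#' `A = 1 / (gf / tau0^2 - 1/2)`. Well-posedness (A > 0) requires
#' `gf > tau0^2 / 2`; smaller `gf` (relative to the threshold) gives larger
#' `A` and a steeper, more brittle softening branch.
#'
#' @param tau0 Initial damage threshold (MPa^1/2), > 0.
#' @param gf Fracture energy per unit volume (MPa).
#' @return The dimensionless exponent A.
#' @examples
#' damage_A(0.1149, 0.0073)  # ~18.89
#' @export
damage_A <- function(tau0, gf) {
  if (any(tau0 <= 0)) stop("`tau0` must be > 0.", call. = FALSE)
  # strict feasibility with a relative guard so that gf == tau0^2/2 up to
  # round-off is still rejected (A would overflow)
  if (any(gf <= tau0^2 / 2 * (1 + 1e-9))) {
    stop("Non-physical damage pair: `gf` must exceed `tau0^2 / 2`.", call. = FALSE)
  }
  1 / (gf / tau0^2 - 1 / 2)
}

#' Exponential damage evolution function
#'
#' \deqn{D(\tau) = \begin{cases} 0 & \tau \le \tau_0 \\
#'   1 - \frac{\tau_0}{\tau} \exp\!\left(A \left(1 -
#'   \frac{\tau}{\tau_0}\right)\right) & \tau > \tau_0,\end{cases}}
#' clamped to `[0, 1]`. Continuous at `tau = tau0` with `D(tau0) = 0` and
#' `D -> 1` as `tau -> Inf`.
#'
#' @param tau Equivalent strain(s) (MPa^1/2), >= 0. Vectorized.
#' @param tau0 Initial damage threshold (MPa^1/2).
#' @param A Evolution exponent from [damage_A()].
#' @return Damage scalar(s) in `[0, 1]`.
#' @examples
#' damage_value(c(0.1149, 0.2298), 0.1149, damage_A(0.1149, 0.0073))
#' @export
damage_value <- function(tau, tau0, A) {
  if (any(tau < 0)) stop("`tau` must be >= 0.", call. = FALSE)
  D <- ifelse(tau <= tau0, 0, 1 - (tau0 / tau) * exp(A * (1 - tau / tau0)))
  pmin(pmax(D, 0), 1)
}

#' Per-layer damage state with irreversible history
#'
#' A `damage_state` carries, for each layer `lm`, `cm`, `sm`, the largest
#' equivalent strain seen so far (`tau_max`, initialized at the threshold
#' `tau0`) and the current damage scalar `D`. [update_damage_state()] applies
#' the strain-space criterion: damage evolves only when the current
#' equivalent strain exceeds the history maximum; on unloading or elastic
#' reloading both `tau_max` and `D` are frozen, so `D` never decreases.
#' In the state (solver) path `D` is capped at `1 - 1e-12` to keep a
#' vanishing but nonzero stiffness for root-finding.
#'
#' @param dpar A [damage_params()].
#' @return An object of class `damage_state`: list with `tau0`, `A`,
#'   `tau_max`, `D` (named numeric vectors over `lm`, `cm`, `sm`).
#' @examples
#' st <- damage_state(as_damage_params(specimen_parameters("S1")))
#' st <- update_damage_state(st, c(lm = 0.02, cm = 0.001, sm = 0.004))
#' st$D
#' @export
damage_state <- function(dpar) {
  stopifnot(inherits(dpar, "damage_params"))
  structure(
    list(tau0 = dpar$tau0, A = dpar$A,
         tau_max = dpar$tau0,
         D = c(lm = 0, cm = 0, sm = 0)),
    class = "damage_state"
  )
}

#' @rdname damage_state
#' @param state A `damage_state`.
#' @param psi_bar Named undamaged layer energies `c(lm =, cm =, sm =)` (MPa).
#' @export
update_damage_state <- function(state, psi_bar) {
  stopifnot(inherits(state, "damage_state"))
  psi_bar <- psi_bar[c("lm", "cm", "sm")]
  tau <- equivalent_strain(psi_bar)
  grow <- tau > state$tau_max
  state$tau_max[grow] <- tau[grow]
  D <- damage_value(state$tau_max, state$tau0, state$A)
  state$D <- pmin(pmax(D, state$D), 1 - 1e-12)
  state
}

#' @export
print.damage_state <- function(x, ...) {
  cat("<damage_state>\n")
  print(round(rbind(tau_max = x$tau_max, D = x$D), 6))
  invisible(x)
}

#' Incremental internal dissipation
#'
#' `D_int = sum_k dD_k * psi_bar_k`, the dissipation of one damage update.
#' Thermodynamic admissibility (Clausius-Duhem inequality) requires it to be
#' non-negative on every update, which holds because the damage variables are
#' non-decreasing and the layer energies are non-negative.
#'
#' @param dD Named per-layer damage increments `c(lm =, cm =, sm =)`.
#' @param psi_bar Named undamaged layer energies (MPa).
#' @return Dissipated energy density (MPa).
#' @examples
#' internal_dissipation(c(lm = 0.1, cm = 0, sm = 0),
#'                      c(lm = 0.2, cm = 0.1, sm = 0.05))  # 0.02
#' @export
internal_dissipation <- function(dD, psi_bar) {
  layers <- c("lm", "cm", "sm")
  sum(dD[layers] * psi_bar[layers])
}
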