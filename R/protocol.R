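#' In-plane Cauchy stresses under incompressible plane stress
#'
#' For a biaxial stretch state `F = diag(lambda_L, lambda_C, lambda_z)` with
#' `lambda_z = 1 / (lambda_L * lambda_C)` (J = 1), the through-thickness
#' condition `sigma_zz = 0` eliminates the constraint pressure and the
#' in-plane true stresses follow in closed form:
#' `sigma_ii = sigma_dev_ii - sigma_dev_zz`. All four fiber families lie in
#' the plane, so with a diagonal stretch state the stress is diagonal (the
#' off-diagonal submucosal contributions of the +alpha and -alpha fibers
#' cancel).
#'
#' @param lambda_L,lambda_C Stretch(es) in the longitudinal and
#'   circumferential directions (vectorized, recycled).
#' @param mat A [material_params()].
#' @param damage Per-layer damage: either a named scalar vector
#'   `c(lm =, cm =, sm =)` or a list/data frame of equally long vectors.
#' @return A tibble with `sigma_LL`, `sigma_CC` (MPa).
#' @examples
#' mat <- as_material_params(specimen_parameters("S1"))
#' equibiaxial_stress(1.25, 1.25, mat)
#' @export
equibiaxial_stress <- function(lambda_L, lambda_C, mat,
                               damage = c(lm = 0, cm = 0, sm = 0)) {
  if (any(lambda_L <= 0) || any(lambda_C <= 0)) {
    stop("Stretches must be > 0.", call. = FALSE)
  }
  n <- max(length(lambda_L), length(lambda_C))
  lambda_L <- rep_len(lambda_L, n)
  lambda_C <- rep_len(lambda_C, n)
  if (is.data.frame(damage) || is.list(damage)) {
    D_lm <- rep_len(damage[["lm"]], n)
    D_cm <- rep_len(damage[["cm"]], n)
    D_sm <- rep_len(damage[["sm"]], n)
  } else {
    damage <- check_damage_scalars(damage)
    D_lm <- rep_len(damage[["lm"]], n)
    D_cm <- rep_len(damage[["cm"]], n)
    D_sm <- rep_len(damage[["sm"]], n)
  }

  lz <- 1 / (lambda_L * lambda_C)
  L2 <- lambda_L^2
  C2 <- lambda_C^2
  z2 <- lz^2
  a <- mat$alpha_deg * pi / 180
  c2 <- cos(a)^2
  s2 <- sin(a)^2

  I4_L <- L2
  I4_C <- C2
  I4_sm <- c2 * L2 + s2 * C2

  dpm_L <- psi_prime(I4_L, mat$k1_mus, mat$k2_mus)
  dpm_C <- psi_prime(I4_C, mat$k1_mus, mat$k2_mus)
  dps <- psi_prime(I4_sm, mat$k1_sm, mat$k2_sm)

  # sigma_ii - sigma_zz; the I4/3 deviatoric offsets cancel in the difference
  sigma_LL <- mat$mu0 * (L2 - z2) +
    (1 - D_lm) * 2 * dpm_L * L2 +
    (1 - D_sm) * 4 * dps * c2 * L2
  sigma_CC <- mat$mu0 * (C2 - z2) +
    (1 - D_cm) * 2 * dpm_C * C2 +
    (1 - D_sm) * 4 * dps * s2 * C2

  tibble::tibble(sigma_LL = sigma_LL, sigma_CC = sigma_CC)
}

#' Build a proportional biaxial load path
#'
#' A stretch path from `(1, 1)` to `(max_stretch_L, max_stretch_C)` in
#' `steps` equal increments (first row is the reference state).
#'
#' @param max_stretch_L,max_stretch_C Final stretches (> 0).
#' @param steps Number of increments (>= 1).
#' @return A tibble with `lambda_L`, `lambda_C`.
#' @examples
#' load_path(1.3, 1.3, steps = 5)
#' @export
load_path <- function(max_stretch_L, max_stretch_C = max_stretch_L, steps = 100) {
  stopifnot(max_stretch_L > 0, max_stretch_C > 0, steps >= 1)
  s <- seq(0, 1, length.out = steps + 1)
  tibble::tibble(lambda_L = 1 + s * (max_stretch_L - 1),
                 lambda_C = 1 + s * (max_stretch_C - 1))
}

#' Drive the damage-coupled model along a biaxial stretch path
#'
#' Steps through an arbitrary (not necessarily monotone) sequence of
#' `(lambda_L, lambda_C)` states under incompressible plane stress. At each
#' frame the undamaged layer energies are evaluated, the damage state is
#' updated (the history maximum of the equivalent strain governs, so
#' unloading freezes damage), and the in-plane Cauchy stresses are computed
#' with the current Kachanov factors. Because the evolution law is a closed
#' form of the running maximum, the whole path is evaluated vectorized.
#'
#' @param path A data frame with columns `lambda_L`, `lambda_C` (and
#'   optionally `time_s`, carried through).
#' @param mat A [material_params()].
#' @param dmg A [damage_params()], or `NULL` for the undamaged hyperelastic
#'   model.
#' @return A tibble with the path columns plus `sigma_LL`, `sigma_CC` (MPa),
#'   undamaged equivalent strains `tau_lm`, `tau_cm`, `tau_sm` (MPa^1/2) and
#'   damage scalars `D_lm`, `D_cm`, `D_sm`.
#' @examples
#' s1 <- specimen_parameters("S1")
#' run_path(load_path(1.3, steps = 20), as_material_params(s1),
#'          as_damage_params(s1))
#' @export
run_path <- function(path, mat, dmg = NULL) {
  if (!all(c("lambda_L", "lambda_C") %in% names(path))) {
    stop("`path` needs columns `lambda_L` and `lambda_C`.", call. = FALSE)
  }
  lambda_L <- path$lambda_L
  lambda_C <- path$lambda_C
  if (any(lambda_L <= 0) || any(lambda_C <= 0)) {
    stop("Stretches must be > 0.", call. = FALSE)
  }
  fw <- forward_biaxial(mat, dmg, lambda_L, lambda_C)
  dplyr::bind_cols(tibble::as_tibble(path), tibble::as_tibble(fw))
}

#' Single-brick equibiaxial displacement simulation
#'
#' Reproduces a displacement-controlled biaxial test on a unit cube treated
#' as one homogeneous material point: prescribed in-plane displacements
#' `DX`, `DY` (mm, on a 1 mm edge) are ramped proportionally in `steps`
#' increments, and at each increment the through-thickness stretch
#' `lambda_z` is found from the plane-stress condition `sigma_zz = 0`.
#' In incompressible mode `lambda_z = 1 / (lambda_x * lambda_y)` exactly;
#' in penalty mode the scalar equation with `p = kappa0 (J - 1)` is solved
#' by bracketed root-finding (bracket initialized at `[0.2, 1.2]` times the
#' incompressible guess and expanded geometrically on failure). The damage
#' state is carried across increments; within an increment the solve and the
#' state update are iterated to a fixed point.
#'
#' @param dx,dy Final in-plane displacements (mm), >= 0.
#' @param mat A [material_params()].
#' @param dmg A [damage_params()] or `NULL`.
#' @param mode `"penalty"` or `"incompressible"`.
#' @param kappa0 Bulk modulus (MPa) for penalty mode; defaults to
#'   [default_kappa0()].
#' @param steps Number of load increments (>= 1).
#' @param edge Cube edge length (mm).
#' @return An object of classes `brick_result`/`tbl_df`: per increment the
#'   prescribed `DX`, `DY`, solved `DZ` (mm), stretches, `J`, pressure,
#'   diagonal Cauchy stresses (MPa, `sigma_zz` is the residual), and damage
#'   scalars.
#' @examples
#' s1 <- specimen_parameters("S1")
#' simulate_brick(0.31, 0.38, as_material_params(s1), as_damage_params(s1),
#'                mode = "incompressible", steps = 10)
#' @export
simulate_brick <- function(dx, dy, mat, dmg = NULL,
                           mode = c("penalty", "incompressible"),
                           kappa0 = default_kappa0(mat), steps = 100,
                           edge = 1) {
  mode <- match.arg(mode)
  stopifnot(dx >= 0, dy >= 0, steps >= 1, edge > 0)
  fibers <- fiber_set(mat$alpha_deg)
  mat_pen <- mat
  mat_pen$kappa0 <- if (mode == "penalty") kappa0 else NULL
  state <- if (is.null(dmg)) NULL else damage_state(dmg)

  sigma_zz_at <- function(lx, ly, lz, D) {
    def <- deformation(diag(c(lx, ly, lz)), fibers)
    st <- cauchy_stress(def, mat_pen, damage = D,
                        pressure = if (mode == "penalty") NULL else 0)
    st$sigma[3, 3]
  }

  solve_lz <- function(lx, ly, D) {
    lz_inc <- 1 / (lx * ly)
    if (mode == "incompressible") return(lz_inc)
    lo <- 0.2 * lz_inc
    hi <- 1.2 * lz_inc
    f_lo <- sigma_zz_at(lx, ly, lo, D)
    f_hi <- sigma_zz_at(lx, ly, hi, D)
    tries <- 0
    while (f_lo * f_hi > 0 && tries < 60) {
      lo <- lo / 1.5
      hi <- hi * 1.5
      f_lo <- sigma_zz_at(lx, ly, lo, D)
      f_hi <- sigma_zz_at(lx, ly, hi, D)
      tries <- tries + 1
    }
    if (f_lo * f_hi > 0) {
      stop(sprintf("Plane-stress root not bracketed in [%.3g, %.3g].", lo, hi),
           call. = FALSE)
    }
    stats::uniroot(function(lz) sigma_zz_at(lx, ly, lz, D),
                   lower = lo, upper = hi,
                   tol = .Machine$double.eps^0.9)$root
  }

  s <- seq(0, 1, length.out = steps + 1)
  rows <- vector("list", steps + 1)
  for (i in seq_along(s)) {
    lx <- 1 + s[i] * dx / edge
    ly <- 1 + s[i] * dy / edge
    D <- if (is.null(state)) c(lm = 0, cm = 0, sm = 0) else state$D
    lz <- solve_lz(lx, ly, D)
    if (!is.null(state)) {
      # fixed point between the root solve and the explicit damage update
      for (it in 1:20) {
        def <- deformation(diag(c(lx, ly, lz)), fibers)
        en <- strain_energy(def, mat_pen)
        state_new <- update_damage_state(
          state, c(lm = en$psi_lm, cm = en$psi_cm, sm = en$psi_sm))
        lz_new <- solve_lz(lx, ly, state_new$D)
        done <- abs(lz_new - lz) < 1e-12
        state <- state_new
        lz <- lz_new
        if (done) break
      }
      D <- state$D
    }
    def <- deformation(diag(c(lx, ly, lz)), fibers)
    if (mode == "penalty") {
      st <- cauchy_stress(def, mat_pen, damage = D)
    } else {
      st0 <- cauchy_stress(def, mat_pen, damage = D, pressure = 0)
      st <- cauchy_stress(def, mat_pen, damage = D, pressure = -st0$sigma[3, 3])
    }
    rows[[i]] <- tibble::tibble(
      step = i - 1L,
      DX = (lx - 1) * edge, DY = (ly - 1) * edge, DZ = (lz - 1) * edge,
      lambda_x = lx, lambda_y = ly, lambda_z = lz, J = def$J,
      pressure = st$pressure,
      sigma_xx = st$sigma[1, 1], sigma_yy = st$sigma[2, 2],
      sigma_zz = st$sigma[3, 3],
      D_lm = D[["lm"]], D_cm = D[["cm"]], D_sm = D[["sm"]]
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("brick_result", class(out))
  attr(out, "mode") <- mode
  attr(out, "kappa0") <- if (mode == "penalty") kappa0 else NA_real_
  out
}
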