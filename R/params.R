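#' Hyperelastic material parameters
#'
#' Container for the constants of the four-fiber strain-energy function:
#' a neo-Hookean ground matrix (`mu0`), one shared pair of HGO constants for
#' the two muscular collagen families (`k1_mus`, `k2_mus`), one pair for the
#' submucosal crosswise families (`k1_sm`, `k2_sm`), and the submucosal fiber
#' half-angle. `kappa0` is the initial bulk modulus of the volumetric penalty
#' term; when `NULL` (the default) the material is treated as exactly
#' incompressible and curve-level computations enforce J = 1.
#'
#' @param mu0 Initial shear modulus of the matrix (MPa), > 0.
#' @param k1_mus,k1_sm Stress-like fiber constants (MPa), > 0.
#' @param k2_mus,k2_sm Dimensionless fiber exponents, >= 0.
#' @param kappa0 Initial bulk modulus (MPa) for penalty mode, or `NULL` for
#'   exact incompressibility.
#' @param alpha_deg Submucosal fiber half-angle (degrees).
#'
#' @return An object of class `material_params`.
#' @examples
#' material_params(k1_mus = 0.0030, k2_mus = 10.6781,
#'                 k1_sm = 0.0068, k2_sm = 13.3155)
#' @export
material_params <- function(mu0 = 1e-4, k1_mus, k2_mus, k1_sm, k2_sm,
                            kappa0 = NULL, alpha_deg = 30) {
  stopifnot(is.numeric(mu0), is.numeric(k1_mus), is.numeric(k2_mus),
            is.numeric(k1_sm), is.numeric(k2_sm))
  if (mu0 <= 0) stop("`mu0` must be > 0.", call. = FALSE)
  if (k1_mus <= 0 || k1_sm <= 0) stop("`k1_mus` and `k1_sm` must be > 0.", call. = FALSE)
  if (k2_mus < 0 || k2_sm < 0) stop("`k2_mus` and `k2_sm` must be >= 0.", call. = FALSE)
  if (!is.null(kappa0) && kappa0 <= 0) stop("`kappa0` must be > 0 when given.", call. = FALSE)
  structure(
    list(mu0 = mu0, k1_mus = k1_mus, k2_mus = k2_mus,
         k1_sm = k1_sm, k2_sm = k2_sm, kappa0 = kappa0,
         alpha_deg = alpha_deg),
    class = "material_params"
  )
}

#' Default penalty bulk modulus
#'
#' The bulk modulus is never identified from planar data; for penalty-mode
#' simulations a value far above every deviatoric stiffness enforces
#' near-incompressibility. The default is `1e4 * max(mu0, k1_mus, k1_sm)`.
#'
#' @param mat A [material_params()] object.
#' @return A bulk modulus in MPa.
#' @export
default_kappa0 <- function(mat) {
  1e4 * max(mat$mu0, mat$k1_mus, mat$k1_sm)
}

#' Per-layer damage parameters
#'
#' Damage in each load-bearing collagenous layer k in {lm, cm, sm}
#' (longitudinal muscular, circumferential muscular, submucosal) is governed
#' by an initial threshold `tau0` (MPa^1/2) on the equivalent strain and a
#' fracture energy per unit volume `gf` (MPa). Well-posedness of the
#' exponential evolution law requires `gf > tau0^2 / 2` for every layer; the
#' constructor enforces this and precomputes the exponent
#' `A = 1 / (gf / tau0^2 - 1/2)`.
#'
#' @param tau0_lm,tau0_cm,tau0_sm Initial damage thresholds (MPa^1/2), > 0.
#' @param gf_lm,gf_cm,gf_sm Fracture energies per unit volume (MPa).
#'
#' @return An object of class `damage_params`: a list with named numeric
#'   vectors `tau0`, `gf`, `A` over layers `lm`, `cm`, `sm`.
#' @examples
#' damage_params(0.1149, 0.0073, 0.0110, 0.0169, 0.0624, 0.0125)
#' @export
damage_params <- function(tau0_lm, gf_lm, tau0_cm, gf_cm, tau0_sm, gf_sm) {
  tau0 <- c(lm = tau0_lm, cm = tau0_cm, sm = tau0_sm)
  gf <- c(lm = gf_lm, cm = gf_cm, sm = gf_sm)
  if (any(!is.finite(tau0)) || any(tau0 <= 0)) {
    stop("All damage thresholds `tau0_*` must be finite and > 0.", call. = FALSE)
  }
  bad <- names(tau0)[!(gf > tau0^2 / 2 * (1 + 1e-9))]
  if (length(bad) > 0) {
    stop("`gf` must exceed `tau0^2 / 2` for layer(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  A <- vapply(names(tau0), function(k) damage_A(tau0[[k]], gf[[k]]), numeric(1))
  structure(list(tau0 = tau0, gf = gf, A = A), class = "damage_params")
}

#' Published specimen parameter table
#'
#' Fitted material and damage parameters of the four porcine large-intestine
#' specimens (S1-S4), with the per-direction coefficients of determination of
#' the original fits. Units: `mu0`, `k1_*`, `gf_*` in MPa; `tau0_*` in
#' MPa^1/2; `k2_*`, `r2_*` dimensionless.
#'
#' @param specimens Character vector of specimen ids to return.
#' @return A tibble with one row per specimen.
#' @examples
#' specimen_parameters("S1")
#' @export
specimen_parameters <- function(specimens = c("S1", "S2", "S3", "S4")) {
  tbl <- tibble::tribble(
    ~specimen, ~mu0, ~k1_mus, ~k2_mus, ~k1_sm, ~k2_sm,
    ~tau0_lm, ~gf_lm, ~tau0_cm, ~gf_cm, ~tau0_sm, ~gf_sm, ~r2_L, ~r2_C,
    "S1", 0.0001, 0.0030, 10.6781, 0.0068, 13.3155,
    0.1149, 0.0073, 0.0110, 0.0169, 0.0624, 0.0125, 0.9793, 0.9377,
    "S2", 0.0001, 0.0138, 0.6804, 0.0002, 7.4843,
    0.1241, 0.0083, 0.2236, 0.0387, 0.0379, 0.0089, 0.9931, 0.9852,
    "S3", 0.0001, 0.0096, 4.1802, 0.0094, 7.0591,
    0.1439, 0.0118, 0.0257, 0.0346, 0.0750, 0.0224, 0.9855, 0.9824,
    "S4", 0.0001, 0.0272, 0.0144, 0.0055, 2.9810,
    0.2308, 0.0278, 0.2921, 0.0461, 0.1302, 0.0738, 0.9873, 0.9775
  )
  unknown <- setdiff(specimens, tbl$specimen)
  if (length(unknown) > 0) {
    stop("Unknown specimen id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  tbl[match(specimens, tbl$specimen), , drop = FALSE]
}

#' Convert a parameter-table row to parameter objects
#'
#' @param row A one-row data frame in the [specimen_parameters()] schema.
#' @return `as_material_params()` returns a [material_params()] object;
#'   `as_damage_params()` a [damage_params()] object.
#' @examples
#' s1 <- specimen_parameters("S1")
#' as_material_params(s1)
#' as_damage_params(s1)
#' @export
as_material_params <- function(row) {
  row <- as.list(dplyr::slice(tibble::as_tibble(row), 1))
  material_params(
    mu0 = row$mu0, k1_mus = row$k1_mus, k2_mus = row$k2_mus,
    k1_sm = row$k1_sm, k2_sm = row$k2_sm,
    kappa0 = row$kappa0, alpha_deg = row$alpha_deg %||% 30
  )
}

#' @rdname as_material_params
#' @export
as_damage_params <- function(row) {
  row <- as.list(dplyr::slice(tibble::as_tibble(row), 1))
  damage_params(row$tau0_lm, row$gf_lm, row$tau0_cm, row$gf_cm,
                row$tau0_sm, row$gf_sm)
}

#' @export
print.material_params <- function(x, ...) {
  cat("<material_params>\n")
  cat(sprintf("  mu0 = %g MPa; k1_mus = %g MPa, k2_mus = %g; k1_sm = %g MPa, k2_sm = %g\n",
              x$mu0, x$k1_mus, x$k2_mus, x$k1_sm, x$k2_sm))
  cat(sprintf("  alpha = %g deg; %s\n", x$alpha_deg,
              if (is.null(x$kappa0)) "incompressible" else
                sprintf("kappa0 = %g MPa (penalty)", x$kappa0)))
  invisible(x)
}

#' @export
print.damage_params <- function(x, ...) {
  cat("<damage_params>\n")
  print(round(rbind(tau0 = x$tau0, gf = x$gf, A = x$A), 5))
  invisible(x)
}

check_damage_scalars <- function(damage) {
  if (is.null(names(damage))) names(damage) <- c("lm", "cm", "sm")
  damage <- damage[c("lm", "cm", "sm")]
  if (any(is.na(damage)) || any(damage < 0) || any(damage > 1)) {
    stop("Damage scalars must be named (lm, cm, sm) values in [0, 1].",
         call. = FALSE)
  }
  damage
}
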