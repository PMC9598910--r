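#' Read and write biaxial curves (CSV dialect)
#'
#' The on-disk dialect is comma-separated, dot-decimal UTF-8 with header
#' `time_s,lambda_L,lambda_C,sigma_LL_MPa,sigma_CC_MPa` and optional extra
#' columns `E_LL,E_CC,P_L_N,P_C_N`. On read, stretches are reconstructed
#' from the Green-Lagrange channels (`lambda = sqrt(2 E + 1)`) when the
#' `lambda_*` columns are absent, and stresses from the force channels
#' (`sigma = P lambda / (L T)`) when the `sigma_*` columns are absent (this
#' requires `thickness`). Validation: schema mismatches name the offending
#' column; time must be non-decreasing; the first frame must sit at
#' `lambda = 1` within `lambda_tol`.
#'
#' @param path File path.
#' @param edge_length Specimen edge length L (mm), used only when stresses
#'   must be derived from forces.
#' @param thickness Specimen thickness T (mm), required to derive stresses
#'   from forces.
#' @param lambda_tol Tolerance on the initial stretch.
#' @return A `biaxial_curve` tibble.
#' @export
read_biaxial_curve <- function(path, edge_length = 40, thickness = NULL,
                               lambda_tol = 0.02) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  known <- c("time_s", "lambda_L", "lambda_C", "sigma_LL_MPa", "sigma_CC_MPa",
             "E_LL", "E_CC", "P_L_N", "P_C_N")
  unknown <- setdiff(names(df), known)
  if (length(unknown) > 0) {
    stop("Unrecognized column(s) in curve file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (dir in c("L", "C")) {
    lam_col <- paste0("lambda_", dir)
    e_col <- paste0("E_", dir, dir)
    if (!lam_col %in% names(df)) {
      if (!e_col %in% names(df)) {
        stop(sprintf("Missing column `%s` (or `%s` to derive it from).",
                     lam_col, e_col), call. = FALSE)
      }
      df[[lam_col]] <- stretch_from_green_lagrange(df[[e_col]])
    }
    sig_col <- paste0("sigma_", dir, dir, "_MPa")
    p_col <- paste0("P_", dir, "_N")
    if (!sig_col %in% names(df)) {
      if (!p_col %in% names(df) || is.null(thickness)) {
        stop(sprintf("Missing column `%s` (or `%s` plus `thickness` to derive it from).",
                     sig_col, p_col), call. = FALSE)
      }
      df[[sig_col]] <- membrane_true_stress(df[[p_col]], df[[lam_col]],
                                            edge_length, thickness)
    }
  }
  if ("time_s" %in% names(df) && is.unsorted(df$time_s)) {
    stop("Column `time_s` must be non-decreasing.", call. = FALSE)
  }
  start <- c(df$lambda_L[1], df$lambda_C[1])
  if (any(abs(start - 1) > lambda_tol)) {
    stop(sprintf("First frame must be at lambda = 1 +/- %g (got %.4f, %.4f).",
                 lambda_tol, start[1], start[2]), call. = FALSE)
  }
  if (any(df$lambda_L <= 0) || any(df$lambda_C <= 0)) {
    stop("Stretches must be > 0.", call. = FALSE)
  }
  class(df) <- c("biaxial_curve", class(df))
  attr(df, "geometry") <- list(L = edge_length, T = thickness)
  df
}

#' @rdname read_biaxial_curve
#' @param curve A biaxial curve tibble.
#' @param overwrite Allow replacing an existing file.
#' @export
write_biaxial_curve <- function(curve, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("File exists (use `overwrite = TRUE`): ", path, call. = FALSE)
  }
  readr::write_csv(as.data.frame(curve), path, progress = FALSE)
  invisible(path)
}

#' Read and write parameter files (JSON schema)
#'
#' The JSON schema is keyed exactly
#' `mu0, kappa0, k1_mus, k2_mus, k1_sm, k2_sm, tau0_lm, gf_lm, tau0_cm,
#' gf_cm, tau0_sm, gf_sm, alpha_deg` (units MPa / MPa^1/2 / degrees;
#' `kappa0` and `alpha_deg` optional). A missing `kappa0` selects exact
#' incompressibility. Feasibility `gf > tau0^2/2` is checked at load time
#' and violations name the layer.
#'
#' @param path File path.
#' @return A list with elements `material` ([material_params()]) and
#'   `damage` ([damage_params()]).
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("mu0", "k1_mus", "k2_mus", "k1_sm", "k2_sm",
                "tau0_lm", "gf_lm", "tau0_cm", "gf_cm", "tau0_sm", "gf_sm")
  missing_keys <- setdiff(required, names(x))
  if (length(missing_keys) > 0) {
    stop("Parameter file is missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  list(
    material = material_params(
      mu0 = x$mu0, k1_mus = x$k1_mus, k2_mus = x$k2_mus,
      k1_sm = x$k1_sm, k2_sm = x$k2_sm,
      kappa0 = x$kappa0, alpha_deg = x$alpha_deg %||% 30
    ),
    damage = damage_params(x$tau0_lm, x$gf_lm, x$tau0_cm, x$gf_cm,
                           x$tau0_sm, x$gf_sm)
  )
}

#' @rdname read_params_json
#' @param mat A [material_params()].
#' @param dmg A [damage_params()] or `NULL` to omit damage keys.
#' @param overwrite Allow replacing an existing file.
#' @export
write_params_json <- function(mat, dmg, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("File exists (use `overwrite = TRUE`): ", path, call. = FALSE)
  }
  x <- list(mu0 = mat$mu0, kappa0 = mat$kappa0,
            k1_mus = mat$k1_mus, k2_mus = mat$k2_mus,
            k1_sm = mat$k1_sm, k2_sm = mat$k2_sm)
  if (!is.null(dmg)) {
    x <- c(x, list(tau0_lm = dmg$tau0[["lm"]], gf_lm = dmg$gf[["lm"]],
                   tau0_cm = dmg$tau0[["cm"]], gf_cm = dmg$gf[["cm"]],
                   tau0_sm = dmg$tau0[["sm"]], gf_sm = dmg$gf[["sm"]]))
  }
  x$alpha_deg <- mat$alpha_deg
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a damage trajectory (CSV dialect)
#'
#' Exports the per-frame equivalent strains and damage scalars of a
#' [run_path()] result with header
#' `lambda_L,lambda_C,tau_lm,tau_cm,tau_sm,D_lm,D_cm,D_sm`.
#'
#' @param traj A [run_path()] result.
#' @param path File path.
#' @param overwrite Allow replacing an existing file.
#' @export
write_damage_trajectory <- function(traj, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("File exists (use `overwrite = TRUE`): ", path, call. = FALSE)
  }
  cols <- c("lambda_L", "lambda_C", "tau_lm", "tau_cm", "tau_sm",
            "D_lm", "D_cm", "D_sm")
  missing_cols <- setdiff(cols, names(traj))
  if (length(missing_cols) > 0) {
    stop("Trajectory is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(as.data.frame(traj)[cols], path, progress = FALSE)
  invisible(path)
}
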