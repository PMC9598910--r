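#' Biaxial rig protocol description
#'
#' Collects the geometry, kinematic and sampling constants of the biaxial
#' testing protocol emulated by the generator: 40 mm x 40 mm square
#' specimens, displacement-controlled loading at 10 mm/min per axis sampled
#' at 1 Hz, and force-to-true-stress conversion under incompressibility.
#' Thickness is either fixed (default 1.188 mm, the study mean) or sampled
#' per specimen from `thickness_range` (default 0.68-2.15 mm, the reported
#' range; a uniform draw is a documented stand-in, the true distribution is
#' unreported).
#'
#' @param edge_length Specimen edge length L (mm).
#' @param thickness Fixed specimen thickness T (mm), used when
#'   `thickness_range` is `NULL`.
#' @param thickness_range Optional length-2 range (mm) to sample T from.
#' @param speed Crosshead speed per axis (mm/min).
#' @param frame_rate Sampling rate (Hz).
#' @param max_stretch Stretch at which the ramp stops if rupture has not
#'   occurred earlier.
#' @param damage_cap Damage level at which the specimen is considered
#'   ruptured and the record truncated.
#' @param noise_rel Relative (multiplicative Gaussian) noise on the recorded
#'   forces; 0 disables.
#' @param force_floor Additive force-sensor noise floor (N, standard
#'   deviation); 0 disables.
#' @return An object of class `rig_protocol`.
#' @examples
#' rig_protocol()
#' @export
rig_protocol <- function(edge_length = 40, thickness = 1.188,
                         thickness_range = NULL, speed = 10, frame_rate = 1,
                         max_stretch = 1.6, damage_cap = 0.99,
                         noise_rel = 0.02, force_floor = 0.01) {
  stopifnot(edge_length > 0, thickness > 0, speed > 0, frame_rate > 0,
            max_stretch > 1, damage_cap > 0, damage_cap <= 1,
            noise_rel >= 0, force_floor >= 0)
  if (!is.null(thickness_range)) {
    stopifnot(length(thickness_range) == 2, all(thickness_range > 0),
              thickness_range[1] < thickness_range[2])
  }
  structure(
    list(edge_length = edge_length, thickness = thickness,
         thickness_range = thickness_range, speed = speed,
         frame_rate = frame_rate, max_stretch = max_stretch,
         damage_cap = damage_cap, noise_rel = noise_rel,
         force_floor = force_floor),
    class = "rig_protocol"
  )
}

#' Generate one synthetic equibiaxial experiment
#'
#' Builds the stretch grid of the displacement-controlled ramp
#' (`lambda(t) = 1 + (speed / 60 / L) * t` on both axes, one frame per
#' `1 / frame_rate` seconds), evaluates the noise-free damage-coupled
#' forward model, truncates at rupture (first frame where any layer's damage
#' exceeds `damage_cap`), back-computes the actuator forces
#' `P = sigma * L * T / lambda`, applies multiplicative Gaussian noise plus
#' an additive sensor floor to the forces, and re-derives the noisy true
#' stresses. Green-Lagrange channels `E = (lambda^2 - 1) / 2` are included.
#'
#' @param mat A [material_params()].
#' @param dmg A [damage_params()] or `NULL` (no damage, ramp runs to
#'   `max_stretch`).
#' @param protocol A [rig_protocol()].
#' @param seed Optional integer seed; the generator is deterministic given
#'   `(params, protocol, seed)`.
#' @param noise If `FALSE`, noise is suppressed regardless of the protocol
#'   settings (ground-truth curve).
#' @return A tibble of class `biaxial_curve` with columns `time_s`,
#'   `lambda_L`, `lambda_C`, `sigma_LL_MPa`, `sigma_CC_MPa`, `E_LL`, `E_CC`,
#'   `P_L_N`, `P_C_N`. Attributes: `truth` (the noise-free [run_path()]
#'   trajectory incl. damage), `geometry` (list with `L`, `T`), `seed`.
#' @examples
#' s1 <- specimen_parameters("S1")
#' curve <- generate_curve(as_material_params(s1), as_damage_params(s1),
#'                         rig_protocol(), seed = 1)
#' @export
generate_curve <- function(mat, dmg, protocol = rig_protocol(), seed = NULL,
                           noise = TRUE) {
  stopifnot(inherits(protocol, "rig_protocol"))
  run <- function() {
    L <- protocol$edge_length
    T <- if (is.null(protocol$thickness_range)) protocol$thickness else
      stats::runif(1, protocol$thickness_range[1], protocol$thickness_range[2])
    rate <- protocol$speed / 60 / L            # stretch per second
    t_end <- (protocol$max_stretch - 1) / rate
    time_s <- seq(0, t_end, by = 1 / protocol$frame_rate)
    lam <- 1 + rate * time_s
    path <- tibble::tibble(time_s = time_s, lambda_L = lam, lambda_C = lam)
    truth <- run_path(path, mat, dmg)
    if (!is.null(dmg)) {
      Dmax <- pmax(truth$D_lm, truth$D_cm, truth$D_sm)
      keep <- Dmax <= protocol$damage_cap
      if (!all(keep)) keep <- seq_len(min(which(!keep)) - 1)
      truth <- truth[keep, , drop = FALSE]
    }
    P_L <- membrane_force(truth$sigma_LL, truth$lambda_L, L, T)
    P_C <- membrane_force(truth$sigma_CC, truth$lambda_C, L, T)
    n <- nrow(truth)
    if (noise && (protocol$noise_rel > 0 || protocol$force_floor > 0)) {
      P_L <- P_L * (1 + stats::rnorm(n, 0, protocol$noise_rel)) +
        stats::rnorm(n, 0, protocol$force_floor)
      P_C <- P_C * (1 + stats::rnorm(n, 0, protocol$noise_rel)) +
        stats::rnorm(n, 0, protocol$force_floor)
    }
    curve <- tibble::tibble(
      time_s = truth$time_s,
      lambda_L = truth$lambda_L,
      lambda_C = truth$lambda_C,
      sigma_LL_MPa = membrane_true_stress(P_L, truth$lambda_L, L, T),
      sigma_CC_MPa = membrane_true_stress(P_C, truth$lambda_C, L, T),
      E_LL = green_lagrange_from_stretch(truth$lambda_L),
      E_CC = green_lagrange_from_stretch(truth$lambda_C),
      P_L_N = P_L,
      P_C_N = P_C
    )
    attr(curve, "truth") <- truth
    attr(curve, "geometry") <- list(L = L, T = T)
    attr(curve, "seed") <- seed
    class(curve) <- c("biaxial_curve", class(curve))
    curve
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a seeded cohort of synthetic experiments
#'
#' One or more replicates per row of a [specimen_parameters()]-style table.
#' Per-curve seeds are drawn reproducibly from the master seed, so identical
#' inputs yield bitwise-identical cohorts.
#'
#' @param param_table A data frame in the [specimen_parameters()] schema.
#' @param protocol A [rig_protocol()].
#' @param n_replicates Replicates per specimen row.
#' @param seed Master integer seed.
#' @return A list with `curves` (named list of [generate_curve()] outputs,
#'   names `"<specimen>_r<replicate>"`) and `manifest` (a tibble recording
#'   specimen, replicate, per-curve seed, thickness and frame count).
#' @examples
#' cohort <- generate_cohort(specimen_parameters("S1"), n_replicates = 2,
#'                           seed = 7)
#' cohort$manifest
#' @export
generate_cohort <- function(param_table, protocol = rig_protocol(),
                            n_replicates = 1, seed = 1) {
  stopifnot(nrow(param_table) >= 1, n_replicates >= 1)
  n_curves <- nrow(param_table) * n_replicates
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_curves))
  grid <- tidyr::expand_grid(
    row = seq_len(nrow(param_table)),
    replicate = seq_len(n_replicates)
  )
  curves <- purrr::pmap(list(grid$row, grid$replicate, seeds),
    function(i, r, s) {
      row <- param_table[i, , drop = FALSE]
      generate_curve(as_material_params(row), as_damage_params(row),
                     protocol, seed = s)
    })
  ids <- param_table$specimen %||% paste0("row", seq_len(nrow(param_table)))
  names(curves) <- paste0(ids[grid$row], "_r", grid$replicate)
  manifest <- tibble::tibble(
    specimen = ids[grid$row],
    replicate = grid$replicate,
    seed = seeds,
    thickness_mm = purrr::map_dbl(curves, ~ attr(.x, "geometry")$T),
    n_frames = purrr::map_int(curves, nrow),
    master_seed = seed
  )
  list(curves = curves, manifest = manifest)
}
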