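#' Coefficient of determination of a fitted stress curve
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the mean of the
#' experimental stresses; computed per loading direction.
#'
#' @param sigma_exp Measured stresses (MPa).
#' @param sigma_fit Model-predicted stresses (MPa), same length.
#' @return R-squared (<= 1).
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(sigma_exp, sigma_fit) {
  if (length(sigma_exp) != length(sigma_fit)) {
    stop("`sigma_exp` and `sigma_fit` must have equal length.", call. = FALSE)
  }
  if (length(sigma_exp) < 2) stop("Need at least two observations.", call. = FALSE)
  ss_tot <- sum((sigma_exp - mean(sigma_exp))^2)
  if (ss_tot == 0) {
    stop("Constant experimental series: R-squared undefined.", call. = FALSE)
  }
  1 - sum((sigma_exp - sigma_fit)^2) / ss_tot
}

#' Forward model prediction on a measured stretch grid
#'
#' Deterministic damage-coupled forward pass along the (assumed monotone)
#' measured path; a thin wrapper around [run_path()] returning only the
#' stress columns.
#'
#' @param mat A [material_params()].
#' @param dmg A [damage_params()] or `NULL`.
#' @param lambda_L,lambda_C Stretch sequences.
#' @return A tibble with `sigma_LL`, `sigma_CC` (MPa).
#' @export
predict_biaxial <- function(mat, dmg, lambda_L, lambda_C) {
  out <- run_path(tibble::tibble(lambda_L = lambda_L, lambda_C = lambda_C),
                  mat, dmg)
  out[c("sigma_LL", "sigma_CC")]
}

#' Fitting configuration
#'
#' Tuning knobs of [fit_biaxial()]. The defaults implement the shipped
#' procedure: a hyperelastic-first start, 16 seeded multi-starts of the
#' damage stage, joint refinement of the three best candidates, and
#' heteroscedasticity-consistent ("relative") residual weighting matched to
#' the multiplicative force-sensor noise of the rig.
#'
#' @param n_starts Number of seeded damage-stage starts.
#' @param n_polish Number of top-ranked damage-stage candidates carried into
#'   joint refinement.
#' @param seed Integer seed; the whole multi-start is deterministic given
#'   the seed.
#' @param mu0 Matrix shear modulus held fixed at its floor (MPa). All
#'   published specimen fits sit on this floor, so it is not searched.
#' @param k1_bounds,k2_bounds Box bounds for the fiber constants; `k1` and
#'   `k2` are searched in log space (`k2` bounds default to `[1e-3, 1e2]`
#'   for conditioning of the exponential model).
#' @param tau0_bounds Box bounds for the damage thresholds (MPa^1/2); start
#'   points are placed relative to the observed equivalent-strain range of
#'   the curve.
#' @param u_bounds Bounds for the fracture-energy reparameterization
#'   `gf = tau0^2 / 2 * (1 + exp(u))`, which enforces feasibility
#'   `gf > tau0^2 / 2` by construction.
#' @param weighting `"relative"` (default; residuals scaled by
#'   `1 / sqrt(sigma^2 + (0.02 max sigma)^2)`, the natural objective under
#'   multiplicative noise) or `"absolute"` (plain pooled squared residual).
#' @param strategy `"sequential-joint"` (linearized toe regression seeds the
#'   fiber constants, then damage multi-start, then joint refinement;
#'   default) or `"joint"` (generic start for the fiber constants, same
#'   machinery).
#' @param qc Apply curve quality control before fitting (see
#'   [qc_biaxial()]).
#' @param qc_j_frac Fraction of initial samples over which the J-shape
#'   (monotone rise) is required.
#' @param qc_soft_frac Trailing fraction of samples over which softening
#'   (negative slope) is required in both directions.
#' @param require_softening Require concurrent softening in both directions
#'   (the selection rule used for experimental records; off by default
#'   because rupture-truncated synthetic records need not soften visibly in
#'   both directions even though all layers damage).
#' @param nm_maxit Nelder-Mead iteration cap per (re)start.
#' @param maxiter Levenberg-Marquardt iteration cap for the final polish.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 16, n_polish = 3, seed = 1, mu0 = 1e-4,
                       k1_bounds = c(1e-8, 10), k2_bounds = c(1e-3, 1e2),
                       tau0_bounds = c(1e-6, 10), u_bounds = c(-20, 20),
                       weighting = c("relative", "absolute"),
                       strategy = c("sequential-joint", "joint"),
                       qc = TRUE, qc_j_frac = 0.8,
                       qc_soft_frac = 0.1, require_softening = FALSE,
                       nm_maxit = 3000, maxiter = 500) {
  structure(
    list(n_starts = n_starts, n_polish = n_polish, seed = seed, mu0 = mu0,
         k1_bounds = k1_bounds, k2_bounds = k2_bounds,
         tau0_bounds = tau0_bounds, u_bounds = u_bounds,
         weighting = match.arg(weighting), strategy = match.arg(strategy),
         qc = qc, qc_j_frac = qc_j_frac, qc_soft_frac = qc_soft_frac,
         require_softening = require_softening,
         nm_maxit = nm_maxit, maxiter = maxiter),
    class = "fit_config"
  )
}

#' Curve quality control
#'
#' Admissibility predicate for fitting: the stress-stretch record must be
#' J-shaped (monotone rise of the lightly smoothed stress over the leading
#' `qc_j_frac` of samples, both directions) and, when `require_softening` is
#' set, must soften concurrently (negative trailing slope in *both*
#' directions) — the selection rule applied to experimental records, since
#' records without concurrent softening carry no information on the damage
#' parameters of all layers.
#'
#' @param curve A biaxial curve tibble (see [read_biaxial_curve()] for the
#'   column dialect).
#' @param config A [fit_config()].
#' @return Invisibly `TRUE`; otherwise an error describing the failure.
#' @export
qc_biaxial <- function(curve, config = fit_config()) {
  smooth5 <- function(x) {
    s <- as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
    s[is.na(s)] <- x[is.na(s)]
    s
  }
  for (dir in c("sigma_LL_MPa", "sigma_CC_MPa")) {
    sig <- curve[[dir]]
    n <- length(sig)
    head_idx <- seq_len(max(5, floor(config$qc_j_frac * n)))
    s <- smooth5(sig)[head_idx]
    s <- s[is.finite(s)]
    drop_tol <- 0.05 * max(abs(s), 1e-12)
    if (any(cummax(s) - s > drop_tol)) {
      stop(sprintf("QC failure: `%s` is not J-shaped (non-monotone rise over the first %d%% of samples).",
                   dir, round(100 * config$qc_j_frac)), call. = FALSE)
    }
  }
  if (config$require_softening) {
    soft <- vapply(c("sigma_LL_MPa", "sigma_CC_MPa"), function(dir) {
      sig <- curve[[dir]]
      n <- length(sig)
      tail_idx <- seq(max(1, n - max(3, ceiling(config$qc_soft_frac * n)) + 1), n)
      unname(stats::coef(stats::lm(sig[tail_idx] ~ tail_idx))[2]) < 0
    }, logical(1))
    if (!all(soft)) {
      stop("QC failure: no concurrent softening in both directions (damage parameters unidentifiable).",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# ---- internal parameter transforms ------------------------------------------
# theta = (lk1m, lk2m, lk1s, lk2s, lt_lm, lt_cm, lt_sm, u_lm, u_cm, u_sm):
# log fiber constants, log thresholds, and the fracture-energy coordinate
# gf = tau0^2/2 (1 + exp(u)) <=> A = 2 exp(-u).

theta_names <- c("lk1m", "lk2m", "lk1s", "lk2s",
                 "lt_lm", "lt_cm", "lt_sm", "u_lm", "u_cm", "u_sm")

theta_to_params <- function(theta, config) {
  # clamp to the search box so unconstrained (Nelder-Mead) excursions can
  # neither overflow nor produce an infeasible damage pair
  b <- theta_bounds(config)
  theta <- pmin(pmax(theta, b$lower), b$upper)
  tau0 <- exp(theta[5:7])
  gf <- tau0^2 / 2 * (1 + pmax(exp(theta[8:10]), 1e-8))
  list(
    mat = material_params(
      mu0 = config$mu0,
      k1_mus = exp(theta[[1]]), k2_mus = exp(theta[[2]]),
      k1_sm = exp(theta[[3]]), k2_sm = exp(theta[[4]])
    ),
    dmg = damage_params(tau0[[1]], gf[[1]], tau0[[2]], gf[[2]],
                        tau0[[3]], gf[[3]])
  )
}

params_to_theta <- function(mat, dmg) {
  u <- log(pmax(2 * dmg$gf / dmg$tau0^2 - 1, 1e-12))
  stats::setNames(
    c(log(mat$k1_mus), log(mat$k2_mus), log(mat$k1_sm), log(mat$k2_sm),
      log(dmg$tau0[["lm"]]), log(dmg$tau0[["cm"]]), log(dmg$tau0[["sm"]]),
      u[["lm"]], u[["cm"]], u[["sm"]]),
    theta_names)
}

theta_bounds <- function(config) {
  lower <- c(log(config$k1_bounds[1]), log(config$k2_bounds[1]),
             log(config$k1_bounds[1]), log(config$k2_bounds[1]),
             rep(log(config$tau0_bounds[1]), 3), rep(config$u_bounds[1], 3))
  upper <- c(log(config$k1_bounds[2]), log(config$k2_bounds[2]),
             log(config$k1_bounds[2]), log(config$k2_bounds[2]),
             rep(log(config$tau0_bounds[2]), 3), rep(config$u_bounds[2], 3))
  list(lower = stats::setNames(lower, theta_names),
       upper = stats::setNames(upper, theta_names))
}

# Toe-region linearization: in the toe of a near-equibiaxial record the
# submucosal response separates from the muscular one through
# sigma_LL - sigma_CC, and log(psi' / x) = log k1 + k2 x^2 is linear in x^2,
# giving start values for (k1, k2) of both families by regression.
toe_start <- function(curve, config) {
  lamL <- curve$lambda_L
  lamC <- curve$lambda_C
  a <- pi / 6
  c2 <- cos(a)^2
  s2 <- sin(a)^2
  L2 <- lamL^2
  lz2 <- 1 / (L2 * lamC^2)
  idx <- seq_len(max(8, floor(0.3 * length(lamL))))
  lam2 <- L2[idx]
  x <- lam2 - 1
  ps <- (curve$sigma_LL_MPa[idx] - curve$sigma_CC_MPa[idx]) /
    (4 * lam2 * (c2 - s2))
  pm <- (curve$sigma_LL_MPa[idx] - config$mu0 * (lam2 - lz2[idx]) -
           4 * c2 * ps * lam2) / (2 * lam2)
  est_fam <- function(psi_p) {
    ok <- is.finite(psi_p) & psi_p > 0 & x > 1e-4 &
      psi_p > 0.02 * max(psi_p, 0, na.rm = TRUE)
    if (sum(ok) < 4) return(c(0.01, 5))
    f <- stats::lm(log(psi_p[ok] / x[ok]) ~ I(x[ok]^2))
    c(min(max(exp(unname(stats::coef(f)[1])), config$k1_bounds[1]), config$k1_bounds[2]),
      min(max(unname(stats::coef(f)[2]), config$k2_bounds[1]), config$k2_bounds[2]))
  }
  km <- est_fam(pm)
  ks <- est_fam(ps)
  c(log(km[1]), log(km[2]), log(ks[1]), log(ks[2]))
}

# ---- the fit ----------------------------------------------------------------

#' Fit material and damage parameters to a biaxial curve
#'
#' Simultaneous two-direction nonlinear least squares over the four fiber
#' constants and the six damage parameters, with the matrix modulus `mu0`
#' held at its floor. `k1`, `k2` and `tau0` are searched in log space; the
#' fracture energies through `gf = tau0^2/2 (1 + exp(u))`, so every iterate
#' satisfies `gf > tau0^2/2` by construction. The shipped procedure is
#' staged:
#' \enumerate{
#'   \item a linearized regression of the toe region seeds the fiber
#'     constants (`strategy = "sequential-joint"`);
#'   \item `n_starts` seeded Nelder-Mead runs over the six damage
#'     parameters (fiber constants frozen), with threshold starts spread
#'     across — and beyond — the observed equivalent-strain range so that
#'     layers may come out undamaged;
#'   \item the `n_polish` best candidates are refined jointly over all ten
#'     parameters (Nelder-Mead, then a bounded Levenberg-Marquardt polish
#'     via [minpack.lm::nls.lm], kept only if it improves the objective).
#' }
#' Residuals from both directions are pooled with equal weight; under the
#' default `weighting = "relative"` they are scaled to account for the
#' multiplicative sensor noise. The search is deterministic given
#' `config$seed`.
#'
#' @param curve A biaxial curve tibble with columns `lambda_L`, `lambda_C`,
#'   `sigma_LL_MPa`, `sigma_CC_MPa` (the [generate_curve()] /
#'   [read_biaxial_curve()] dialect).
#' @param config A [fit_config()].
#' @return An object of class `biaxial_fit`; see [tidy.biaxial_fit()],
#'   [glance.biaxial_fit()], [autoplot.biaxial_fit()].
#' @examples
#' \donttest{
#' s1 <- specimen_parameters("S1")
#' curve <- generate_curve(as_material_params(s1), as_damage_params(s1),
#'                         rig_protocol(noise_rel = 0, force_floor = 0),
#'                         noise = FALSE)
#' fit <- fit_biaxial(curve, fit_config(n_starts = 6))
#' glance(fit)
#' }
#' @export
fit_biaxial <- function(curve, config = fit_config()) {
  needed <- c("lambda_L", "lambda_C", "sigma_LL_MPa", "sigma_CC_MPa")
  missing_cols <- setdiff(needed, names(curve))
  if (length(missing_cols) > 0) {
    stop("Curve is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (config$qc) qc_biaxial(curve, config)

  lam_L <- curve$lambda_L
  lam_C <- curve$lambda_C
  obs <- c(curve$sigma_LL_MPa, curve$sigma_CC_MPa)
  w <- if (config$weighting == "relative") {
    1 / sqrt(obs^2 + (0.02 * max(abs(obs)))^2)
  } else {
    rep(1, length(obs))
  }
  wss_tot <- sum((w * obs - mean(w * obs))^2)
  bounds <- theta_bounds(config)

  fwd_theta <- function(theta) {
    p <- theta_to_params(theta, config)
    f <- forward_biaxial(p$mat, p$dmg, lam_L, lam_C)
    c(f$sigma_LL, f$sigma_CC)
  }
  wres <- function(theta) w * (fwd_theta(theta) - obs)
  wobj <- function(theta) {
    r <- wres(theta)
    sum(r * r)
  }

  result <- withr::with_seed(config$seed, {
    th_k <- if (config$strategy == "sequential-joint") {
      toe_start(curve, config)
    } else {
      c(log(0.01), log(5), log(0.01), log(5))
    }

    # observed equivalent-strain maxima under the start fiber constants
    p0 <- material_params(mu0 = config$mu0,
                          k1_mus = exp(th_k[1]), k2_mus = exp(th_k[2]),
                          k1_sm = exp(th_k[3]), k2_sm = exp(th_k[4]))
    f0 <- forward_biaxial(p0, NULL, lam_L, lam_C)
    tau_max_obs <- pmax(c(max(f0$tau_lm), max(f0$tau_cm), max(f0$tau_sm)),
                        1e-5)

    n_starts <- max(config$n_starts, 3)
    fracs <- rbind(c(0.5, 0.5, 0.5), c(0.8, 0.8, 0.8), c(1.3, 1.3, 1.3),
                   matrix(exp(stats::runif(3 * (n_starts - 3),
                                           log(0.15), log(1.6))), ncol = 3))
    us <- rbind(c(1, 1, 1), c(3, 3, 3), c(1, 1, 1),
                matrix(stats::runif(3 * (n_starts - 3), -2, 6), ncol = 3))

    wobj6 <- function(thd) wobj(c(th_k, thd))
    nm <- function(par, fn, maxit) {
      o <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-14))
      stats::optim(o$par, fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-14))
    }

    cand <- vector("list", n_starts)
    early <- FALSE
    for (i in seq_len(n_starts)) {
      th0d <- c(pmin(log(fracs[i, ] * tau_max_obs), bounds$upper[5:7]), us[i, ])
      o <- nm(th0d, wobj6, config$nm_maxit)
      cand[[i]] <- list(v = o$value, thd = o$par)
      if (o$value < 1e-14 * wss_tot) {
        early <- TRUE
        break
      }
    }
    cand <- cand[!vapply(cand, is.null, logical(1))]
    ord <- order(vapply(cand, function(z) z$v, numeric(1)))
    stage_b <- tibble::tibble(
      start = seq_along(cand),
      objective = vapply(cand, function(z) z$v, numeric(1))
    )

    best <- NULL
    for (j in ord[seq_len(min(config$n_polish, length(ord)))]) {
      th <- c(th_k, cand[[j]]$thd)
      o <- nm(th, wobj, 2 * config$nm_maxit)
      th <- o$par
      v <- o$value
      lm_fit <- try(suppressWarnings(minpack.lm::nls.lm(
        par = th, fn = wres, lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                             ftol = 1e-15, ptol = 1e-15,
                                             maxfev = 100000))),
        silent = TRUE)
      if (!inherits(lm_fit, "try-error")) {
        v_lm <- sum(stats::residuals(lm_fit)^2)
        if (v_lm < v) {
          th <- stats::coef(lm_fit)
          v <- v_lm
        }
      }
      th <- pmin(pmax(th, bounds$lower), bounds$upper)
      if (is.null(best) || v < best$v) best <- list(v = v, theta = th, start = j)
      if (early || v < 1e-14 * wss_tot) break
    }
    list(best = best, stage_b = stage_b)
  })

  best <- result$best
  if (is.null(best)) stop("All multi-start optimizations failed.", call. = FALSE)
  theta <- stats::setNames(best$theta, theta_names)
  p <- theta_to_params(theta, config)
  pred <- predict_biaxial(p$mat, p$dmg, lam_L, lam_C)
  res <- c(pred$sigma_LL, pred$sigma_CC) - obs
  structure(
    list(material = p$mat, damage = p$dmg,
         r2_L = r_squared(curve$sigma_LL_MPa, pred$sigma_LL),
         r2_C = r_squared(curve$sigma_CC_MPa, pred$sigma_CC),
         objective = best$v,
         residual_norm = sqrt(sum(res^2)),
         theta = theta,
         best_start = best$start,
         starts = result$stage_b,
         seed = config$seed, config = config,
         curve = tibble::as_tibble(curve)[needed],
         fitted = pred),
    class = "biaxial_fit"
  )
}

# ---- methods ----------------------------------------------------------------

#' @export
print.biaxial_fit <- function(x, ...) {
  cat("<biaxial_fit>\n")
  cat(sprintf("  R2 (L) = %.4f, R2 (C) = %.4f, residual norm = %.3g MPa\n",
              x$r2_L, x$r2_C, x$residual_norm))
  cat(sprintf("  objective %.3g, best damage-stage start #%d of %d\n",
              x$objective, x$best_start, nrow(x$starts)))
  print(x$material)
  print(x$damage)
  invisible(x)
}

#' Tidy and summarize a biaxial fit
#'
#' `tidy()` returns one row per model parameter; `glance()` a one-row model
#' summary with the per-direction coefficients of determination.
#'
#' @param x A `biaxial_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy biaxial_fit
#' @export
tidy.biaxial_fit <- function(x, ...) {
  m <- x$material
  d <- x$damage
  tibble::tibble(
    term = c("mu0", "k1_mus", "k2_mus", "k1_sm", "k2_sm",
             "tau0_lm", "gf_lm", "tau0_cm", "gf_cm", "tau0_sm", "gf_sm"),
    estimate = c(m$mu0, m$k1_mus, m$k2_mus, m$k1_sm, m$k2_sm,
                 d$tau0[["lm"]], d$gf[["lm"]], d$tau0[["cm"]], d$gf[["cm"]],
                 d$tau0[["sm"]], d$gf[["sm"]]),
    unit = c("MPa", "MPa", "", "MPa", "", "MPa^1/2", "MPa", "MPa^1/2", "MPa",
             "MPa^1/2", "MPa"),
    fixed = c(TRUE, rep(FALSE, 10))
  )
}

#' @rdname tidy.biaxial_fit
#' @method glance biaxial_fit
#' @export
glance.biaxial_fit <- function(x, ...) {
  tibble::tibble(
    r2_L = x$r2_L, r2_C = x$r2_C,
    residual_norm = x$residual_norm,
    objective = x$objective,
    n_obs = nrow(x$curve),
    n_starts = nrow(x$starts),
    best_start = x$best_start,
    seed = x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
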