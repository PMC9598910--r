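test_that("plane-stress closed form: reference, matrix-only, tensor cross-check", {
  mat <- s1_material()
  expect_equal(unlist(equibiaxial_stress(1, 1, mat)),
               c(sigma_LL = 0, sigma_CC = 0))

  # matrix-only limit: incompressible neo-Hookean plane stress
  m_nh <- material_params(mu0 = 1e-4, k1_mus = 1e-30, k2_mus = 1,
                          k1_sm = 1e-30, k2_sm = 1)
  s <- equibiaxial_stress(1.2, 1.2, m_nh)
  expect_equal(s$sigma_LL, 1e-4 * (1.2^2 - 1 / 1.2^4), tolerance = 1e-9)

  # closed form equals the full tensor engine with the solved pressure
  fs <- fiber_set(30)
  for (lam in list(c(1.25, 1.25), c(1.35, 1.1), c(1.05, 1.3))) {
    cf <- equibiaxial_stress(lam[1], lam[2], mat)
    d <- deformation(diag(c(lam, 1 / prod(lam))), fs)
    dev <- cauchy_stress(d, mat, pressure = 0)
    full <- cauchy_stress(d, mat, pressure = -dev$sigma[3, 3])
    expect_equal(cf$sigma_LL, full$sigma[1, 1], tolerance = 1e-12)
    expect_equal(cf$sigma_CC, full$sigma[2, 2], tolerance = 1e-12)
    expect_equal(full$sigma[3, 3], 0, tolerance = 1e-15)
  }
})

test_that("run_path: no damage below thresholds, kink at onset, unloading branch", {
  mat <- s1_material()
  dmg <- s1_damage()

  # below every threshold the damage-coupled model is the elastic model
  path_low <- load_path(1.05, steps = 40)
  out_low <- run_path(path_low, mat, dmg)
  out_el <- run_path(path_low, mat, NULL)
  expect_equal(out_low$sigma_LL, out_el$sigma_LL)
  expect_true(all(out_low[c("D_lm", "D_cm", "D_sm")] == 0))

  # sigma_LL departs from the elastic curve where the first of its two
  # load-bearing layers (lm fiber or submucosal pair) crosses its threshold,
  # and the longitudinal threshold crossing steepens the departure
  path <- load_path(1.4, steps = 4000)
  out <- run_path(path, mat, dmg)
  el <- run_path(path, mat, NULL)
  i_first <- min(which(out$tau_lm > dmg$tau0[["lm"]])[1],
                 which(out$tau_sm > dmg$tau0[["sm"]])[1])
  i_lm <- which(out$tau_lm > dmg$tau0[["lm"]])[1]
  expect_equal(out$sigma_LL[seq_len(i_first - 1)],
               el$sigma_LL[seq_len(i_first - 1)])  # identical before onset
  expect_true(all(out$sigma_LL[(i_first + 5):nrow(out)] <
                    el$sigma_LL[(i_first + 5):nrow(out)]))
  expect_gt(i_lm, i_first)  # S1: submucosal onset precedes longitudinal

  # ramp then reverse: unloading lies below loading wherever D > 0 and is
  # the (1 - D)-scaled elastic response at the frozen final damage
  up <- load_path(1.3, steps = 100)
  down <- up[rev(seq_len(nrow(up))), ]
  cycle <- rbind(up, down[-1, ])
  out_c <- run_path(cycle, mat, dmg)
  n_up <- nrow(up)
  D_final <- unlist(out_c[n_up, c("D_lm", "D_cm", "D_sm")])
  names(D_final) <- c("lm", "cm", "sm")
  expect_gt(max(D_final), 0)
  reload <- out_c[(n_up + 1):nrow(out_c), ]
  frozen <- equibiaxial_stress(reload$lambda_L, reload$lambda_C, mat,
                               damage = D_final)
  expect_equal(reload$sigma_LL, frozen$sigma_LL, tolerance = 1e-12)
  # row j of the unloading branch revisits loading row n_up - j
  load_match <- out_c$sigma_LL[n_up - seq_len(nrow(reload))]
  mask <- reload$lambda_L > 1.01
  expect_true(all(reload$sigma_LL[mask] <= load_match[mask] + 1e-12))
})

test_that("path-step refinement changes final stresses by < 0.1%", {
  mat <- s1_material()
  dmg <- s1_damage()
  out_fine <- run_path(load_path(1.35, steps = 400), mat, dmg)
  out_coarse <- run_path(load_path(1.35, steps = 200), mat, dmg)
  expect_equal(out_coarse$sigma_LL[nrow(out_coarse)],
               out_fine$sigma_LL[nrow(out_fine)], tolerance = 1e-3)
  expect_equal(out_coarse$sigma_CC[nrow(out_coarse)],
               out_fine$sigma_CC[nrow(out_fine)], tolerance = 1e-3)
})

test_that("equal-direction symmetry at alpha = 45 under equibiaxial stretch", {
  mat <- s1_material()
  mat$alpha_deg <- 45
  # per-direction symmetry requires equal muscular damage parameters too
  dmg <- damage_params(0.05, 0.004, 0.05, 0.004, 0.0624, 0.0125)
  out <- run_path(load_path(1.3, steps = 50), mat, dmg)
  expect_gt(max(out$D_lm), 0)  # damage active, not a trivial elastic check
  expect_equal(out$sigma_LL, out$sigma_CC, tolerance = 1e-12)
})

test_that("brick: reference state, incompressible kinematics, penalty limit", {
  mat <- s1_material()
  dmg <- s1_damage()

  br0 <- simulate_brick(0, 0, mat, dmg, mode = "incompressible", steps = 2)
  expect_equal(br0$DZ, rep(0, 3))
  expect_equal(br0$sigma_xx, rep(0, 3), tolerance = 1e-14)

  # J = 1 forces DZ = 1/(1.31 * 1.38) - 1
  br <- simulate_brick(0.31, 0.38, mat, dmg, mode = "incompressible",
                       steps = 20)
  expect_equal(br$DZ[nrow(br)], 1 / (1.31 * 1.38) - 1, tolerance = 1e-10)
  expect_equal(br$J, rep(1, nrow(br)), tolerance = 1e-12)
  expect_equal(br$sigma_zz, rep(0, nrow(br)), tolerance = 1e-12)

  # penalty-mode DZ approaches the incompressible value monotonically in kappa0
  dz <- vapply(c(10, 100, 1000, 1e4), function(k) {
    b <- simulate_brick(0.31, 0.38, mat, dmg, mode = "penalty", kappa0 = k,
                        steps = 10)
    expect_lt(max(abs(b$sigma_zz)), 1e-9)  # plane-stress residual
    b$DZ[nrow(b)]
  }, numeric(1))
  dz_inc <- 1 / (1.31 * 1.38) - 1
  err <- abs(dz - dz_inc)
  expect_true(all(diff(err) < 0))            # monotone convergence
  expect_gt(min(dz - dz_inc), 0)             # penalty J >= 1 so DZ above limit
  expect_lt(err[4], 1e-4)
})
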