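test_that("stretch grid follows the displacement-controlled protocol", {
  curve <- generate_curve(s1_material(), NULL,
                          noise_free_protocol(max_stretch = 1.1),
                          noise = FALSE)
  # 10 mm/min on a 40 mm edge at 1 Hz: stretch increment 1/240 per frame
  expect_equal(unique(round(diff(curve$lambda_L), 12)), 1 / 240)
  expect_equal(curve$lambda_L[1], 1)
  expect_equal(curve$time_s, seq(0, by = 1, length.out = nrow(curve)))
  expect_equal(curve$lambda_C, curve$lambda_L)
})

test_that("force, stress and strain channels are mutually consistent", {
  curve <- generate_curve(s1_material(), s1_damage(), rig_protocol(),
                          seed = 42)
  geom <- attr(curve, "geometry")
  expect_equal(membrane_true_stress(curve$P_L_N, curve$lambda_L,
                                    geom$L, geom$T),
               curve$sigma_LL_MPa)
  expect_equal(membrane_force(curve$sigma_CC_MPa, curve$lambda_C,
                              geom$L, geom$T),
               curve$P_C_N)
  expect_equal(stretch_from_green_lagrange(curve$E_LL), curve$lambda_L)
})

test_that("noise-free curves are J-shaped before the first threshold crossing", {
  for (sp in c("S1", "S2", "S3", "S4")) {
    row <- specimen_parameters(sp)
    curve <- generate_curve(as_material_params(row), as_damage_params(row),
                            noise_free_protocol(), noise = FALSE)
    truth <- attr(curve, "truth")
    pre <- truth$tau_lm <= truth$tau_lm[1] |
      (truth$D_lm + truth$D_cm + truth$D_sm) == 0
    sig <- curve$sigma_LL_MPa[pre]
    expect_true(all(diff(sig) > 0))
    expect_true(all(diff(diff(sig)) > -1e-12))  # convex rise (J shape)
  }
})

test_that("anisotropy: longitudinal stiffer than circumferential up to longitudinal failure", {
  # sigma_LL > sigma_CC from the toe until the longitudinal muscular layer
  # crosses its threshold; past that the brittle lm collapse can drop the
  # longitudinal branch below the circumferential one
  for (sp in c("S1", "S2", "S3", "S4")) {
    row <- specimen_parameters(sp)
    dmg <- as_damage_params(row)
    curve <- generate_curve(as_material_params(row), dmg,
                            noise_free_protocol(), noise = FALSE)
    truth <- attr(curve, "truth")
    i_lm <- which(truth$tau_lm > dmg$tau0[["lm"]])[1]
    expect_false(is.na(i_lm))  # lm threshold is reached in every record
    keep <- which(curve$lambda_L > 1.05)
    keep <- keep[keep <= i_lm]
    expect_gt(length(keep), 5)
    expect_true(all(curve$sigma_LL_MPa[keep] > curve$sigma_CC_MPa[keep]))
  }
})

test_that("S1 layer failure ordering: circumferential first, then submucosal, then longitudinal", {
  row <- specimen_parameters("S1")
  curve <- generate_curve(as_material_params(row), as_damage_params(row),
                          noise_free_protocol(), noise = FALSE)
  truth <- attr(curve, "truth")
  dmg <- as_damage_params(row)
  cross <- vapply(c("cm", "sm", "lm"), function(k) {
    i <- which(truth[[paste0("tau_", k)]] > dmg$tau0[[k]])[1]
    truth$lambda_L[i]
  }, numeric(1))
  expect_true(cross[["cm"]] < cross[["sm"]])
  expect_true(cross[["sm"]] < cross[["lm"]])
})

test_that("rupture truncation respects the damage cap", {
  prot <- noise_free_protocol(damage_cap = 0.9)
  curve <- generate_curve(s1_material(), s1_damage(), prot, noise = FALSE)
  truth <- attr(curve, "truth")
  expect_true(all(pmax(truth$D_lm, truth$D_cm, truth$D_sm) <= 0.9))
  expect_lt(max(curve$lambda_L), prot$max_stretch)
})

test_that("cohorts are seeded and bitwise reproducible", {
  tbl <- specimen_parameters(c("S1", "S3"))
  c1 <- generate_cohort(tbl, rig_protocol(), n_replicates = 2, seed = 9)
  c2 <- generate_cohort(tbl, rig_protocol(), n_replicates = 2, seed = 9)
  expect_identical(c1$curves, c2$curves)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(nrow(c1$manifest), 4)
  expect_named(c1$curves, c("S1_r1", "S1_r2", "S3_r1", "S3_r2"))
  c3 <- generate_cohort(tbl, rig_protocol(), n_replicates = 2, seed = 10)
  expect_false(identical(c1$curves, c3$curves))
})

test_that("thickness sampling reproduces the reported range and mean", {
  prot <- rig_protocol(thickness_range = c(0.68, 2.15), max_stretch = 1.02,
                       noise_rel = 0)
  thick <- vapply(1:300, function(i) {
    attr(generate_curve(s1_material(), NULL, prot, seed = i), "geometry")$T
  }, numeric(1))
  expect_true(all(thick >= 0.68 & thick <= 2.15))
  expect_equal(mean(thick), (0.68 + 2.15) / 2, tolerance = 0.03)
  # fixed mode uses the printed mean thickness
  fixed <- attr(generate_curve(s1_material(), NULL,
                               rig_protocol(max_stretch = 1.02), seed = 1),
                "geometry")$T
  expect_equal(fixed, 1.188)
})
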