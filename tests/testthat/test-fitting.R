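test_that("r_squared matches hand arithmetic and guards degenerate input", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "Constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("prediction is a path-state property, independent of grid refinement", {
  mat <- s1_material()
  dmg <- s1_damage()
  lam_fine <- seq(1, 1.35, length.out = 201)
  lam_coarse <- lam_fine[seq(1, 201, by = 4)]
  p_fine <- predict_biaxial(mat, dmg, lam_fine, lam_fine)
  p_coarse <- predict_biaxial(mat, dmg, lam_coarse, lam_coarse)
  expect_equal(p_fine$sigma_LL[seq(1, 201, by = 4)], p_coarse$sigma_LL)
  expect_equal(p_fine$sigma_CC[seq(1, 201, by = 4)], p_coarse$sigma_CC)
  # and reproduces the generator's noise-free output exactly
  curve <- generate_curve(mat, dmg, noise_free_protocol(), noise = FALSE)
  pred <- predict_biaxial(mat, dmg, curve$lambda_L, curve$lambda_C)
  expect_equal(pred$sigma_LL, curve$sigma_LL_MPa)
})

test_that("quality control detects non-J-shaped records and softening", {
  curve <- generate_curve(s1_material(), s1_damage(), noise_free_protocol(),
                          noise = FALSE)
  expect_true(qc_biaxial(curve))
  bad <- curve
  n <- nrow(bad)
  bad$sigma_LL_MPa[seq_len(floor(0.5 * n))] <-
    rev(bad$sigma_LL_MPa[seq_len(floor(0.5 * n))])
  expect_error(qc_biaxial(bad), "J-shaped")
  # concurrent-softening selection rule: the noise-free S1 record ends at
  # rupture while sigma_CC still rises, so it fails the experimental rule
  cfg_soft <- fit_config(require_softening = TRUE)
  expect_error(qc_biaxial(curve, cfg_soft), "softening")
})

test_that("hyperelastic-only recovery when damage never activates", {
  mat <- s1_material()
  curve <- generate_curve(mat, NULL, noise_free_protocol(max_stretch = 1.25),
                          noise = FALSE)
  fit <- fit_biaxial(curve, fit_config(n_starts = 6, seed = 3))
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "k1_mus"], mat$k1_mus,
               tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "k2_mus"], mat$k2_mus,
               tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "k1_sm"], mat$k1_sm,
               tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "k2_sm"], mat$k2_sm,
               tolerance = 1e-6)
  # the fitted model predicts an undamaged record
  pred_D <- run_path(tibble::tibble(lambda_L = curve$lambda_L,
                                    lambda_C = curve$lambda_C),
                     fit$material, fit$damage)
  expect_lt(max(pred_D$D_lm, pred_D$D_cm, pred_D$D_sm), 1e-6)
  expect_gt(fit$r2_L, 0.99999)
})

test_that("fit is deterministic given the seed and beats the truth objective no worse than tolerance", {
  row <- specimen_parameters("S1")
  mat <- as_material_params(row)
  dmg <- as_damage_params(row)
  curve <- generate_curve(mat, dmg, noise_free_protocol(), noise = FALSE)
  cfg <- fit_config(n_starts = 6, seed = 11)
  f1 <- fit_biaxial(curve, cfg)
  f2 <- fit_biaxial(curve, cfg)
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)
  expect_identical(f1$objective, f2$objective)
  # on noise-free data the generating parameters are a global optimum:
  # the fit objective cannot exceed the (zero) objective at truth by more
  # than solver tolerance
  pred_truth <- predict_biaxial(mat, dmg, curve$lambda_L, curve$lambda_C)
  obj_truth <- sum((pred_truth$sigma_LL - curve$sigma_LL_MPa)^2) +
    sum((pred_truth$sigma_CC - curve$sigma_CC_MPa)^2)
  expect_equal(obj_truth, 0)
  expect_lt(f1$residual_norm, 1e-8)
})

test_that("fit result object: tidy, glance, feasibility, plotting", {
  curve <- generate_curve(s1_material(), s1_damage(), noise_free_protocol(),
                          noise = FALSE)
  fit <- fit_biaxial(curve, fit_config(n_starts = 4, seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 11)
  expect_true(td$fixed[td$term == "mu0"])
  gl <- glance(fit)
  expect_lte(gl$r2_L, 1)
  expect_lte(gl$r2_C, 1)
  expect_gt(gl$r2_L, 0.9999)
  # feasibility enforced by construction
  d <- fit$damage
  expect_true(all(d$gf > d$tau0^2 / 2))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_error(fit_biaxial(curve[, c("lambda_L", "lambda_C")]), "missing")
})
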