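# Kinetic coefficient estimation, condition comparison and the critical
# extrapolation.

test_that("exact rates invert to the generating coefficients", {
  pts <- exact_rate_points()
  fit <- fit_kinetics(pts, n_boot = 0)
  expect_equal(fit$regressions$w[["intercept"]], 0.1, tolerance = 1e-9)
  expect_equal(fit$regressions$w[["slope"]], -1.9529e-8 / 1.54e-7,
               tolerance = 1e-6)
  expect_equal(fit$regressions$a[["slope"]], -2.43e-7 / 2.34e-7,
               tolerance = 1e-6)
  truth <- unlist(kinetic_params())
  est <- vapply(names(truth), function(k) fit$params[[k]], numeric(1))
  expect_equal(unname(est), unname(truth), tolerance = 1e-6)
  # zero residuals inside the window on exact data
  expect_equal(unname(fit$r2), c(1, 1), tolerance = 1e-12)
})

test_that("the fit is exactly invariant to a common rescaling of amounts", {
  pts <- exact_rate_points()
  f1 <- fit_kinetics(pts, n_boot = 0)
  sc <- data.table::copy(pts)
  lam <- 37.5
  sc[, c("a_iu", "w_iu", "dw", "da") :=
       .(a_iu * lam, w_iu * lam, dw * lam, da * lam)]
  f2 <- fit_kinetics(sc, n_boot = 0)
  for (k in c("k_r", "k_l", "k_b", "k_d")) {
    expect_equal(f1$params[[k]], f2$params[[k]], tolerance = 1e-12)
  }
})

test_that("noise-free tracks recover coefficients to finite-difference accuracy", {
  fit <- fit_kinetics(noise_free_points(), n_boot = 0)
  truth <- unlist(kinetic_params())
  est <- vapply(names(truth), function(k) fit$params[[k]], numeric(1))
  expect_lt(max(abs(est - truth) / truth), 1e-3)
  expect_gt(min(fit$r2), 1 - 1e-4)
})

test_that("the noisy reference ensemble is recovered within ten percent", {
  fit <- memo("big_noisy_fit",
              fit_kinetics(big_noisy_points(), n_boot = 100))
  truth <- unlist(kinetic_params())
  est <- vapply(names(truth), function(k) fit$params[[k]], numeric(1))
  expect_lt(max(abs(est - truth) / truth), 0.1)
  expect_true(all(fit$se > 0))
  # self-consistency: nullclines from the fitted coefficients agree with
  # the empirical nullclines extracted from the same ensemble
  nc_fit <- nullcline_stoichiometries(as_kinetic_params(fit$params))
  ncw <- extract_nullcline(big_noisy_field(), "W", n_boot = 0)
  nca <- extract_nullcline(big_noisy_field(), "A", n_boot = 0)
  expect_lt(abs(nc_fit["s_W"] - ncw$stoichiometry), 0.02)
  expect_lt(abs(nc_fit["s_A"] - nca$stoichiometry), 0.02)
})

test_that("condition comparisons report folds, regimes and the critical point", {
  fit <- memo("big_noisy_fit",
              fit_kinetics(big_noisy_points(), n_boot = 100))
  # identical fits: all folds are one
  same <- compare_conditions(fit, fit)
  expect_equal(same$table$fold, rep(1, 4))
  expect_false(same$perturbed_kd_exceeds_critical)
  # exact-rate fits of the mild preset: folds equal the preset factors
  ctrl <- fit_kinetics(exact_rate_points(), n_boot = 0)
  mild <- fit_kinetics(exact_rate_points(rnai_preset("mild")), n_boot = 0)
  cmp <- compare_conditions(ctrl, mild)
  expect_equal(cmp$table[coefficient == "k_d", fold], 1.7, tolerance = 1e-5)
  expect_equal(cmp$table[coefficient == "k_r", fold], 0.83, tolerance = 1e-5)
  # mild stays bounded under its own coefficients (its k_l increase lowers
  # the criterion), but its k_d exceeds the control geometry's critical rate
  expect_identical(unname(cmp$regimes), c("bounded", "bounded"))
  expect_true(cmp$perturbed_kd_exceeds_critical) # 0.255 > 0.2196
})

test_that("perturbed portraits switch nullclines beyond the critical point", {
  ctrl <- kinetic_params()
  kds <- critical_kd()
  sw <- predict_perturbed_portrait(ctrl, 1.2 * kds)
  expect_true(sw$switched)
  expect_identical(sw$regime, "unbounded")
  id <- predict_perturbed_portrait(ctrl, ctrl$k_d)
  expect_false(id$switched)
  expect_equal(id$nullclines, id$control_nullclines)
  cr <- predict_perturbed_portrait(ctrl, kds)
  expect_true(cr$coincident)
  expect_equal(unname(cr$nullclines["s_W"]), unname(cr$nullclines["s_A"]),
               tolerance = 1e-6)
})

test_that("the severity extrapolation bounds k_d for the strong condition", {
  lb <- estimate_kd_lower_bound(c(0.15, 0.255, 0.405, NA),
                                c(2000, 120, 70, 0))
  expect_equal(lb$kd_lower_bound, 0.525, tolerance = 1e-9)
  expect_gt(lb$kd_lower_bound, 0.405)
  expect_gt(lb$kd_lower_bound, critical_kd()) # consistent with unbounded
  expect_error(estimate_kd_lower_bound(c(0.15, NA), c(100, 0)),
               "insufficient trend")
  expect_warning(estimate_kd_lower_bound(c(0.3, 0.2, 0.4, NA),
                                         c(900, 500, 70, 0)),
                 "monotone")
})
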