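# The growth-law dynamical system: rate evaluation, nullcline geometry,
# critical point, orbits and intensive composition dynamics.

test_that("growth rates match hand-evaluated values and axis limits", {
  # axes: pure exponential WSP-1 growth / pure F-actin decay
  expect_equal(growth_rates(0, 50), data.frame(dW = 5, dA = 0))
  expect_equal(growth_rates(100, 0), data.frame(dW = 0, dA = -15))
  # interior state, hand arithmetic: V = 2.71e-5 um^3, AW/V = 1.845e8
  r <- growth_rates(100, 50)
  V <- 1.54e-7 * 100 + 2.34e-7 * 50
  expect_equal(V, 2.71e-5)
  expect_equal(r$dW, 0.1 * 50 - 1.9529e-8 * 5000 / V, tolerance = 1e-12)
  expect_equal(r$dA, 2.43e-7 * 5000 / V - 0.15 * 100, tolerance = 1e-12)
  expect_equal(r$dW, 1.397, tolerance = 1e-3)
  expect_equal(r$dA, 29.83, tolerance = 1e-3)
  # fixed point and domain errors
  expect_equal(growth_rates(0, 0), data.frame(dW = 0, dA = 0))
  expect_error(growth_rates(-1, 5), "nonnegative")
  expect_error(kinetic_params(k_r = 0), "positive")
})

test_that("the vector field is degree-1 homogeneous", {
  set.seed(1)
  states <- matrix(runif(40, 0.01, 500), ncol = 2)
  for (lam in c(1e-3, 0.7, 1, 1e4)) {
    r1 <- growth_rates(states[, 1], states[, 2])
    r2 <- growth_rates(lam * states[, 1], lam * states[, 2])
    expect_equal(r2$dW, lam * r1$dW, tolerance = 1e-12)
    expect_equal(r2$dA, lam * r1$dA, tolerance = 1e-12)
  }
})

test_that("nullcline stoichiometries match formulas, numeric search and reported values", {
  nc <- nullcline_stoichiometries()
  expect_equal(unname(nc["s_W"]), 0.85, tolerance = 1e-3)
  expect_equal(unname(nc["s_A"]), 0.90, tolerance = 1e-12)
  # independent oracle: sign change of the rates along rays of fixed
  # stoichiometry (state (A, W) = (s, 1 - s))
  s_W_num <- uniroot(function(s) growth_rates(s, 1 - s)$dW,
                     c(0.5, 0.999), tol = 1e-12)$root
  s_A_num <- uniroot(function(s) growth_rates(s, 1 - s)$dA,
                     c(0.5, 0.999), tol = 1e-12)$root
  expect_equal(unname(nc["s_W"]), s_W_num, tolerance = 1e-6)
  expect_equal(unname(nc["s_A"]), s_A_num, tolerance = 1e-6)
  # degenerate geometries collapse onto the axes
  p <- kinetic_params()
  v <- volume_coefficients()
  degW <- kinetic_params(k_r = p$k_l / v$v_A) # k_l = k_r v_A
  expect_equal(unname(nullcline_stoichiometries(degW)["s_W"]), 1)
  degA <- kinetic_params(k_d = p$k_b / v$v_W) # k_b = k_d v_W
  expect_equal(unname(nullcline_stoichiometries(degA)["s_A"]), 0)
})

test_that("critical k_d matches the closed form and a bisection oracle", {
  kds <- critical_kd()
  expect_equal(kds, 0.2196, tolerance = 1e-3)
  # oracle: bisection on k_d for coincidence of the two nullcline rays
  f <- function(kd) {
    nc <- nullcline_stoichiometries(kinetic_params(k_d = kd))
    nc["s_W"] - nc["s_A"]
  }
  kds_num <- uniroot(f, c(0.16, 0.4), tol = 1e-12)$root
  expect_equal(kds, kds_num, tolerance = 1e-9)
  # limit: v_A k_r / k_l = 1 makes the critical rate vanish
  v <- volume_coefficients()
  expect_equal(critical_kd(kinetic_params(k_r = 0.1, k_l = 0.1 * v$v_A * (1 + 1e-12))),
               0, tolerance = 1e-9)
  expect_error(critical_kd(kinetic_params(k_l = 1e-9)), "degenerate")
})

test_that("regime classification follows the criterion value", {
  expect_equal(regime_criterion(), 0.933, tolerance = 1e-3)
  expect_identical(classify_regime(), "bounded")
  p27 <- kinetic_params(k_d = 0.405)
  expect_equal(regime_criterion(p27), 1.179, tolerance = 1e-3)
  expect_identical(classify_regime(p27), "unbounded")
  expect_identical(classify_regime(kinetic_params(k_d = critical_kd())),
                   "critical")
})

test_that("orbits are homoclinic in the bounded regime and exact on the A axis", {
  orb <- integrate_orbit(A0 = 1, W0 = 5, duration = 60, step = 0.1)
  # stoichiometry converges monotonically towards the dominant value
  expect_true(all(diff(orb$s) > -1e-9))
  # W rises then falls below its start
  expect_gt(max(orb$W), 5)
  expect_lt(orb$W[nrow(orb)], 5)
  expect_equal(orb$s[nrow(orb)], fixed_point_phi()$s, tolerance = 2e-3)
  # invariant A axis: closed-form exponential decay
  axis <- integrate_orbit(A0 = 10, W0 = 0, duration = 20, step = 0.5)
  expect_equal(axis$A, 10 * exp(-0.15 * axis$time), tolerance = 1e-7)
  expect_equal(axis$W, rep(0, nrow(axis)))
  expect_error(integrate_orbit(A0 = 0, W0 = 0, duration = 1), "initial")
})

test_that("composition dynamics are intensive along orbits", {
  base <- integrate_orbit(A0 = 1, W0 = 2, duration = 40, step = 0.2)
  for (lam in c(0.01, 100)) {
    sc <- integrate_orbit(A0 = lam * 1, W0 = lam * 2, duration = 40, step = 0.2)
    expect_lt(max(abs(sc$phi - base$phi)), 1e-6)
    expect_lt(max(abs(sc$s - base$s)), 1e-6)
  }
})

test_that("phi dynamics vanish on the boundary and have the predicted interior root", {
  expect_equal(phi_dynamics(c(0, 1)), c(0, 0))
  expect_equal(phi_dynamics(0.5), 0.5 * 0.5 * 0.33264, tolerance = 1e-3)
  expect_gt(phi_dynamics(0.5), 0)
  expect_error(phi_dynamics(1.2), "phi")
  # interior zero of the bracket: root-finder oracle vs closed form
  root <- uniroot(function(p) phi_dynamics(p), c(0.5, 0.99), tol = 1e-12)$root
  fp <- fixed_point_phi()
  expect_equal(fp$phi, root, tolerance = 1e-9)
  expect_equal(fp$phi, 0.8649, tolerance = 1e-4)
  expect_equal(fp$s, 0.9068, tolerance = 1e-4)
  # stability: dphi/dt positive below the root, negative above
  expect_gt(phi_dynamics(fp$phi - 0.05), 0)
  expect_lt(phi_dynamics(fp$phi + 0.05), 0)
  # dominant stoichiometry sits above the F-actin nullcline when bounded
  expect_gt(fp$s, nullcline_stoichiometries()["s_A"])
  # k_r, k_l -> 0 limit: root at 1 - k_d v_W / k_b
  p0 <- kinetic_params(k_r = 1e-9, k_l = 1e-12)
  v <- volume_coefficients()
  expect_equal(fixed_point_phi(p0)$phi, 1 - 0.15 * v$v_W / p0$k_b,
               tolerance = 1e-4)
})

test_that("phi dynamics agree with finite differences of an integrated orbit", {
  orb <- integrate_orbit(A0 = 1, W0 = 5, duration = 30, step = 0.01)
  mid <- seq(500, 2500, by = 250)
  fd <- (orb$phi[mid + 1] - orb$phi[mid - 1]) / 0.02
  expect_equal(fd, phi_dynamics(orb$phi[mid]), tolerance = 1e-4)
})

test_that("observables satisfy the density-line identity and phi/s conversions", {
  ob <- observables(100, 50)
  expect_equal(ob$s, 2 / 3, tolerance = 1e-12)
  expect_equal(ob$phi, 0.5683, tolerance = 1e-4)
  v <- volume_coefficients()
  expect_equal(v$v_A * ob$c_A + v$v_W * ob$c_W, 1, tolerance = 1e-14)
  # reported transition composition: s = 0.86 maps to phi ~ 0.8
  expect_equal(stoich_to_phi(0.86), 0.80, tolerance = 5e-3)
  expect_equal(phi_to_stoich(stoich_to_phi(0.37)), 0.37, tolerance = 1e-12)
  # symmetric coefficients: phi = s
  expect_equal(stoich_to_phi(0.5, volume_coefficients(1e-7, 1e-7)), 0.5)
  expect_error(observables(0, 0), "fixed point")
})

test_that("predicted flux field vanishes on the nullcline rays", {
  nc <- nullcline_stoichiometries()
  amounts <- c(1, 10, 100, 1000)
  fW <- growth_rates(amounts * nc["s_W"], amounts * (1 - nc["s_W"]))
  expect_lt(max(abs(fW$dW)), 1e-10)
  fA <- growth_rates(amounts * nc["s_A"], amounts * (1 - nc["s_A"]))
  expect_lt(max(abs(fA$dA)), 1e-12)
  # grid evaluation consistent with growth_rates
  fld <- predict_flux_field(A_nodes = c(50, 100), W_nodes = c(25, 50))
  row <- fld[fld$A == 100 & fld$W == 50, ]
  expect_equal(row$dW, growth_rates(100, 50)$dW)
  expect_equal(row$dA, growth_rates(100, 50)$dA)
})

test_that("between the nullclines WSP-1 is lost while F-actin still grows", {
  nc <- nullcline_stoichiometries()
  s_mid <- seq(nc["s_W"] + 1e-3, nc["s_A"] - 1e-3, length.out = 25)
  for (m in c(2, 40, 800)) {
    r <- growth_rates(m * s_mid, m * (1 - s_mid))
    expect_true(all(r$dW < 0))
    expect_true(all(r$dA > 0))
  }
})

test_that("regime classification agrees with long-horizon integration", {
  kds <- critical_kd()
  # bounded at 0.9 k_d*: total amount below its running maximum and decaying
  pb <- kinetic_params(k_d = 0.9 * kds)
  expect_identical(classify_regime(pb), "bounded")
  ob <- integrate_orbit(pb, volume_coefficients(), A0 = 1, W0 = 5,
                        duration = 500, step = 0.5)
  totb <- ob$A + ob$W
  expect_lt(totb[length(totb)], max(totb))
  expect_lt(totb[length(totb)], totb[length(totb) - 40])
  # unbounded at 1.1 k_d*: F-actin strictly increasing over the final 100 s
  pu <- kinetic_params(k_d = 1.1 * kds)
  expect_identical(classify_regime(pu), "unbounded")
  ou <- integrate_orbit(pu, volume_coefficients(), A0 = 1, W0 = 5,
                        duration = 500, step = 0.5)
  lastA <- ou$A[ou$time >= 400]
  expect_true(all(diff(lastA) > 0))
})
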