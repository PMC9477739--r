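# Mass-balance imaging: derivative estimation, binned fields, empirical
# nullclines, stoichiometry curves, occupancy contours and the (phi, V)
# representation.

make_track <- function(t, w, a, id = "c1") {
  data.table(condition = "c", oocyte_id = "o", condensate_id = id,
             t = t, w_iu = w, a_iu = a, area_um2 = NA_real_)
}

test_that("central differences are exact for linear and quadratic signals", {
  t <- seq(0, 10, by = 0.5)
  lin <- make_track(t, 2 * t + 1, 5 + 0 * t)
  d <- estimate_derivatives(lin)
  expect_equal(d$dw, rep(2, nrow(d)))
  expect_equal(d$da, rep(0, nrow(d)))
  quad <- make_track(t, 1 + 0 * t, t^2 + 1)
  dq <- estimate_derivatives(quad)
  expect_equal(dq$da, 2 * dq$t) # no bias for quadratics
  # the smoothed (local quadratic) variant is exact for quadratics too
  dq5 <- estimate_derivatives(quad, smooth = TRUE)
  expect_equal(dq5$da, 2 * dq5$t, tolerance = 1e-12)
  # endpoints are dropped
  expect_equal(nrow(d), length(t) - 2)
})

test_that("irregular spacing and short tracks are rejected", {
  bad <- make_track(c(0, 0.5, 1.2, 1.5), 1:4, 1:4)
  expect_error(estimate_derivatives(bad), "irregular")
  expect_error(estimate_derivatives(make_track(c(0, 0.5), 1:2, 1:2)),
               "at least 3")
})

test_that("derivatives on a deterministic orbit converge at second order", {
  errs <- sapply(c(0.25, 0.5, 1.0), function(dt_frame) {
    orb <- integrate_orbit(A0 = 0.5, W0 = 4, duration = 30, step = dt_frame)
    tr <- make_track(orb$time, orb$W, orb$A)
    d <- estimate_derivatives(tr)
    truth <- growth_rates(d$a_iu, d$w_iu)
    # error relative to the scale of each rate component (pointwise
    # relative error is ill-defined where a rate crosses zero)
    max(max(abs(d$da - truth$dA)) / max(abs(truth$dA)),
        max(abs(d$dw - truth$dW)) / max(abs(truth$dW)))
  })
  expect_true(all(diff(errs) > 0))          # error grows with step
  expect_gt(errs[3] / errs[1], 8)           # ~16x expected for 2nd order
  expect_lt(errs[2], 0.01)                  # < 1% at the 0.5 s default
})

test_that("binned fields are permutation-invariant and average point rates", {
  one <- data.table(condition = "c", oocyte_id = "o", condensate_id = "c1",
                    t = 0, a_iu = rep(20, 100), w_iu = rep(10, 100),
                    dw = rnorm(100), da = rnorm(100))
  f1 <- bin_vector_field(one, n_bins = 5, min_count = 10)
  occ <- f1$bins[count > 0]
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$mean_dw, mean(one$dw))
  expect_equal(occ$mean_da, mean(one$da))
  expect_equal(sum(f1$bins$count), 100)
  pts <- big_noisy_points()
  fa <- bin_vector_field(pts)
  set.seed(9)
  fb <- bin_vector_field(pts[sample(nrow(pts))])
  expect_equal(fa$bins, fb$bins)
})

test_that("the binned field reproduces the three dynamic regimes", {
  field <- big_noisy_field()
  nc <- nullcline_stoichiometries()
  bins <- field$bins[masked == FALSE]
  s_bin <- bins$a_mid / (bins$a_mid + bins$w_mid)
  # growth regime: above the WSP-1 nullcline ray WSP-1 is gained
  growth <- s_bin < nc["s_W"] - 0.03
  expect_gt(mean(bins$mean_dw[growth] > 0), 0.9)
  # transition regime: WSP-1 lost while F-actin still grows. Individual
  # bins near the F-actin nullcline are resolution- and noise-limited, so
  # the dW sign is checked per bin and the dA sign on the pooled points.
  trans <- s_bin > nc["s_W"] + 0.01 & s_bin < nc["s_A"] - 0.02
  expect_gt(mean(bins$mean_dw[trans] < 0), 0.7)
  pts <- big_noisy_points()
  s_pt <- pts$a_iu / (pts$a_iu + pts$w_iu)
  band <- s_pt > nc["s_W"] + 0.01 & s_pt < nc["s_A"] - 0.005
  expect_lt(mean(pts$dw[band]), 0)
  expect_gt(mean(pts$da[band]), 0)
})

test_that("nullclines extracted from the exact field match the analytic rays", {
  nodes <- 10^seq(0, 2.7, length.out = 240)
  fld <- predict_flux_field(A_nodes = nodes, W_nodes = nodes)
  pts <- data.table(condition = "c", oocyte_id = "o",
                    condensate_id = sprintf("g%06d", seq_len(nrow(fld))),
                    t = 0, a_iu = fld$A, w_iu = fld$W, dw = fld$dW, da = fld$dA)
  f <- bin_vector_field(pts, n_bins = 80, min_count = 1)
  ncw <- extract_nullcline(f, "W", n_boot = 0)
  nca <- extract_nullcline(f, "A", n_boot = 0)
  nc <- nullcline_stoichiometries()
  expect_equal(ncw$stoichiometry, unname(nc["s_W"]), tolerance = 1e-3)
  expect_equal(nca$stoichiometry, unname(nc["s_A"]), tolerance = 1e-3)
})

test_that("data on one side of a nullcline give a no-nullcline error", {
  # exact rates restricted to the growth regime: dW > 0 everywhere
  pts <- exact_rate_points(s_grid = seq(0.1, 0.8, by = 0.01))
  f <- bin_vector_field(pts, n_bins = 10, min_count = 1)
  expect_error(extract_nullcline(f, "W"), "no sign change")
})

test_that("growth-vs-stoichiometry curves cross zero in the right order", {
  g <- growth_vs_stoichiometry(big_noisy_points())
  expect_lt(g$zero_crossing["W"], g$zero_crossing["A"])
  expect_equal(unname(g$zero_crossing["W"]), 0.85, tolerance = 0.02)
  # noise-free ray-sampled data: bin means equal analytic rates at the
  # occupancy-weighted stoichiometry
  pts <- exact_rate_points(s_grid = seq(0.4, 0.95, by = 0.05), scales = 70)
  ge <- growth_vs_stoichiometry(pts, n_bins = 12, min_count = 1)
  cu <- ge$curves[count > 0]
  truth <- growth_rates(70 * cu$s_mean, 70 * (1 - cu$s_mean))
  expect_equal(cu$mean_dw, truth$dW, tolerance = 1e-10)
  expect_equal(cu$mean_da, truth$dA, tolerance = 1e-10)
  # unbounded preset: crossing order swaps (F-actin nullcline below WSP-1)
  pu <- exact_rate_points(rnai_preset("strong"),
                          s_grid = seq(0.6, 0.95, by = 0.002))
  gu <- growth_vs_stoichiometry(pu, n_bins = 30, min_count = 1)
  expect_lt(gu$zero_crossing["A"], gu$zero_crossing["W"])
})

test_that("occupancy contours are calibrated and nested", {
  set.seed(6)
  x <- rnorm(4000); y <- rnorm(4000)
  oc <- occupancy_contours(x, y)
  f68 <- oc$contours$level_0.68
  f25 <- oc$contours$level_0.25
  expect_lt(abs(f68$fraction_inside - 0.68), 0.02)
  expect_lt(abs(f25$fraction_inside - 0.25), 0.02)
  # the 25% highest-density region is strictly inside the 68% one
  expect_gt(f25$threshold, f68$threshold)
  expect_gt(length(f68$polygons), 0)
  expect_error(occupancy_contours(rep(1, 200), rep(1, 200)), "degenerate")
  expect_error(occupancy_contours(x[1:50], y[1:50]), "at least 100")
})

test_that("binned kernel density agrees with the direct estimator on small data", {
  skip_if_not_installed("MASS")
  set.seed(12)
  x <- rnorm(800, 3, 1); y <- rnorm(800, -1, 2)
  hb <- c(stats::bw.nrd0(x), stats::bw.nrd0(y))
  ours <- cortcond:::.binned_kde2d(x, y, n_grid = 96, hx = hb[1], hy = hb[2])
  ref <- MASS::kde2d(x, y, h = 4 * hb, n = 96,
                     lims = c(range(ours$x), range(ours$y)))
  expect_gt(cor(as.vector(ours$z), as.vector(ref$z)), 0.995)
  io <- arrayInd(which.max(ours$z), dim(ours$z))
  ir <- arrayInd(which.max(ref$z), dim(ref$z))
  expect_lt(abs(ours$x[io[1]] - ref$x[ir[1]]), 0.3)
  expect_lt(abs(ours$y[io[2]] - ref$y[ir[2]]), 0.6)
})

test_that("the preferred concentration pair returns a point mass unchanged", {
  pp <- preferred_concentration_pair(rep(2e6, 150), rep(5e5, 150), n_boot = 0)
  expect_equal(pp$c_a, 2e6)
  expect_equal(pp$c_w, 5e5)
})

test_that("the (phi, V) field finds the volume nullcline and the axis limit", {
  # exact-rate oracle for the volume nullcline: root of the dV/dt quadratic
  p <- kinetic_params(); v <- volume_coefficients()
  dVrel <- function(phi) {
    phi * (p$k_b * (1 - phi) / v$v_W - p$k_d) +
      (1 - phi) * (p$k_r - (p$k_l / v$v_A) * phi)
  }
  root <- uniroot(dVrel, c(0.5, 0.99), tol = 1e-12)$root
  expect_equal(root, 0.8542, tolerance = 1e-4)
  pv <- phi_V_field(noise_free_points(), n_bins = 30)
  expect_equal(pv$volume_nullcline$phi, root, tolerance = 0.02)
  # pure-WSP-1 limit: relative volume growth rate tends to k_r
  pts0 <- exact_rate_points(s_grid = seq(1e-4, 1e-3, by = 1e-4), scales = 100)
  Vl <- v$v_A * pts0$a_iu + v$v_W * pts0$w_iu
  dV <- v$v_A * pts0$da + v$v_W * pts0$dw
  expect_equal(mean(dV / Vl), p$k_r, tolerance = 0.01)
})

test_that("rate slices at constant amounts match the field they cut", {
  nodes <- 10^seq(0, 2.5, length.out = 50)
  fld <- predict_flux_field(A_nodes = nodes, W_nodes = nodes)
  pts <- data.table(condition = "c", oocyte_id = "o",
                    condensate_id = sprintf("g%05d", seq_len(nrow(fld))),
                    t = 0, a_iu = fld$A, w_iu = fld$W, dw = fld$dW, da = fld$dA)
  f <- bin_vector_field(pts, n_bins = 25, min_count = 1)
  sl <- conditional_rate_slices(f, "A", 30)
  truth <- growth_rates(sl$a_mid, sl$w_mid)
  expect_equal(sl$mean_dw, truth$dW, tolerance = 0.15)
  # dW/dt rises with W towards and beyond the nullcline crossing (at very
  # small W the loss term still dominates, so the rise starts above ~2 IU)
  below <- sl[sl$w_mid > 2.3, ]
  expect_gt(nrow(below), 10)
  expect_true(all(diff(below$mean_dw) > 0))
  expect_error(conditional_rate_slices(f, "A", 1e9), "outside")
})
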