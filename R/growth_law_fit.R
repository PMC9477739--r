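# Kinetic coefficient estimation. The growth laws imply that both relative
# rates are linear in the effective F-actin volume fraction phi:
#   dW/dt / W = k_r - (k_l / v_A) phi
#   dA/dt / A = (k_b / v_W) - k_d - (k_b / v_W) phi
# so two weighted least-squares regressions inside the phi validity window
# identify all four coefficients.

# weighted instrumental-variable regression sufficient statistics per
# condensate; the condensate-level bootstrap then just resamples and sums
# rows. With instrument z == regressor phi this reduces to ordinary WLS.
.wls_stats <- function(dt, ycol, wcol) {
  dt[, .(Sw = sum(get(wcol)),
         Sx = sum(get(wcol) * phi),
         Sz = sum(get(wcol) * z),
         Sxx = sum(get(wcol) * phi^2),
         Szx = sum(get(wcol) * z * phi),
         Sy = sum(get(wcol) * get(ycol)),
         Sxy = sum(get(wcol) * phi * get(ycol)),
         Szy = sum(get(wcol) * z * get(ycol)),
         Syy = sum(get(wcol) * get(ycol)^2)),
     by = condensate_id]
}

.wls_solve <- function(st) {
  Sw <- sum(st$Sw); Sx <- sum(st$Sx); Sz <- sum(st$Sz)
  Sxx <- sum(st$Sxx); Szx <- sum(st$Szx)
  Sy <- sum(st$Sy); Sxy <- sum(st$Sxy); Szy <- sum(st$Szy)
  Syy <- sum(st$Syy)
  den <- Szx - Sz * Sx / Sw
  if (abs(den) <= .Machine$double.eps * max(abs(Szx), 1)) {
    stop("degenerate phi design in kinetic fit", call. = FALSE)
  }
  slope <- (Szy - Sz * Sy / Sw) / den
  intercept <- (Sy - slope * Sx) / Sw
  sse <- Syy + intercept^2 * Sw + slope^2 * Sxx -
    2 * intercept * Sy - 2 * slope * Sxy + 2 * intercept * slope * Sx
  sst <- Syy - Sy^2 / Sw
  list(slope = slope, intercept = intercept,
       r2 = if (sst > 0) 1 - sse / sst else NA_real_)
}

.map_coefs <- function(fw, fa, vol) {
  c(k_r = fw$intercept,
    k_l = -fw$slope * vol$v_A,
    k_b = -fa$slope * vol$v_W,
    k_d = -fa$slope - fa$intercept)
}

#' Fit the four kinetic coefficients from rate points
#'
#' Two weighted least-squares regressions of the relative growth rates on
#' the effective F-actin volume fraction, restricted to the phi image of
#' the stoichiometry validity window: (i) `dW/dt / W` vs `phi` yields
#' intercept `k_r` and slope `-k_l / v_A`; (ii) `dA/dt / A` vs `phi`
#' yields slope `-k_b / v_W` and `k_d = -slope - intercept`. Weights are
#' proportional to the current amount (variance stabilisation under
#' multiplicative noise); points with either amount below `min_amount` are
#' excluded because relative rates diverge as amounts vanish. Standard
#' errors come from a bootstrap over condensates. The fit is exactly
#' invariant to rescaling all amounts by a common factor (phi and relative
#' rates are intensive).
#'
#' When the point table carries the lagged amounts `a_lag2`, `w_lag2`
#' (added by [estimate_derivatives()]), the regressions use the
#' two-frame-lagged composition as an instrument: the central-difference
#' rate at frame `i` shares its observation noise (frames `i - 1`,
#' `i + 1`) and its within-window process noise with the contemporaneous
#' `phi_i`, which attenuates the ordinary least-squares slopes where
#' tracks linger near the dominant composition; `phi_{i-2}` is correlated
#' with `phi_i` through the process memory but independent of both noise
#' sources, removing that bias. Without the lag columns the fit falls
#' back to ordinary weighted least squares (exact on noise-free rates).
#'
#' @param points output of [estimate_derivatives()].
#' @param volume_model a `volume_model` or [volume_coefficients()] used for
#'   phi and the coefficient mapping.
#' @param window_s stoichiometry validity window; its phi image bounds the
#'   regression.
#' @param min_amount amount floor (IU) for relative rates.
#' @param n_boot bootstrap resamples over condensates.
#' @param boot_seed bootstrap seed.
#' @return An object of class `kinetic_fit`: `params` ([kinetic_params()]
#'   when all positive, else a plain list with a `positivity_flag`), `se`,
#'   `window_phi`, `window_s`, `n_points`, `n_condensates`, `r2` (both
#'   regressions), `boot_reps` (n_boot x 4 matrix) and `vol`.
#' @export
fit_kinetics <- function(points, volume_model = volume_coefficients(),
                         window_s = c(0.65, 0.93), min_amount = 0.5,
                         n_boot = 200, boot_seed = 1L) {
  vol <- .vol_of(volume_model)
  pt <- as.data.table(points)
  stopifnot(all(c("condensate_id", "a_iu", "w_iu", "dw", "da") %in% names(pt)))
  pt <- pt[is.finite(dw) & is.finite(da) & a_iu >= min_amount & w_iu >= min_amount]
  pt[, phi := vol$v_A * a_iu / (vol$v_A * a_iu + vol$v_W * w_iu)]
  window_phi <- stoich_to_phi(window_s, vol)
  pt <- pt[phi >= window_phi[1] & phi <= window_phi[2]]
  if (all(c("a_lag2", "w_lag2") %in% names(pt))) {
    pt[, z := vol$v_A * a_lag2 / (vol$v_A * a_lag2 + vol$v_W * w_lag2)]
    pt <- pt[is.finite(z)]
  } else {
    pt[, z := phi]
  }
  if (nrow(pt) < 100L) {
    stop("fewer than 100 rate points inside the phi window", call. = FALSE)
  }
  pt[, `:=`(yw = dw / w_iu, ya = da / a_iu)]
  stw <- .wls_stats(pt, "yw", "w_iu")
  sta <- .wls_stats(pt, "ya", "a_iu")
  fw <- .wls_solve(stw); fa <- .wls_solve(sta)
  coefs <- .map_coefs(fw, fa, vol)
  flag <- fw$slope >= 0 || fa$slope >= 0
  if (flag) {
    warning("non-negative regression slope: fitted k_l or k_b violates positivity",
            call. = FALSE)
  }
  reps <- NULL
  se <- setNames(rep(NA_real_, 4), names(coefs))
  ids <- stw$condensate_id
  if (n_boot > 0 && length(ids) > 1) {
    set.seed(boot_seed)
    setkey(stw, condensate_id); setkey(sta, condensate_id)
    reps <- t(vapply(seq_len(n_boot), function(b) {
      idx <- sample(ids, replace = TRUE)
      tryCatch(.map_coefs(.wls_solve(stw[J(idx)]), .wls_solve(sta[J(idx)]), vol),
               error = function(e) setNames(rep(NA_real_, 4), names(coefs)))
    }, numeric(4)))
    se <- apply(reps, 2, sd, na.rm = TRUE)
  }
  params <- if (!flag && all(coefs > 0)) {
    do.call(kinetic_params, as.list(coefs))
  } else {
    c(as.list(coefs), positivity_flag = TRUE)
  }
  structure(list(params = params, se = se,
                 window_phi = window_phi, window_s = window_s,
                 n_points = nrow(pt), n_condensates = length(ids),
                 r2 = c(w = fw$r2, a = fa$r2),
                 regressions = list(
                   w = c(intercept = fw$intercept, slope = fw$slope),
                   a = c(intercept = fa$intercept, slope = fa$slope)),
                 boot_reps = reps, vol = vol,
                 positivity_flag = flag),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Growth-law kinetic fit:\n")
  p <- x$params
  for (nm in c("k_r", "k_l", "k_b", "k_d")) {
    cat(sprintf("  %s = %.5g (+/- %.2g)\n", nm, p[[nm]], x$se[[nm]]))
  }
  cat(sprintf("  R^2: WSP-1 %.4f, F-actin %.4f; %d points, %d condensates, phi in [%.3f, %.3f]\n",
              x$r2["w"], x$r2["a"], x$n_points, x$n_condensates,
              x$window_phi[1], x$window_phi[2]))
  if (isTRUE(x$positivity_flag)) cat("  WARNING: positivity violated\n")
  invisible(x)
}

#' Compare fitted kinetic coefficients between conditions
#'
#' Per-coefficient fold and percent changes of a perturbed condition
#' relative to control, with uncertainties propagated from the paired
#' bootstrap replicate distributions, plus regime labels for both
#' conditions, the control's critical F-actin loss rate [critical_kd()]
#' and whether the perturbed `k_d` exceeds it.
#'
#' @param control,perturbed [fit_kinetics()] results (or lists with a
#'   `params` element).
#' @return An object of class `condition_comparison` with a `table`
#'   (`data.table`: coefficient, control, perturbed, fold, percent,
#'   fold_se), `regimes`, `critical_kd_control`,
#'   `perturbed_kd_exceeds_critical`.
#' @export
compare_conditions <- function(control, perturbed) {
  pc <- control$params; pp <- perturbed$params
  nm <- c("k_r", "k_l", "k_b", "k_d")
  ctrl <- vapply(nm, function(k) pc[[k]], numeric(1))
  pert <- vapply(nm, function(k) pp[[k]], numeric(1))
  fold <- pert / ctrl
  fold_se <- rep(NA_real_, 4)
  if (!is.null(control$boot_reps) && !is.null(perturbed$boot_reps)) {
    nb <- min(nrow(control$boot_reps), nrow(perturbed$boot_reps))
    ratio <- perturbed$boot_reps[seq_len(nb), ] / control$boot_reps[seq_len(nb), ]
    fold_se <- apply(ratio, 2, sd, na.rm = TRUE)
  }
  vol <- if (!is.null(control$vol)) control$vol else volume_coefficients()
  crit <- tryCatch(critical_kd(as_kinetic_params(ctrl_list <- setNames(as.list(ctrl), nm)), vol),
                   error = function(e) NA_real_)
  regimes <- c(
    control = tryCatch(classify_regime(as_kinetic_params(setNames(as.list(ctrl), nm)), vol),
                       error = function(e) NA_character_),
    perturbed = tryCatch(classify_regime(as_kinetic_params(setNames(as.list(pert), nm)), vol),
                         error = function(e) NA_character_))
  structure(list(
    table = data.table(coefficient = nm, control = ctrl, perturbed = pert,
                       fold = fold, percent = 100 * (fold - 1),
                       fold_se = fold_se),
    regimes = regimes, critical_kd_control = crit,
    perturbed_kd_exceeds_critical = is.finite(crit) && pert["k_d"] > crit),
    class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison (perturbed vs control):\n")
  print(x$table)
  cat(sprintf("  regimes: control %s, perturbed %s; critical k_d (control) = %.4g s^-1%s\n",
              x$regimes["control"], x$regimes["perturbed"],
              x$critical_kd_control,
              if (isTRUE(x$perturbed_kd_exceeds_critical))
                " (perturbed k_d exceeds it)" else ""))
  invisible(x)
}

#' Predict the phase portrait under an altered F-actin loss rate
#'
#' Substitutes `k_d` into a fitted (or given) control coefficient set,
#' evaluates the theoretical flux field and nullcline geometry, and
#' reports whether the nullclines are switched relative to the control
#' order (`s_W < s_A`) — the hallmark of crossing the critical point into
#' unbounded growth.
#'
#' @param control_fit a [fit_kinetics()] result, [kinetic_params()], or
#'   list with `params`/`vol`.
#' @param kd_override replacement F-actin loss rate (s^-1, > 0).
#' @param A_nodes,W_nodes grid axes for the predicted field.
#' @param tol nullcline-coincidence tolerance on the regime criterion.
#' @return A list with `params`, `field`, `nullclines` (`c(s_W, s_A)`),
#'   `control_nullclines`, `regime`, `switched`, `coincident`.
#' @export
predict_perturbed_portrait <- function(control_fit, kd_override,
                                       A_nodes = 10^seq(0, 3, length.out = 15),
                                       W_nodes = 10^seq(0, 3, length.out = 15),
                                       tol = 1e-9) {
  stopifnot(is.finite(kd_override), kd_override > 0)
  if (inherits(control_fit, "kinetic_fit")) {
    base <- as_kinetic_params(control_fit$params)
    vol <- control_fit$vol
  } else if (inherits(control_fit, "kinetic_params")) {
    base <- control_fit; vol <- volume_coefficients()
  } else {
    base <- as_kinetic_params(control_fit$params)
    vol <- .vol_of(control_fit$vol)
  }
  pert <- kinetic_params(k_r = base$k_r, k_l = base$k_l, k_b = base$k_b,
                         k_d = kd_override)
  nc0 <- nullcline_stoichiometries(base, vol)
  nc1 <- nullcline_stoichiometries(pert, vol)
  regime <- classify_regime(pert, vol, tol = tol)
  list(params = pert,
       field = predict_flux_field(pert, vol, A_nodes, W_nodes),
       nullclines = nc1, control_nullclines = nc0,
       regime = regime,
       switched = nc1["s_A"] < nc1["s_W"],
       coincident = regime == "critical")
}

#' Lower-bound extrapolation of the F-actin loss rate
#'
#' For a condition (strong knockdown) in which no dynamic condensates
#' remain, no mass-balance fit is possible; but the systematic increase of
#' the fitted `k_d` with knockdown severity — severity indexed by the rank
#' order of decreasing condensate counts per oocyte — supports a linear
#' extrapolation to the zero-condensate condition, reported as a lower
#' bound.
#'
#' @param kd_fits fitted `k_d` values per condition, with `NA` for the
#'   target (zero-count) condition.
#' @param counts condensate counts per oocyte for the same conditions;
#'   exactly the `NA` entries of `kd_fits` should have count 0.
#' @return A list with `kd_lower_bound`, `severity_index`, `fit`
#'   (intercept/slope).
#' @examples
#' estimate_kd_lower_bound(c(0.15, 0.255, 0.405, NA), c(2000, 120, 70, 0))
#' @export
estimate_kd_lower_bound <- function(kd_fits, counts) {
  stopifnot(length(kd_fits) == length(counts), all(counts >= 0))
  fitted <- !is.na(kd_fits)
  if (sum(fitted) < 2) {
    stop("insufficient trend: need at least 2 conditions with fitted k_d",
         call. = FALSE)
  }
  sev <- rank(-counts, ties.method = "first")
  x <- sev[fitted]; y <- kd_fits[fitted]
  if (any(diff(y[order(x)]) < 0)) {
    warning("k_d is not monotone across severity; extrapolating anyway",
            call. = FALSE)
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  target <- if (any(!fitted)) sev[!fitted][1] else max(sev) + 1
  list(kd_lower_bound = intercept + slope * target,
       severity_index = sev,
       fit = c(intercept = intercept, slope = slope))
}
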