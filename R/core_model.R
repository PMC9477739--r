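# The growth-law dynamical system for cortical condensates:
#   dW/dt = k_r W - k_l A W / V
#   dA/dt = k_b A W / V - k_d A,   V = v_A A + v_W W.
# The field is degree-1 homogeneous, so nullclines are rays of constant
# stoichiometry s = A/(A+W) and all composition dynamics are intensive.

#' Kinetic coefficients of the condensate growth laws
#'
#' Container for the four growth-law coefficients. The defaults are the
#' package's canonical coefficient set: it reproduces the experimentally
#' reported WSP-1 and F-actin nullcline stoichiometries (0.85 and 0.90)
#' together with the printed volume coefficients, and sits in the bounded
#' (grow-then-dissolve) regime. These defaults are configuration used by the
#' synthetic generator and the examples, not measured truth.
#'
#' @param k_r WSP-1 self-recruitment rate (s^-1, > 0).
#' @param k_l branching-dependent WSP-1 loss coefficient (µm³ IU^-1 s^-1, > 0).
#' @param k_b branching coefficient for WSP-1-dependent F-actin growth
#'   (µm³ IU^-1 s^-1, > 0).
#' @param k_d F-actin loss rate (s^-1, > 0).
#' @return An object of class `kinetic_params` (named list).
#' @examples
#' kinetic_params()
#' kinetic_params(k_d = 0.405) # moderate knockdown-like F-actin loss
#' @export
kinetic_params <- function(k_r = 0.1, k_l = 1.9529e-8, k_b = 2.43e-7,
                           k_d = 0.15) {
  vals <- c(k_r = k_r, k_l = k_l, k_b = k_b, k_d = k_d)
  if (length(vals) != 4L || !all(is.finite(vals)) || any(vals <= 0)) {
    stop("all four kinetic coefficients must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Growth-law kinetic coefficients:\n")
  cat(sprintf("  k_r = %.6g s^-1   (WSP-1 self-recruitment)\n", x$k_r))
  cat(sprintf("  k_l = %.6g um^3 IU^-1 s^-1 (branching-dependent WSP-1 loss)\n", x$k_l))
  cat(sprintf("  k_b = %.6g um^3 IU^-1 s^-1 (branching)\n", x$k_b))
  cat(sprintf("  k_d = %.6g s^-1   (F-actin loss)\n", x$k_d))
  invisible(x)
}

#' Volume coefficients of the linear volume relation
#'
#' The condensate volume is well described by `V = v_A * A + v_W * W` within
#' the stoichiometry window 0.65–0.93. Defaults are the experimentally
#' reported coefficients.
#'
#' @param v_A volume per unit F-actin intensity (µm³ IU^-1, > 0).
#' @param v_W volume per unit WSP-1 intensity (µm³ IU^-1, > 0).
#' @return An object of class `volume_coefficients`.
#' @examples
#' volume_coefficients()
#' @export
volume_coefficients <- function(v_A = 1.54e-7, v_W = 2.34e-7) {
  vals <- c(v_A = v_A, v_W = v_W)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("volume coefficients must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "volume_coefficients")
}

#' @export
print.volume_coefficients <- function(x, ...) {
  cat(sprintf("Volume relation V = v_A*A + v_W*W with v_A = %.6g, v_W = %.6g um^3 IU^-1\n",
              x$v_A, x$v_W))
  invisible(x)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  x <- as.list(x)
  do.call(kinetic_params, x[c("k_r", "k_l", "k_b", "k_d")])
}

as_volume_coefficients <- function(x) {
  if (inherits(x, "volume_coefficients")) return(x)
  x <- as.list(x)
  do.call(volume_coefficients, x[c("v_A", "v_W")])
}

#' Condensate volume from the linear volume relation
#'
#' @param A,W integrated F-actin and WSP-1 intensities (IU, vectorised).
#' @param vol a [volume_coefficients()] object.
#' @return Volumes in µm³.
#' @export
condensate_volume <- function(A, W, vol = volume_coefficients()) {
  vol <- as_volume_coefficients(vol)
  vol$v_A * A + vol$v_W * W
}

# unchecked fast path used by integrators and the simulator; evaluates the
# AW/V terms as (A/V)*W so the field is continuous along rays into the origin
.rates <- function(A, W, params, vol) {
  V <- vol$v_A * A + vol$v_W * W
  aV <- ifelse(V > 0, A / V, 0)
  dW <- params$k_r * W - params$k_l * aV * W
  dA <- params$k_b * aV * W - params$k_d * A
  list(dW = dW, dA = dA)
}

#' Growth rates of WSP-1 and F-actin amounts
#'
#' Evaluates the empirical growth laws
#' `dW/dt = k_r W - k_l A W / V` and `dA/dt = k_b A W / V - k_d A` with
#' `V = v_A A + v_W W`. The field is degree-1 homogeneous: scaling `(A, W)`
#' by any factor scales both rates by the same factor. At exactly
#' `(0, 0)` the rates are defined as `(0, 0)` (the fixed point).
#'
#' @param A,W nonnegative amounts (IU), vectorised.
#' @param params a [kinetic_params()] object.
#' @param vol a [volume_coefficients()] object.
#' @return A `data.frame` with columns `dW`, `dA` (IU s^-1).
#' @examples
#' growth_rates(100, 50) # transition-regime state under canonical defaults
#' @export
growth_rates <- function(A, W, params = kinetic_params(),
                         vol = volume_coefficients()) {
  params <- as_kinetic_params(params)
  vol <- as_volume_coefficients(vol)
  if (length(A) != length(W)) stop("A and W must have equal length", call. = FALSE)
  if (any(!is.finite(A)) || any(!is.finite(W)) || any(A < 0) || any(W < 0)) {
    stop("amounts must be finite and nonnegative", call. = FALSE)
  }
  r <- .rates(A, W, params, vol)
  data.frame(dW = r$dW, dA = r$dA)
}

#' Derived per-state observables
#'
#' For a state `(A, W)` returns the relation volume `V`, the stoichiometry
#' `s = A/(A+W)`, the effective F-actin volume fraction `phi = v_A A / V`
#' and the internal concentrations `c_A = A/V`, `c_W = W/V`. With `V` from
#' the volume relation, every concentration pair satisfies
#' `v_A c_A + v_W c_W = 1` exactly (the line of constant total density).
#'
#' @inheritParams growth_rates
#' @return A `data.frame` with columns `V`, `s`, `phi`, `c_A`, `c_W`.
#' @examples
#' observables(100, 50)
#' @export
observables <- function(A, W, vol = volume_coefficients()) {
  vol <- as_volume_coefficients(vol)
  if (any(!is.finite(A)) || any(!is.finite(W)) || any(A < 0) || any(W < 0)) {
    stop("amounts must be finite and nonnegative", call. = FALSE)
  }
  if (any(A + W <= 0)) {
    stop("observables are undefined at the (0, 0) fixed point", call. = FALSE)
  }
  V <- vol$v_A * A + vol$v_W * W
  data.frame(V = V, s = A / (A + W), phi = vol$v_A * A / V,
             c_A = A / V, c_W = W / V)
}

#' Convert between stoichiometry and effective F-actin volume fraction
#'
#' `stoich_to_phi()` maps `s = A/(A+W)` to `phi = v_A A / V` and
#' `phi_to_stoich()` is its inverse; both depend only on the volume
#' coefficients, not on amounts (composition variables are intensive).
#'
#' @param s stoichiometry in `[0, 1]` (vectorised).
#' @param phi volume fraction in `[0, 1]` (vectorised).
#' @inheritParams growth_rates
#' @return Numeric vector.
#' @examples
#' stoich_to_phi(0.86) # ~0.80: the growth-to-shrinkage transition
#' @export
stoich_to_phi <- function(s, vol = volume_coefficients()) {
  vol <- as_volume_coefficients(vol)
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("s must lie in [0, 1]", call. = FALSE)
  vol$v_A * s / (vol$v_A * s + vol$v_W * (1 - s))
}

#' @rdname stoich_to_phi
#' @export
phi_to_stoich <- function(phi, vol = volume_coefficients()) {
  vol <- as_volume_coefficients(vol)
  if (any(phi < 0 | phi > 1, na.rm = TRUE)) stop("phi must lie in [0, 1]", call. = FALSE)
  vol$v_W * phi / (vol$v_W * phi + vol$v_A * (1 - phi))
}

#' Stoichiometries of the two nullclines
#'
#' Both nullclines of the growth laws are rays through the origin, so each is
#' summarised by a single stoichiometry. The WSP-1 nullcline
#' `W_c(A) = A (k_l - k_r v_A) / (k_r v_W)` has stoichiometry
#' `s_W = k_r v_W / (k_r v_W + k_l - k_r v_A)`; the F-actin nullcline has
#' `s_A = (k_b - k_d v_W) / (k_b - k_d v_W + k_d v_A)`. If
#' `k_l <= k_r v_A` the WSP-1 nullcline degenerates to the A axis
#' (`s_W = 1`); if `k_b <= k_d v_W` the F-actin nullcline degenerates to the
#' W axis (`s_A = 0`).
#'
#' @inheritParams growth_rates
#' @return Named numeric vector `c(s_W, s_A)`.
#' @examples
#' nullcline_stoichiometries() # c(0.85, 0.90) for canonical defaults
#' @export
nullcline_stoichiometries <- function(params = kinetic_params(),
                                      vol = volume_coefficients()) {
  params <- as_kinetic_params(params)
  vol <- as_volume_coefficients(vol)
  s_W <- if (params$k_l > params$k_r * vol$v_A) {
    params$k_r * vol$v_W /
      (params$k_r * vol$v_W + params$k_l - params$k_r * vol$v_A)
  } else 1
  s_A <- if (params$k_b > params$k_d * vol$v_W) {
    (params$k_b - params$k_d * vol$v_W) /
      (params$k_b - params$k_d * vol$v_W + params$k_d * vol$v_A)
  } else 0
  c(s_W = s_W, s_A = s_A)
}

#' Regime criterion and classification
#'
#' The bounded (grow-then-dissolve) and unbounded growth regimes are
#' separated by the criterion `v_A k_r / k_l + v_W k_d / k_b = 1`, at which
#' the two nullclines coincide. `regime_criterion()` returns the criterion
#' value; `classify_regime()` labels the parameter set `"bounded"`
#' (criterion < 1), `"unbounded"` (> 1) or `"critical"` (within `tol`).
#'
#' @inheritParams growth_rates
#' @param tol tolerance on the criterion value for the `"critical"` label.
#' @return `regime_criterion()`: a number; `classify_regime()`: a string.
#' @examples
#' classify_regime() # "bounded": criterion ~0.933
#' classify_regime(kinetic_params(k_d = 0.405)) # "unbounded"
#' @export
regime_criterion <- function(params = kinetic_params(),
                             vol = volume_coefficients()) {
  params <- as_kinetic_params(params)
  vol <- as_volume_coefficients(vol)
  vol$v_A * params$k_r / params$k_l + vol$v_W * params$k_d / params$k_b
}

#' @rdname regime_criterion
#' @export
classify_regime <- function(params = kinetic_params(),
                            vol = volume_coefficients(), tol = 1e-9) {
  crit <- regime_criterion(params, vol)
  if (abs(crit - 1) <= tol) "critical" else if (crit < 1) "bounded" else "unbounded"
}

#' Critical F-actin loss rate
#'
#' Returns the value `k_d*` at which the two nullclines coincide,
#' `k_d* = (k_b / v_W) (1 - v_A k_r / k_l)`. For `k_d < k_d*` orbits are
#' bounded homoclinic loops; for `k_d > k_d*` condensates grow without bound.
#' Requires `k_l > k_r v_A`; otherwise no bounded regime exists for any
#' `k_d` and an error is signalled.
#'
#' @inheritParams growth_rates
#' @return Critical rate in s^-1.
#' @examples
#' critical_kd() # ~0.2196 s^-1
#' @export
critical_kd <- function(params = kinetic_params(),
                        vol = volume_coefficients()) {
  params <- as_kinetic_params(params)
  vol <- as_volume_coefficients(vol)
  if (params$k_l <= params$k_r * vol$v_A) {
    stop("degenerate geometry: k_l <= k_r * v_A, no bounded regime exists",
         call. = FALSE)
  }
  (params$k_b / vol$v_W) * (1 - vol$v_A * params$k_r / params$k_l)
}

#' Integrate a deterministic condensate orbit
#'
#' Solves the growth laws with adaptive error control (deSolve's lsoda,
#' relative tolerance 1e-8 by default). In the bounded regime, orbits started
#' above the WSP-1 nullcline are homoclinic: amounts first rise, then fall
#' back towards the origin while the stoichiometry converges monotonically
#' to the dominant stoichiometry (see [fixed_point_phi()]).
#'
#' @inheritParams growth_rates
#' @param A0,W0 initial amounts (IU); not both zero.
#' @param duration total integration time (s, > 0).
#' @param step output sampling interval (s, > 0); does not limit the
#'   internal adaptive step.
#' @param rtol,atol relative/absolute integrator tolerances.
#' @return A `data.frame` with columns `time`, `A`, `W`, `s`, `phi`.
#' @examples
#' orb <- integrate_orbit(A0 = 1, W0 = 5, duration = 60)
#' range(orb$s)
#' @export
integrate_orbit <- function(params = kinetic_params(),
                            vol = volume_coefficients(),
                            A0, W0, duration, step = 0.1,
                            rtol = 1e-8, atol = 1e-12) {
  params <- as_kinetic_params(params)
  vol <- as_volume_coefficients(vol)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (!is.finite(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  if (A0 < 0 || W0 < 0 || (A0 == 0 && W0 == 0)) {
    stop("initial state must be nonnegative and not (0, 0)", call. = FALSE)
  }
  deriv <- function(t, y, parms) {
    r <- .rates(max(y[1], 0), max(y[2], 0), params, vol)
    list(c(r$dA, r$dW))
  }
  times <- seq(0, duration, by = step)
  sol <- deSolve::ode(y = c(A = A0, W = W0), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (any(!is.finite(sol))) stop("nonfinite values during integration", call. = FALSE)
  A <- pmax(sol[, "A"], 0); W <- pmax(sol[, "W"], 0)
  tot <- A + W
  V <- vol$v_A * A + vol$v_W * W
  data.frame(time = sol[, "time"], A = A, W = W,
             s = ifelse(tot > 0, A / tot, NA_real_),
             phi = ifelse(V > 0, vol$v_A * A / V, NA_real_))
}

# bracket of the intensive phi dynamics; dphi/dt = phi (1 - phi) * bracket
.phi_bracket <- function(phi, params, vol) {
  params$k_b * (1 - phi) / vol$v_W - params$k_d - params$k_r +
    (params$k_l / vol$v_A) * phi
}

#' Intensive dynamics of the effective F-actin volume fraction
#'
#' The composition variable `phi = v_A A / V` evolves independently of
#' condensate size:
#' `dphi/dt = phi (1 - phi) [k_b (1 - phi)/v_W - k_d - k_r + (k_l/v_A) phi]`.
#' It vanishes on the invariant boundary rays `phi = 0` (pure WSP-1, the W
#' axis) and `phi = 1` (pure F-actin, the A axis).
#'
#' @param phi volume fraction in `[0, 1]` (vectorised).
#' @inheritParams growth_rates
#' @return `dphi/dt` in s^-1.
#' @export
phi_dynamics <- function(phi, params = kinetic_params(),
                         vol = volume_coefficients()) {
  params <- as_kinetic_params(params)
  vol <- as_volume_coefficients(vol)
  if (any(!is.finite(phi)) || any(phi < 0 | phi > 1)) {
    stop("phi must lie in [0, 1]", call. = FALSE)
  }
  phi * (1 - phi) * .phi_bracket(phi, params, vol)
}

#' Dominant composition: fixed point of the intensive dynamics
#'
#' Returns the interior root `phi*` of the bracket in [phi_dynamics()]
#' (closed form: `phi* = (k_b/v_W - k_d - k_r) / (k_b/v_W - k_l/v_A)`),
#' its stoichiometry image `s*`, and the relative amount growth rate
#' `k_r - (k_l/v_A) phi*` on the `phi*` ray. The root is stable for the
#' composition dynamics (`dphi/dt > 0` below, `< 0` above): every interior
#' trajectory converges to this composition, which is why the ensemble's
#' slowest dynamics and its preferred concentration pair sit on the `s*`
#' ray. In the bounded regime the amount growth rate along the ray is
#' negative (condensates dissolve along it, and `s* > s_A`); beyond the
#' critical point it is positive (unbounded growth at fixed composition).
#'
#' @inheritParams growth_rates
#' @return A list with `phi`, `s` and `amount_growth_rate` (s^-1).
#' @examples
#' fixed_point_phi() # phi* ~0.865, s* ~0.907
#' @export
fixed_point_phi <- function(params = kinetic_params(),
                            vol = volume_coefficients()) {
  params <- as_kinetic_params(params)
  vol <- as_volume_coefficients(vol)
  denom <- params$k_b / vol$v_W - params$k_l / vol$v_A
  if (denom == 0) stop("no dominant composition: bracket has no interior root",
                       call. = FALSE)
  phi_star <- (params$k_b / vol$v_W - params$k_d - params$k_r) / denom
  if (!is.finite(phi_star) || phi_star <= 0 || phi_star >= 1) {
    stop("no dominant composition: bracket root lies outside (0, 1)",
         call. = FALSE)
  }
  list(phi = phi_star,
       s = phi_to_stoich(phi_star, vol),
       amount_growth_rate = params$k_r - (params$k_l / vol$v_A) * phi_star)
}

#' Theoretical flux field on a grid of states
#'
#' Evaluates [growth_rates()] on every node of the grid spanned by `A_nodes`
#' and `W_nodes`. Used to overlay "theory" arrows on empirical portraits and
#' as the residual baseline for kinetic fits.
#'
#' @param A_nodes,W_nodes nonnegative amounts defining the grid axes (IU).
#' @inheritParams growth_rates
#' @return A `data.frame` with columns `A`, `W`, `dW`, `dA`.
#' @export
predict_flux_field <- function(params = kinetic_params(),
                               vol = volume_coefficients(),
                               A_nodes, W_nodes) {
  grid <- expand.grid(A = A_nodes, W = W_nodes, KEEP.OUT.ATTRS = FALSE)
  cbind(grid, growth_rates(grid$A, grid$W, params, vol))
}
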