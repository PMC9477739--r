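# The linear volume relation V = v_A A + v_W W: fitting from measured
# cross-sectional areas (spherical assumption), concentrations, and the
# line of constant total density it implies.

#' Volume of a sphere from its cross-sectional area
#'
#' Condensate volumes are estimated from segmented cross-sectional areas
#' under a spherical-shape assumption: `r = sqrt(area / pi)`,
#' `V = 4/3 pi r^3`.
#'
#' @param area cross-sectional area (µm², >= 0, vectorised).
#' @return Volume in µm³.
#' @examples
#' sphere_volume_from_area(pi) # unit radius: 4*pi/3
#' @export
sphere_volume_from_area <- function(area) {
  if (any(!is.finite(area)) || any(area < 0)) {
    stop("area must be finite and nonnegative", call. = FALSE)
  }
  (4 / 3) * pi * (area / pi)^(3 / 2)
}

# weighted-by-none zero-intercept two-regressor LS sufficient statistics,
# aggregated per condensate so the bootstrap can resample tracks in O(n)
.volume_fit_stats <- function(dt) {
  dt[, .(Saa = sum(a_iu^2), Sww = sum(w_iu^2), Saw = sum(a_iu * w_iu),
         Sav = sum(a_iu * V_meas), Swv = sum(w_iu * V_meas), n = .N),
     by = condensate_id]
}

.volume_coef_from_stats <- function(st) {
  XtX <- matrix(c(sum(st$Saa), sum(st$Saw), sum(st$Saw), sum(st$Sww)), 2, 2)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) {
    stop("rank-deficient volume fit: all points share one stoichiometry",
         call. = FALSE)
  }
  drop(solve(XtX, c(sum(st$Sav), sum(st$Swv))))
}

#' Fit the linear volume relation
#'
#' Zero-intercept least squares of the measured volume (from `area_um2` via
#' [sphere_volume_from_area()]) on the two amounts `(a_iu, w_iu)`,
#' restricted to points whose stoichiometry lies inside the validity window
#' (default 0.65–0.93, the range over which the relation accounts for
#' measured volumes). Uncertainties come from a bootstrap that resamples
#' condensates, not points, because frames within a track are
#' autocorrelated.
#'
#' @param tracks a track table (see [read_tracks()]) with an `area_um2`
#'   column.
#' @param window stoichiometry validity window `c(s_lo, s_hi)`.
#' @param n_boot bootstrap resamples for coefficient standard errors.
#' @param boot_seed seed for the bootstrap resampling.
#' @return An object of class `volume_model`: `coefficients`
#'   ([volume_coefficients()]), `se`, `window`, `n_points`, `n_condensates`.
#' @export
fit_volume_coefficients <- function(tracks, window = c(0.65, 0.93),
                                    n_boot = 200, boot_seed = 1L) {
  dt <- as.data.table(tracks)
  stopifnot(all(c("condensate_id", "a_iu", "w_iu") %in% names(dt)),
            "area_um2" %in% names(dt),
            length(window) == 2, window[1] < window[2],
            window[1] >= 0, window[2] <= 1)
  dt <- dt[is.finite(area_um2) & area_um2 > 0 & (a_iu + w_iu) > 0]
  dt[, s := a_iu / (a_iu + w_iu)]
  dt <- dt[s >= window[1] & s <= window[2]]
  if (nrow(dt) < 10L) {
    stop("fewer than 10 usable points inside the stoichiometry window",
         call. = FALSE)
  }
  dt[, V_meas := sphere_volume_from_area(area_um2)]
  st <- .volume_fit_stats(dt)
  coefs <- .volume_coef_from_stats(st)
  se <- c(NA_real_, NA_real_)
  if (n_boot > 0 && nrow(st) > 1) {
    set.seed(boot_seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(st), replace = TRUE)
      tryCatch(.volume_coef_from_stats(st[idx]),
               error = function(e) c(NA_real_, NA_real_))
    }, numeric(2))
    se <- apply(reps, 1, sd, na.rm = TRUE)
  }
  if (any(coefs <= 0)) {
    warning("fitted volume coefficients are not both positive", call. = FALSE)
    cf <- structure(list(v_A = coefs[1], v_W = coefs[2]),
                    class = "volume_coefficients_raw")
  } else {
    cf <- volume_coefficients(v_A = coefs[1], v_W = coefs[2])
  }
  structure(list(coefficients = cf,
                 se = c(v_A = se[1], v_W = se[2]),
                 window = window, n_points = nrow(dt),
                 n_condensates = nrow(st), n_boot = n_boot),
            class = "volume_model")
}

#' @export
print.volume_model <- function(x, ...) {
  cat("Linear volume relation fit (zero intercept):\n")
  cat(sprintf("  v_A = %.4g (+/- %.2g) um^3 IU^-1\n",
              x$coefficients$v_A, x$se["v_A"]))
  cat(sprintf("  v_W = %.4g (+/- %.2g) um^3 IU^-1\n",
              x$coefficients$v_W, x$se["v_W"]))
  cat(sprintf("  window s in [%.2f, %.2f], %d points from %d condensates\n",
              x$window[1], x$window[2], x$n_points, x$n_condensates))
  invisible(x)
}

.vol_of <- function(x) {
  if (inherits(x, "volume_model")) as_volume_coefficients(x$coefficients)
  else as_volume_coefficients(x)
}

#' Per-point internal concentrations
#'
#' Computes `c_A = A/V` and `c_W = W/V` for every track point, with `V`
#' either from the fitted volume relation (`"relation"`) or from the
#' measured area (`"measured"`, via [sphere_volume_from_area()]). With
#' relation volumes all pairs lie exactly on the line of constant total
#' density `v_A c_A + v_W c_W = 1`; with measured volumes the scatter about
#' that line reflects measurement noise. Points with nonpositive volume are
#' dropped with a message.
#'
#' @param tracks a track table.
#' @param volume_model a `volume_model` or [volume_coefficients()].
#' @param volume_source `"relation"` or `"measured"`.
#' @return A `data.table` with the track keys plus `V`, `c_a`, `c_w`, `s`.
#' @export
concentrations <- function(tracks, volume_model = volume_coefficients(),
                           volume_source = c("relation", "measured")) {
  volume_source <- match.arg(volume_source)
  vol <- .vol_of(volume_model)
  dt <- as.data.table(tracks)
  if (volume_source == "relation") {
    dt[, V := vol$v_A * a_iu + vol$v_W * w_iu]
  } else {
    stopifnot("area_um2" %in% names(dt))
    dt[, V := sphere_volume_from_area(area_um2)]
  }
  bad <- !is.finite(dt$V) | dt$V <= 0
  if (any(bad)) {
    message(sprintf("dropping %d points with nonpositive volume", sum(bad)))
    dt <- dt[!bad]
  }
  dt[, `:=`(c_a = a_iu / V, c_w = w_iu / V,
            s = ifelse(a_iu + w_iu > 0, a_iu / (a_iu + w_iu), NA_real_))]
  dt[]
}

#' Line of constant total density
#'
#' The volume relation constrains relation-derived concentration pairs to
#' the line `v_A c_A + v_W c_W = 1`, with axis intercepts `1/v_A` and
#' `1/v_W`. `density_line_residual()` evaluates the signed deviation
#' `v_A c_A + v_W c_W - 1` for given pairs.
#'
#' @param volume_model a `volume_model` or [volume_coefficients()].
#' @return A list with `v_A`, `v_W`, `intercept_c_A`, `intercept_c_W`.
#' @examples
#' density_line()$intercept_c_A # ~6.49e6 IU um^-3
#' @export
density_line <- function(volume_model = volume_coefficients()) {
  vol <- .vol_of(volume_model)
  structure(list(v_A = vol$v_A, v_W = vol$v_W,
                 intercept_c_A = 1 / vol$v_A, intercept_c_W = 1 / vol$v_W),
            class = "density_line")
}

#' @rdname density_line
#' @param c_a,c_w concentration pairs (IU µm^-3).
#' @export
density_line_residual <- function(c_a, c_w,
                                  volume_model = volume_coefficients()) {
  vol <- .vol_of(volume_model)
  vol$v_A * c_a + vol$v_W * c_w - 1
}
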