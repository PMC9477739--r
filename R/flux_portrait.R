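# Mass-balance imaging: per-point time derivatives of tracked amounts,
# binned vector fields in the (A, W) and (phi, V) planes, empirical
# nullclines, growth-rate-vs-stoichiometry curves, occupancy contours and
# the preferred concentration pair.

#' Per-point time derivatives of track amounts
#'
#' Central differences `(x[i+1] - x[i-1]) / (2 dt)` at interior frames;
#' endpoint frames are dropped. Optionally applies a Savitzky–Golay-style
#' local-quadratic derivative over a 5-frame window (`smooth = TRUE`),
#' which is unbiased for quadratics but attenuates rates near the loop's
#' turning points — hence off by default. Frame spacing must be constant
#' within 1% inside each track.
#'
#' @param tracks a track table (see [read_tracks()]).
#' @param smooth use the 5-frame local-quadratic derivative instead of
#'   plain central differences (tracks shorter than 5 frames fall back to
#'   central differences).
#' @param spacing_tol maximum relative deviation of frame spacing.
#' @return A `data.table` of interior points: track keys, `t`, `a_iu`,
#'   `w_iu`, optional `area_um2`, rates `dw`, `da` (IU s^-1), and the
#'   two-frame-lagged amounts `a_lag2`, `w_lag2` ([fit_kinetics()] uses the
#'   lagged composition as a noise-independent instrument).
#' @export
estimate_derivatives <- function(tracks, smooth = FALSE, spacing_tol = 0.01) {
  dt <- as.data.table(tracks)
  stopifnot(all(c("condensate_id", "t", "w_iu", "a_iu") %in% names(dt)))
  if (!"condition" %in% names(dt)) dt[, condition := "unknown"]
  if (!"oocyte_id" %in% names(dt)) dt[, oocyte_id := "unknown"]
  setorder(dt, condition, oocyte_id, condensate_id, t)
  dt[, n_frames := .N, by = .(condition, oocyte_id, condensate_id)]
  if (any(dt$n_frames < 3L)) {
    stop("all tracks must have at least 3 frames", call. = FALSE)
  }
  dt[, spacing := c(NA_real_, diff(t)),
     by = .(condition, oocyte_id, condensate_id)]
  bad <- dt[, {
    sp <- spacing[-1]
    md <- median(sp)
    any(abs(sp - md) > spacing_tol * md)
  }, by = .(condition, oocyte_id, condensate_id)][V1 == TRUE]
  if (nrow(bad)) {
    stop(sprintf("irregular frame spacing (> %.0f%%) in condensate(s): %s",
                 spacing_tol * 100,
                 paste(utils::head(bad$condensate_id, 5), collapse = ", ")),
         call. = FALSE)
  }
  deriv_one <- function(x, dtau, use_sg) {
    n <- length(x)
    if (use_sg && n >= 5L) {
      # local quadratic over 5 frames: derivative weights (-2,-1,0,1,2)/(10 dt)
      d <- rep(NA_real_, n)
      for (i in 3:(n - 2)) {
        d[i] <- sum(c(-2, -1, 0, 1, 2) * x[(i - 2):(i + 2)]) / (10 * dtau)
      }
      d
    } else {
      c(NA_real_, (x[3:n] - x[1:(n - 2)]) / (2 * dtau), NA_real_)
    }
  }
  dt[, `:=`(dw = deriv_one(w_iu, median(spacing, na.rm = TRUE), smooth),
            da = deriv_one(a_iu, median(spacing, na.rm = TRUE), smooth)),
     by = .(condition, oocyte_id, condensate_id)]
  # two-frame-lagged amounts: noise-independent instruments for the kinetic
  # regressions (their measurement and within-window process noise are
  # independent of the central-difference rates at frame i)
  dt[, `:=`(a_lag2 = shift(a_iu, 2L), w_lag2 = shift(w_iu, 2L)),
     by = .(condition, oocyte_id, condensate_id)]
  keep <- c("condition", "oocyte_id", "condensate_id", "t", "w_iu", "a_iu",
            intersect("area_um2", names(dt)), "dw", "da", "a_lag2", "w_lag2")
  out <- dt[is.finite(dw) & is.finite(da), ..keep]
  out[]
}

# geometric (log-spaced) bin edges over the occupied positive range
.geom_edges <- function(x, n_bins) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) stop("no positive values to bin", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) hi <- lo * (1 + 1e-9)
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  # pin the ends so extreme points cannot fall out through rounding
  edges[1] <- lo
  edges[n_bins + 1] <- hi
  edges
}

.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Bin a rate point cloud into a mass-flux vector field
#'
#' Bins points (with their per-point rates from [estimate_derivatives()])
#' on a geometric (log-spaced) grid over the occupied `(A, W)` range —
#' amounts span orders of magnitude — and records per-bin mean rates,
#' standard errors and occupancy. Bins with fewer than `min_count` points
#' are masked and excluded from nullcline extraction. Bin means are
#' permutation-invariant, so the field is independent of track ordering.
#'
#' @param points output of [estimate_derivatives()] (needs `a_iu`, `w_iu`,
#'   `dw`, `da`).
#' @param n_bins bins per axis.
#' @param min_count minimum occupancy for a bin to be used.
#' @return An object of class `flux_field`: `bins` (a `data.table` with
#'   `ia`, `iw`, `a_mid`, `w_mid`, `mean_dw`, `mean_da`, `sem_dw`,
#'   `sem_da`, `count`, `masked`), plus `edges_a`, `edges_w`, `min_count`,
#'   `n_points`.
#' @export
bin_vector_field <- function(points, n_bins = 24, min_count = 20) {
  pt <- as.data.table(points)
  stopifnot(all(c("a_iu", "w_iu", "dw", "da") %in% names(pt)))
  pt <- pt[is.finite(a_iu) & is.finite(w_iu) & is.finite(dw) & is.finite(da) &
             a_iu > 0 & w_iu > 0]
  if (!nrow(pt)) stop("no usable points", call. = FALSE)
  edges_a <- .geom_edges(pt$a_iu, n_bins)
  edges_w <- .geom_edges(pt$w_iu, n_bins)
  pt[, ia := .bin_index(a_iu, edges_a)]
  pt[, iw := .bin_index(w_iu, edges_w)]
  pt <- pt[!is.na(ia) & !is.na(iw)]
  bins <- pt[, .(mean_dw = mean(dw), mean_da = mean(da),
                 sem_dw = sd(dw) / sqrt(.N), sem_da = sd(da) / sqrt(.N),
                 count = .N), by = .(ia, iw)]
  bins[, `:=`(a_mid = sqrt(edges_a[ia] * edges_a[ia + 1L]),
              w_mid = sqrt(edges_w[iw] * edges_w[iw + 1L]),
              masked = count < min_count)]
  if (all(bins$masked)) {
    stop(sprintf("empty field: no bin reaches min_count = %d", min_count),
         call. = FALSE)
  }
  setorder(bins, ia, iw)
  structure(list(bins = bins[], edges_a = edges_a, edges_w = edges_w,
                 min_count = min_count, n_points = nrow(pt)),
            class = "flux_field")
}

#' @export
print.flux_field <- function(x, ...) {
  cat(sprintf("Mass-flux field: %d points in %d occupied bins (%d unmasked, min_count %d)\n",
              x$n_points, nrow(x$bins), sum(!x$bins$masked), x$min_count))
  invisible(x)
}

# total-least-squares ray through the origin: principal direction of the
# (uncentred) second-moment matrix; returns its stoichiometry
.tls_ray_stoich <- function(a, w) {
  M <- matrix(c(sum(a^2), sum(a * w), sum(a * w), sum(w^2)), 2, 2)
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v[1] / (v[1] + v[2])
}

#' Extract an empirical nullcline from a binned flux field
#'
#' Locates zero-crossings of the requested mean-rate component by linear
#' interpolation between adjacent unmasked bins (along the W direction of
#' each A column for the WSP-1 component, along A within each W row for
#' the F-actin component), fits a ray through the origin to the crossings
#' by total least squares, and reports the ray's stoichiometry with a
#' bootstrap standard error. In the unbounded regime the occupied region
#' lies entirely on the growth side, there is no sign change, and a
#' no-nullcline error is raised.
#'
#' @param field a [bin_vector_field()] result.
#' @param component `"W"` (WSP-1 nullcline) or `"A"` (F-actin nullcline).
#' @param n_boot bootstrap resamples over crossings.
#' @param boot_seed bootstrap seed.
#' @return An object of class `empirical_nullcline`: `component`,
#'   `crossings` (`data.table` of `(A, W)` crossing points),
#'   `stoichiometry`, `se`.
#' @export
extract_nullcline <- function(field, component = c("W", "A"),
                              n_boot = 200, boot_seed = 1L) {
  stopifnot(inherits(field, "flux_field"))
  component <- match.arg(component)
  bins <- field$bins[masked == FALSE]
  val_col <- if (component == "W") "mean_dw" else "mean_da"
  scan_by <- if (component == "W") "ia" else "iw"
  along <- if (component == "W") "iw" else "ia"
  crossings <- bins[, {
    o <- order(get(along))
    idx <- get(along)[o]
    v <- get(val_col)[o]
    am <- a_mid[o]; wm <- w_mid[o]
    res <- list(A = numeric(0), W = numeric(0))
    if (.N >= 2) {
      for (k in seq_len(.N - 1)) {
        if (idx[k + 1] == idx[k] + 1L && is.finite(v[k]) && is.finite(v[k + 1]) &&
            v[k] * v[k + 1] < 0) {
          f <- v[k] / (v[k] - v[k + 1])
          if (component == "W") {
            # interpolate along W (log position) at fixed A column
            res$A <- c(res$A, am[k])
            res$W <- c(res$W, exp(log(wm[k]) + f * (log(wm[k + 1]) - log(wm[k]))))
          } else {
            res$W <- c(res$W, wm[k])
            res$A <- c(res$A, exp(log(am[k]) + f * (log(am[k + 1]) - log(am[k]))))
          }
        }
      }
    }
    res
  }, by = scan_by]
  if (!nrow(crossings)) {
    stop(sprintf("no sign change in mean d%s/dt: no empirical %s nullcline (expected for unbounded-regime data)",
                 component, component), call. = FALSE)
  }
  s_hat <- .tls_ray_stoich(crossings$A, crossings$W)
  se <- NA_real_
  if (n_boot > 0 && nrow(crossings) > 1) {
    set.seed(boot_seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(crossings), replace = TRUE)
      .tls_ray_stoich(crossings$A[idx], crossings$W[idx])
    }, numeric(1))
    se <- sd(reps)
  }
  structure(list(component = component, crossings = crossings,
                 stoichiometry = s_hat, se = se),
            class = "empirical_nullcline")
}

#' @export
print.empirical_nullcline <- function(x, ...) {
  cat(sprintf("Empirical %s nullcline: stoichiometry %.4f (+/- %.4f) from %d crossings\n",
              x$component, x$stoichiometry, x$se, nrow(x$crossings)))
  invisible(x)
}

#' Growth rates as a function of stoichiometry
#'
#' Bins the per-point rates by stoichiometry `s = A/(A+W)` and reports the
#' mean WSP-1 and F-actin rates per bin with standard errors, together
#' with the interpolated growth-to-loss zero crossings of both curves. In
#' the bounded regime the WSP-1 curve crosses zero at a lower
#' stoichiometry than the F-actin curve (the three regimes: growth,
#' transition, disassembly); beyond the critical point the order is
#' swapped.
#'
#' @inheritParams bin_vector_field
#' @param n_bins stoichiometry bins over the occupied range.
#' @return An object of class `growth_curves`: `curves` (a `data.table`
#'   with `s_mid`, `s_mean` (occupancy-weighted stoichiometry), `mean_dw`,
#'   `mean_da`, `sem_dw`, `sem_da`, `count`, `masked`) and `zero_crossing` (named vector `c(W=, A=)`, `NA` when a
#'   curve does not cross).
#' @export
growth_vs_stoichiometry <- function(points, n_bins = 20, min_count = 20) {
  pt <- as.data.table(points)
  stopifnot(all(c("a_iu", "w_iu", "dw", "da") %in% names(pt)))
  pt <- pt[is.finite(dw) & is.finite(da) & (a_iu + w_iu) > 0]
  pt[, s := a_iu / (a_iu + w_iu)]
  edges <- seq(min(pt$s), max(pt$s), length.out = n_bins + 1)
  if (edges[1] == edges[n_bins + 1]) stop("degenerate stoichiometry range", call. = FALSE)
  pt[, ia := .bin_index(s, edges)]
  pt <- pt[!is.na(ia)]
  curves <- pt[, .(mean_dw = mean(dw), mean_da = mean(da),
                   sem_dw = sd(dw) / sqrt(.N), sem_da = sd(da) / sqrt(.N),
                   s_mean = mean(s), count = .N), by = ia]
  curves[, `:=`(s_mid = (edges[ia] + edges[ia + 1L]) / 2,
                masked = count < min_count)]
  setorder(curves, ia)
  if (all(curves$masked)) {
    stop(sprintf("no stoichiometry bin reaches min_count = %d", min_count),
         call. = FALSE)
  }
  cross_down <- function(s_mid, v) {
    # first +/- crossing (growth to loss) between adjacent unmasked bins
    for (k in seq_len(length(v) - 1)) {
      if (is.finite(v[k]) && is.finite(v[k + 1]) && v[k] > 0 && v[k + 1] < 0) {
        return(s_mid[k] + (s_mid[k + 1] - s_mid[k]) * v[k] / (v[k] - v[k + 1]))
      }
    }
    NA_real_
  }
  cu <- curves[masked == FALSE]
  zc <- c(W = cross_down(cu$s_mid, cu$mean_dw),
          A = cross_down(cu$s_mid, cu$mean_da))
  structure(list(curves = curves[], zero_crossing = zc, edges = edges),
            class = "growth_curves")
}

# ---- kernel density utilities ---------------------------------------------
# Binned 2-D Gaussian KDE (histogram + separable Gaussian smoothing).
# Scales to millions of points where a direct kernel sum cannot; Silverman's
# rule per axis for the bandwidth.
.binned_kde2d <- function(x, y, n_grid = 128, hx = NULL, hy = NULL, pad = 3) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (is.null(hx)) hx <- bw.nrd0(x)
  if (is.null(hy)) hy <- bw.nrd0(y)
  if (hx <= 0) hx <- max(abs(x), 1) * 1e-3
  if (hy <= 0) hy <- max(abs(y), 1) * 1e-3
  gx <- seq(min(x) - pad * hx, max(x) + pad * hx, length.out = n_grid)
  gy <- seq(min(y) - pad * hy, max(y) + pad * hy, length.out = n_grid)
  dxg <- gx[2] - gx[1]; dyg <- gy[2] - gy[1]
  ix <- pmin(pmax(findInterval(x, gx - dxg / 2), 1L), n_grid)
  iy <- pmin(pmax(findInterval(y, gy - dyg / 2), 1L), n_grid)
  C <- matrix(0, n_grid, n_grid)
  tb <- data.table(ix = ix, iy = iy)[, .N, by = .(ix, iy)]
  C[cbind(tb$ix, tb$iy)] <- tb$N
  Kx <- outer(gx, gx, function(a, b) dnorm(a - b, sd = hx)) * dxg
  Ky <- outer(gy, gy, function(a, b) dnorm(a - b, sd = hy)) * dyg
  Z <- (Kx %*% C %*% Ky) / (length(x) * dxg * dyg)
  list(x = gx, y = gy, z = Z, hx = hx, hy = hy)
}

# bilinear interpolation of a kde grid at points
.interp2 <- function(kde, x, y) {
  gx <- kde$x; gy <- kde$y; Z <- kde$z
  nx <- length(gx); ny <- length(gy)
  i <- pmin(pmax(findInterval(x, gx), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(y, gy), 1L), ny - 1L)
  tx <- pmin(pmax((x - gx[i]) / (gx[i + 1] - gx[i]), 0), 1)
  ty <- pmin(pmax((y - gy[j]) / (gy[j + 1] - gy[j]), 0), 1)
  Z[cbind(i, j)] * (1 - tx) * (1 - ty) + Z[cbind(i + 1L, j)] * tx * (1 - ty) +
    Z[cbind(i, j + 1L)] * (1 - tx) * ty + Z[cbind(i + 1L, j + 1L)] * tx * ty
}

#' Highest-density occupancy contours
#'
#' Kernel-density-based highest-density regions containing the stated
#' probability mass (defaults 68% and 25%, the conventional occupancy
#' contours for instantaneous condensate states). The density threshold for
#' level `p` is the `(1 - p)` quantile of the point densities, so the
#' fraction of points inside each contour matches its level by
#' construction; the achieved fraction is returned for checking.
#'
#' @param x,y point coordinates.
#' @param levels probability masses of the nested regions.
#' @param n_grid KDE grid resolution per axis.
#' @return An object of class `occupancy_contours`: per level a list with
#'   `level`, `threshold`, `fraction_inside` and `polygons` (from
#'   [grDevices::contourLines()]); plus the `kde` grid.
#' @export
occupancy_contours <- function(x, y, levels = c(0.68, 0.25), n_grid = 128) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 100) stop("need at least 100 points", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) stop("degenerate point cloud", call. = FALSE)
  kde <- .binned_kde2d(x, y, n_grid = n_grid)
  fp <- .interp2(kde, x, y)
  out <- lapply(levels, function(p) {
    thr <- as.numeric(quantile(fp, probs = 1 - p, type = 7))
    list(level = p, threshold = thr,
         fraction_inside = mean(fp >= thr),
         polygons = grDevices::contourLines(kde$x, kde$y, kde$z, levels = thr))
  })
  names(out) <- sprintf("level_%g", levels)
  structure(list(contours = out, kde = kde), class = "occupancy_contours")
}

#' Preferred concentration pair of an ensemble
#'
#' The mode of the 2-D kernel density of instantaneous internal
#' concentrations `(c_A, c_W)` — the pair of concentrations the ensemble
#' preferentially maintains. For relation-derived volumes this pair sits at
#' the intersection of the line of constant total density and the
#' dominant-stoichiometry ray. Reported with a bootstrap spread. If a
#' second density peak comes within 1% of the highest an ambiguity warning
#' is raised and the highest is returned.
#'
#' @param c_a,c_w concentration coordinates (IU µm^-3).
#' @param n_boot bootstrap resamples for the spread (0 disables).
#' @param n_grid KDE grid resolution.
#' @param boot_seed bootstrap seed.
#' @return A list with `c_a`, `c_w`, `spread` (bootstrap sds) and `s`
#'   (stoichiometry of the pair).
#' @export
preferred_concentration_pair <- function(c_a, c_w, n_boot = 50,
                                         n_grid = 128, boot_seed = 1L) {
  ok <- is.finite(c_a) & is.finite(c_w)
  c_a <- c_a[ok]; c_w <- c_w[ok]
  if (length(c_a) < 100) stop("need at least 100 points", call. = FALSE)
  if (sd(c_a) == 0 && sd(c_w) == 0) {
    return(list(c_a = c_a[1], c_w = c_w[1], spread = c(c_a = 0, c_w = 0),
                s = c_a[1] / (c_a[1] + c_w[1])))
  }
  kde <- .binned_kde2d(c_a, c_w, n_grid = n_grid)
  k <- arrayInd(which.max(kde$z), dim(kde$z))
  peak <- c(kde$x[k[1]], kde$y[k[2]])
  # secondary-peak check: local maxima of the grid away from the global one
  zmax <- max(kde$z)
  loc <- which(kde$z >= zmax * 0.99, arr.ind = TRUE)
  far <- abs(loc[, 1] - k[1]) + abs(loc[, 2] - k[2]) > n_grid / 8
  if (any(far)) {
    warning("ambiguous density: a second peak within 1% of the highest; returning the highest",
            call. = FALSE)
  }
  spread <- c(c_a = NA_real_, c_w = NA_real_)
  if (n_boot > 0) {
    set.seed(boot_seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(c_a), replace = TRUE)
      kb <- .binned_kde2d(c_a[idx], c_w[idx], n_grid = max(n_grid / 2, 32))
      kk <- arrayInd(which.max(kb$z), dim(kb$z))
      c(kb$x[kk[1]], kb$y[kk[2]])
    }, numeric(2))
    spread <- c(c_a = sd(reps[1, ]), c_w = sd(reps[2, ]))
  }
  list(c_a = peak[1], c_w = peak[2], spread = spread,
       s = peak[1] / (peak[1] + peak[2]))
}

#' Flux field in the (phi, V) plane
#'
#' Changes variables from amounts to composition and size: per point,
#' `phi = v_A A / V` and `V`, with rates obtained by the chain rule from
#' the amount rates (`dV = v_A dA + v_W dW`,
#' `dphi = (v_A dA - phi dV) / V`). Bins on a linear phi x geometric V
#' grid, extracts the volume nullcline (zero of mean `dV/dt` along phi
#' within each V row), and summarises intensivity: per phi row with enough
#' occupied V bins, the weighted trend of mean `dphi/dt` across `log V`
#' (slope consistent with zero when composition dynamics are independent
#' of size).
#'
#' @inheritParams bin_vector_field
#' @param volume_model a `volume_model` or [volume_coefficients()].
#' @param volume_source `"relation"` (volumes from the fitted relation) or
#'   `"measured"` (from `area_um2`).
#' @param n_bins bins per axis.
#' @return An object of class `phi_v_field`: `bins` (with `i_phi`, `i_V`,
#'   `phi_mid`, `V_mid`, `mean_dphi`, `mean_dV`, sems, `count`, `masked`),
#'   `volume_nullcline` (crossings and mean phi with se), and
#'   `intensivity` (per-phi-row slope of mean dphi/dt vs log V with
#'   standard error and t value).
#' @export
phi_V_field <- function(points, volume_model = volume_coefficients(),
                        volume_source = c("relation", "measured"),
                        n_bins = 24, min_count = 20) {
  volume_source <- match.arg(volume_source)
  vol <- .vol_of(volume_model)
  pt <- as.data.table(points)
  stopifnot(all(c("a_iu", "w_iu", "dw", "da") %in% names(pt)))
  if (volume_source == "measured") {
    stopifnot("area_um2" %in% names(pt))
    pt[, V := sphere_volume_from_area(area_um2)]
  } else {
    pt[, V := vol$v_A * a_iu + vol$v_W * w_iu]
  }
  pt <- pt[is.finite(V) & V > 0]
  pt[, phi := vol$v_A * a_iu / V]
  pt <- pt[is.finite(phi) & phi >= 0 & phi <= 1]
  pt[, dV := vol$v_A * da + vol$v_W * dw]
  pt[, dphi := (vol$v_A * da - phi * dV) / V]
  edges_phi <- seq(min(pt$phi), max(pt$phi), length.out = n_bins + 1)
  edges_V <- .geom_edges(pt$V, n_bins)
  pt[, i_phi := .bin_index(phi, edges_phi)]
  pt[, i_V := .bin_index(V, edges_V)]
  pt <- pt[!is.na(i_phi) & !is.na(i_V)]
  bins <- pt[, .(mean_dphi = mean(dphi), mean_dV = mean(dV),
                 sem_dphi = sd(dphi) / sqrt(.N), sem_dV = sd(dV) / sqrt(.N),
                 count = .N), by = .(i_phi, i_V)]
  bins[, `:=`(phi_mid = (edges_phi[i_phi] + edges_phi[i_phi + 1L]) / 2,
              V_mid = sqrt(edges_V[i_V] * edges_V[i_V + 1L]),
              masked = count < min_count)]
  if (all(bins$masked)) {
    stop(sprintf("empty field: no bin reaches min_count = %d", min_count),
         call. = FALSE)
  }
  setorder(bins, i_V, i_phi)
  # volume nullcline: phi at which mean dV/dt crosses +/- within each V row
  un <- bins[masked == FALSE]
  crossings <- un[, {
    o <- order(i_phi)
    v <- mean_dV[o]; pm <- phi_mid[o]; idx <- i_phi[o]
    res <- numeric(0)
    if (.N >= 2) {
      for (k in seq_len(.N - 1)) {
        if (idx[k + 1] == idx[k] + 1L && v[k] > 0 && v[k + 1] < 0) {
          res <- c(res, pm[k] + (pm[k + 1] - pm[k]) * v[k] / (v[k] - v[k + 1]))
        }
      }
    }
    list(phi_c = res)
  }, by = i_V]
  vol_null <- list(crossings = crossings,
                   phi = if (nrow(crossings)) mean(crossings$phi_c) else NA_real_,
                   se = if (nrow(crossings) > 1)
                     sd(crossings$phi_c) / sqrt(nrow(crossings)) else NA_real_)
  # intensivity: weighted slope of mean dphi across log V at fixed phi
  intens <- un[, {
    if (.N >= 3) {
      wgt <- 1 / pmax(sem_dphi, 1e-12)^2
      xv <- log(V_mid)
      Sw <- sum(wgt); Sx <- sum(wgt * xv); Sxx <- sum(wgt * xv^2)
      Sy <- sum(wgt * mean_dphi); Sxy <- sum(wgt * xv * mean_dphi)
      den <- Sw * Sxx - Sx^2
      slope <- (Sw * Sxy - Sx * Sy) / den
      se <- sqrt(Sw / den)
      list(slope = slope, se = se, t_value = slope / se, n_bins_V = .N)
    } else {
      list(slope = NA_real_, se = NA_real_, t_value = NA_real_, n_bins_V = .N)
    }
  }, by = i_phi]
  intens[, phi_mid := (edges_phi[i_phi] + edges_phi[i_phi + 1L]) / 2]
  structure(list(bins = bins[], edges_phi = edges_phi, edges_V = edges_V,
                 volume_nullcline = vol_null, intensivity = intens[],
                 min_count = min_count, n_points = nrow(pt)),
            class = "phi_v_field")
}

#' One-dimensional rate profiles at constant amount
#'
#' Slices a binned flux field at a fixed F-actin (`axis = "A"`) or WSP-1
#' (`axis = "W"`) amount and returns the mean rates with standard errors
#' along the other axis — the binned analogue of studying growth rates at
#' constant amounts.
#'
#' @param field a [bin_vector_field()] result.
#' @param axis which amount is held fixed.
#' @param value the amount (IU) at which to slice.
#' @return A `data.table` of unmasked bins along the slice.
#' @export
conditional_rate_slices <- function(field, axis = c("A", "W"), value) {
  stopifnot(inherits(field, "flux_field"))
  axis <- match.arg(axis)
  edges <- if (axis == "A") field$edges_a else field$edges_w
  if (!is.finite(value) || value < edges[1] || value > edges[length(edges)]) {
    stop("slice value outside the occupied range", call. = FALSE)
  }
  i <- .bin_index(value, edges)
  sl <- if (axis == "A") field$bins[ia == i & masked == FALSE]
        else field$bins[iw == i & masked == FALSE]
  if (!nrow(sl)) stop("empty slice: no unmasked bins at this value", call. = FALSE)
  setorderv(sl, if (axis == "A") "iw" else "ia")
  sl[]
}
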