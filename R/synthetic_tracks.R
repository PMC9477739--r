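# Stochastic condensate-track generator. Latent states follow
# Euler-Maruyama steps of the growth laws with independent multiplicative
# Gaussian noise on each of the four rate terms (chemical-Langevin-like,
# preserves positivity and approximate homogeneity); observations multiply
# latent amounts by log-normal factors; tracks are truncated at a detection
# threshold and sampled at a fixed frame interval.

#' Configuration for the synthetic track generator
#'
#' Defaults encode the observation conditions the analysis assumes: 0.5 s
#' frame interval, a 600 s observation window (the duration of the cortical
#' activation stage), Poisson nucleation, WSP-1-rich nucleation seeds (median
#' 3 IU, log-sd 0.5, F-actin 0.2 IU — condensates are enriched first in
#' WSP-1 and must start above the WSP-1 nullcline to grow), a 1 IU detection
#' threshold, intrinsic rate noise 0.1 and 5% multiplicative measurement
#' noise.
#'
#' @param params [kinetic_params()] governing the latent dynamics.
#' @param vol [volume_coefficients()] for volumes/areas.
#' @param nucleation_rate nucleation events per second per field of view (> 0).
#' @param seed_W_median,seed_W_sdlog log-normal nucleation WSP-1 amount
#'   (median IU, log-sd).
#' @param seed_A nucleation F-actin amount (IU).
#' @param frame_interval frame spacing (s, > 0).
#' @param duration observation window (s, >= frame_interval).
#' @param intrinsic_noise_sd dimensionless multiplicative rate-noise scale
#'   per sqrt(s) (>= 0); each of the four rate terms receives an independent
#'   Gaussian factor per integration step.
#' @param obs_noise_sd log-sd of the multiplicative measurement noise (>= 0).
#' @param detection_threshold total intensity (IU) below which a latent
#'   track is truncated.
#' @param rng_seed integer seed; all generator randomness flows from it.
#' @param substeps internal Euler-Maruyama substeps per frame interval.
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config(duration = 60, rng_seed = 7L)
#' @export
generator_config <- function(params = kinetic_params(),
                             vol = volume_coefficients(),
                             nucleation_rate = 7,
                             seed_W_median = 3, seed_W_sdlog = 0.5,
                             seed_A = 0.2,
                             frame_interval = 0.5, duration = 600,
                             intrinsic_noise_sd = 0.1, obs_noise_sd = 0.05,
                             detection_threshold = 1,
                             rng_seed = 1L, substeps = 10L) {
  params <- as_kinetic_params(params)
  vol <- as_volume_coefficients(vol)
  stopifnot(is.finite(nucleation_rate), nucleation_rate > 0,
            is.finite(seed_W_median), seed_W_median > 0,
            is.finite(seed_W_sdlog), seed_W_sdlog >= 0,
            is.finite(seed_A), seed_A >= 0,
            is.finite(frame_interval), frame_interval > 0,
            is.finite(duration), duration >= frame_interval,
            is.finite(intrinsic_noise_sd), intrinsic_noise_sd >= 0,
            is.finite(obs_noise_sd), obs_noise_sd >= 0,
            is.finite(detection_threshold), detection_threshold >= 0,
            substeps >= 1)
  structure(list(params = params, vol = vol,
                 nucleation_rate = nucleation_rate,
                 seed_W_median = seed_W_median, seed_W_sdlog = seed_W_sdlog,
                 seed_A = seed_A, frame_interval = frame_interval,
                 duration = duration,
                 intrinsic_noise_sd = intrinsic_noise_sd,
                 obs_noise_sd = obs_noise_sd,
                 detection_threshold = detection_threshold,
                 rng_seed = as.integer(rng_seed),
                 substeps = as.integer(substeps)),
            class = "generator_config")
}

# cross-sectional area of a sphere of volume V (inverse of the spherical
# volume-from-area conversion)
.area_from_volume <- function(V) {
  pi * (3 * V / (4 * pi))^(2 / 3)
}

# Vectorised Euler-Maruyama simulation of many tracks on a common step grid.
# Consumes the current RNG stream; callers are responsible for seeding.
.simulate_latent <- function(config, nucleation_times) {
  p <- config$params; v <- config$vol
  dt <- config$frame_interval / config$substeps
  sqdt <- sqrt(dt)
  nsteps <- as.integer(round(config$duration / dt))
  n <- length(nucleation_times)
  start_step <- pmin(as.integer(round(nucleation_times / dt)), nsteps)
  W0 <- rlnorm(n, meanlog = log(config$seed_W_median),
               sdlog = config$seed_W_sdlog)
  A0 <- rep(config$seed_A, n)
  max_frames <- as.integer(ceiling(config$duration / config$frame_interval)) + 1L
  Wf <- matrix(NA_real_, max_frames, n)
  Af <- matrix(NA_real_, max_frames, n)
  frame_count <- integer(n)
  A <- numeric(n); W <- numeric(n)
  alive <- rep(FALSE, n); dead <- rep(FALSE, n)
  death_time <- rep(NA_real_, n)
  sig <- config$intrinsic_noise_sd
  thr <- config$detection_threshold
  for (j in 0:nsteps) {
    act <- which(!alive & !dead & start_step == j)
    if (length(act)) {
      A[act] <- A0[act]; W[act] <- W0[act]; alive[act] <- TRUE
      below <- act[A[act] + W[act] < thr]
      if (length(below)) {
        alive[below] <- FALSE; dead[below] <- TRUE; death_time[below] <- j * dt
      }
    }
    rec <- which(alive & (j - start_step) %% config$substeps == 0L)
    if (length(rec)) {
      fi <- frame_count[rec] + 1L
      frame_count[rec] <- fi
      Wf[cbind(fi, rec)] <- W[rec]
      Af[cbind(fi, rec)] <- A[rec]
    }
    if (j == nsteps) break
    ai <- which(alive)
    if (!length(ai)) next
    Aa <- A[ai]; Wa <- W[ai]
    V <- v$v_A * Aa + v$v_W * Wa
    aV <- ifelse(V > 0, Aa / V, 0)
    T1 <- p$k_r * Wa; T2 <- p$k_l * aV * Wa
    T3 <- p$k_b * aV * Wa; T4 <- p$k_d * Aa
    if (sig > 0) {
      m <- length(ai)
      dWs <- (T1 - T2) * dt + (T1 * rnorm(m) - T2 * rnorm(m)) * sig * sqdt
      dAs <- (T3 - T4) * dt + (T3 * rnorm(m) - T4 * rnorm(m)) * sig * sqdt
    } else {
      dWs <- (T1 - T2) * dt
      dAs <- (T3 - T4) * dt
    }
    Wn <- pmax(Wa + dWs, 0)
    An <- pmax(Aa + dAs, 0)
    if (any(!is.finite(Wn)) || any(!is.finite(An))) {
      stop(sprintf("nonfinite latent state at t = %.3f s (tracks %s)",
                   (j + 1) * dt,
                   paste(utils::head(ai[!is.finite(Wn) | !is.finite(An)], 5),
                         collapse = ", ")), call. = FALSE)
    }
    W[ai] <- Wn; A[ai] <- An
    died <- ai[Wn + An < thr]
    if (length(died)) {
      alive[died] <- FALSE; dead[died] <- TRUE
      death_time[died] <- (j + 1) * dt
    }
  }
  list(Wf = Wf, Af = Af, frame_count = frame_count,
       start_step = start_step, dt = dt, seed_W = W0,
       dissolved = dead, death_time = death_time, censored = alive)
}

# latent frame matrices -> observed long-format track table
.observe_tracks <- function(sim, config, condition, oocyte_id,
                            keep_latent = FALSE) {
  n <- length(sim$frame_count)
  ids <- rep(seq_len(n), sim$frame_count)
  if (!length(ids)) {
    return(list(tracks = .empty_track_table(), latent = NULL,
                kept_ids = integer(0)))
  }
  fidx <- sequence(sim$frame_count)
  latW <- sim$Wf[cbind(fidx, ids)]
  latA <- sim$Af[cbind(fidx, ids)]
  t_abs <- (sim$start_step[ids] + (fidx - 1L) * config$substeps) * sim$dt
  N <- length(ids)
  fw <- if (config$obs_noise_sd > 0) rlnorm(N, 0, config$obs_noise_sd) else rep(1, N)
  fa <- if (config$obs_noise_sd > 0) rlnorm(N, 0, config$obs_noise_sd) else rep(1, N)
  fs <- if (config$obs_noise_sd > 0) rlnorm(N, 0, config$obs_noise_sd) else rep(1, N)
  Vlat <- config$vol$v_A * latA + config$vol$v_W * latW
  dtb <- data.table(condition = condition, oocyte_id = oocyte_id,
                    track_no = ids,
                    condensate_id = sprintf("c%05d", ids),
                    t = t_abs,
                    w_iu = latW * fw, a_iu = latA * fa,
                    area_um2 = .area_from_volume(Vlat) * fs)
  if (keep_latent) {
    dtb[, `:=`(w_lat = latW, a_lat = latA)]
  }
  # trim leading/trailing observed frames below the detection threshold,
  # then drop tracks shorter than 3 frames
  thr <- config$detection_threshold
  dtb[, keep := {
    ok <- (w_iu + a_iu) >= thr
    if (any(ok)) seq_len(.N) >= min(which(ok)) & seq_len(.N) <= max(which(ok))
    else rep(FALSE, .N)
  }, by = track_no]
  dtb <- dtb[keep == TRUE][, keep := NULL]
  dtb <- dtb[, if (.N >= 3L) .SD, by = track_no]
  kept <- unique(dtb$track_no)
  latent <- NULL
  if (keep_latent && nrow(dtb)) {
    latent <- dtb[, .(condensate_id, t, W = w_lat, A = a_lat)]
    dtb[, `:=`(w_lat = NULL, a_lat = NULL)]
  }
  dtb[, track_no := NULL]
  list(tracks = dtb[], latent = latent, kept_ids = kept)
}

.empty_track_table <- function() {
  data.table(condition = character(), oocyte_id = character(),
             condensate_id = character(), t = numeric(),
             w_iu = numeric(), a_iu = numeric(), area_um2 = numeric())
}

#' Simulate a single condensate track
#'
#' Runs one latent Euler-Maruyama realisation of the growth laws from a
#' WSP-1-rich nucleation seed, applies measurement noise and detection
#' truncation, and returns both the observed track and the latent states.
#' Fully deterministic given `config$rng_seed`.
#'
#' @param config a [generator_config()].
#' @param nucleation_time nucleation time within the observation window (s).
#' @return A list with `track` (observed frames: `condition`, `oocyte_id`,
#'   `condensate_id`, `t`, `w_iu`, `a_iu`, `area_um2`), `latent` (true
#'   amounts at frame times) and `dissolved` (logical).
#' @examples
#' tr <- simulate_track(generator_config(duration = 60, rng_seed = 3L))
#' head(tr$track)
#' @export
simulate_track <- function(config, nucleation_time = 0) {
  stopifnot(inherits(config, "generator_config"),
            nucleation_time >= 0, nucleation_time < config$duration)
  set.seed(config$rng_seed)
  sim <- .simulate_latent(config, nucleation_time)
  obs <- .observe_tracks(sim, config, condition = "control",
                         oocyte_id = "oo1", keep_latent = TRUE)
  list(track = obs$tracks, latent = obs$latent,
       dissolved = sim$dissolved[1], death_time = sim$death_time[1])
}

#' Generate a synthetic condensate track ensemble
#'
#' Draws nucleation times from a Poisson process over the observation
#' window (or conditions on `n_condensates`, in which case times are iid
#' uniform over the window), simulates every track with the vectorised
#' Euler-Maruyama stepper, applies measurement noise and detection
#' truncation, and returns the observed track table together with a
#' ground-truth sidecar for parameter-recovery tests.
#'
#' @param config a [generator_config()].
#' @param n_condensates fixed number of nucleation events; `NULL` draws
#'   `Poisson(nucleation_rate * nucleation_window)`.
#' @param condition,oocyte_id labels stamped on every row.
#' @param nucleation_window length of the nucleation window (s); defaults to
#'   the full observation window. Set it small to nucleate all condensates
#'   near `t = 0` (useful for lifetime and regime studies without censoring).
#' @return An object of class `track_ensemble`: a list with `tracks` (the
#'   observed [read_tracks()]-format table) and `truth` (generator
#'   parameters plus a per-condensate table of nucleation time, seed
#'   amounts, dissolution flag and death time).
#' @examples
#' ens <- generate_ensemble(generator_config(duration = 40, rng_seed = 2L),
#'                          n_condensates = 20)
#' nrow(ens$tracks)
#' @export
generate_ensemble <- function(config, n_condensates = NULL,
                              condition = "control", oocyte_id = "oo1",
                              nucleation_window = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$rng_seed)
  win <- if (is.null(nucleation_window)) config$duration else nucleation_window
  stopifnot(win >= 0, win <= config$duration)
  n <- if (is.null(n_condensates)) rpois(1, config$nucleation_rate * max(win, 1e-9))
       else as.integer(n_condensates)
  if (n <= 0) stop("empty ensemble: no condensates nucleated", call. = FALSE)
  t0 <- sort(runif(n, 0, win))
  sim <- .simulate_latent(config, t0)
  obs <- .observe_tracks(sim, config, condition, oocyte_id)
  if (!nrow(obs$tracks)) {
    stop("empty ensemble: no track survived detection/length filters",
         call. = FALSE)
  }
  truth <- list(
    params = config$params, vol = config$vol, config = config,
    condensates = data.table(
      condensate_id = sprintf("c%05d", seq_len(n)),
      nucleation_time = t0, seed_W = sim$seed_W, seed_A = config$seed_A,
      dissolved = sim$dissolved, censored = sim$censored,
      death_time = sim$death_time,
      kept = seq_len(n) %in% obs$kept_ids))
  structure(list(tracks = obs$tracks, truth = truth),
            class = "track_ensemble")
}

#' @export
print.track_ensemble <- function(x, ...) {
  nt <- length(unique(x$tracks$condensate_id))
  cat(sprintf("Synthetic track ensemble: %d tracks, %d frames, %d dissolved, %d censored\n",
              nt, nrow(x$tracks), sum(x$truth$condensates$dissolved),
              sum(x$truth$condensates$censored)))
  invisible(x)
}

#' Kinetic coefficient presets for ARP2/3 (arx-2) knockdown conditions
#'
#' Rescales the canonical control coefficients by the experimentally
#' reported knockdown effects: mild RNAi reduces WSP-1 self-recruitment
#' `k_r` by 17% and increases F-actin loss `k_d` 1.7-fold; moderate RNAi
#' reduces `k_r` by 15%, increases `k_l` by 20% and `k_d` 2.7-fold; the
#' branching coefficient `k_b` is unchanged throughout. The strong preset
#' (no dynamic condensates observable, so no fit is possible) pins `k_d`
#' at 1.2x the critical value [critical_kd()], just beyond the transition
#' to unbounded growth.
#'
#' @param name one of `"control"`, `"mild"`, `"moderate"`, `"strong"`.
#' @param base control coefficients to rescale.
#' @param vol volume coefficients (used by the strong preset's critical
#'   point).
#' @return A [kinetic_params()] object.
#' @examples
#' rnai_preset("mild")$k_d # 1.7 * 0.15
#' classify_regime(rnai_preset("strong"))
#' @export
rnai_preset <- function(name = c("control", "mild", "moderate", "strong"),
                        base = kinetic_params(),
                        vol = volume_coefficients()) {
  name <- match.arg(name)
  base <- as_kinetic_params(base)
  switch(name,
    control = base,
    mild = kinetic_params(k_r = base$k_r * 0.83, k_l = base$k_l * 1.01,
                          k_b = base$k_b, k_d = base$k_d * 1.7),
    moderate = kinetic_params(k_r = base$k_r * 0.85, k_l = base$k_l * 1.20,
                              k_b = base$k_b, k_d = base$k_d * 2.7),
    strong = kinetic_params(k_r = base$k_r, k_l = base$k_l, k_b = base$k_b,
                            k_d = 1.2 * critical_kd(base, vol)))
}

#' Write an ensemble's tracks and ground-truth sidecar
#'
#' Writes the observed tracks in the TSV dialect of [write_tracks()] and
#' the ground truth (generator parameters and per-condensate fate) as a
#' YAML sidecar.
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param tracks_path,truth_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_ensemble <- function(ensemble, tracks_path, truth_path) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  write_tracks(ensemble$tracks, tracks_path)
  tr <- ensemble$truth
  side <- list(
    params = unclass(tr$params), vol = unclass(tr$vol),
    generator = unclass(tr$config)[setdiff(names(tr$config), c("params", "vol"))],
    condensates = lapply(seq_len(nrow(tr$condensates)), function(i)
      as.list(tr$condensates[i])))
  yaml::write_yaml(side, truth_path)
  invisible(c(tracks_path, truth_path))
}
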