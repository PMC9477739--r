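# Track-table IO, ensemble statistics, configuration and the end-to-end
# pipeline: simulate -> fit-volume -> portrait -> fit-kinetics -> compare
# -> report.

.track_cols <- c("condition", "oocyte_id", "condensate_id", "t",
                 "w_iu", "a_iu", "area_um2")

#' Read and write condensate track tables
#'
#' The on-disk dialect is TSV with a fixed lowercase header
#' `condition  oocyte_id  condensate_id  t  w_iu  a_iu  area_um2`
#' (UTF-8, `.` decimal separator; `area_um2` may be empty). Times are
#' seconds, intensities integrated intensity units (IU, background already
#' subtracted), areas µm². `read_tracks()` validates the invariants —
#' nonnegative finite intensities, unique `(condition, oocyte_id,
#' condensate_id, t)` keys, per-condensate times sorted with constant
#' spacing within 1% — and reports offending data line numbers.
#' Write-then-read round-trips are lossless at double precision.
#'
#' @param path file path.
#' @return `read_tracks()`: a `data.table` in track-table format.
#' @export
read_tracks <- function(path) {
  hdr <- names(fread(path, sep = "\t", header = TRUE, nrows = 0L))
  missing_cols <- setdiff(setdiff(.track_cols, "area_um2"), hdr)
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("condition", "oocyte_id", "condensate_id")))
  if (!"area_um2" %in% names(dt)) dt[, area_um2 := NA_real_]
  if (!nrow(dt)) {
    warning("empty track file (header only)", call. = FALSE)
    return(dt[])
  }
  dt[, line := .I + 1L] # data line numbers in the file (1 = header)
  bad <- dt[!is.finite(t) | t < 0 | !is.finite(w_iu) | w_iu < 0 |
              !is.finite(a_iu) | a_iu < 0]
  if (nrow(bad)) {
    stop(sprintf("invalid (negative or nonfinite) values at line(s): %s",
                 paste(utils::head(bad$line, 5), collapse = ", ")),
         call. = FALSE)
  }
  dup <- dt[duplicated(dt, by = c("condition", "oocyte_id", "condensate_id", "t"))]
  if (nrow(dup)) {
    stop(sprintf("duplicate (condition, oocyte, condensate, t) key at line(s): %s",
                 paste(utils::head(dup$line, 5), collapse = ", ")),
         call. = FALSE)
  }
  chk <- dt[, {
    if (.N >= 2) {
      sp <- diff(t)
      md <- median(sp)
      list(bad_line = if (any(sp <= 0) || any(abs(sp - md) > 0.01 * md))
        line[1] else NA_integer_)
    } else list(bad_line = NA_integer_)
  }, by = .(condition, oocyte_id, condensate_id)]
  if (any(!is.na(chk$bad_line))) {
    stop(sprintf("unsorted or irregular times within condensate starting at line(s): %s",
                 paste(utils::head(chk$bad_line[!is.na(chk$bad_line)], 5),
                       collapse = ", ")), call. = FALSE)
  }
  dt[, line := NULL]
  dt[]
}

#' @rdname read_tracks
#' @param tracks a track table.
#' @return `write_tracks()`: the path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  dt <- as.data.table(tracks)
  missing_cols <- setdiff(setdiff(.track_cols, "area_um2"), names(dt))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"area_um2" %in% names(dt)) dt[, area_um2 := NA_real_]
  fwrite(dt[, .SD, .SDcols = .track_cols], path, sep = "\t", na = "",
         quote = FALSE)
  invisible(path)
}

#' Condensate lifetime distribution
#'
#' Lifetime is the last minus the first observed frame time of each track.
#' Tracks whose last frame reaches the observation horizon (within one
#' frame spacing) are censored — they did not dissolve within the window —
#' and are flagged separately, as happens for unbounded-growth conditions.
#'
#' @param tracks a track table.
#' @param bin_width histogram bin width (s).
#' @param horizon observation-window end time (s); `NULL` disables
#'   censoring detection.
#' @return A list with `lifetimes` (per-condensate `data.table` including
#'   a `censored` flag), `histogram` (`mids`, `counts`, `density`), `mean`,
#'   `median` (dissolved tracks only), `n`, `n_censored`.
#' @export
lifetime_distribution <- function(tracks, bin_width = 1, horizon = NULL) {
  dt <- as.data.table(tracks)
  stopifnot(all(c("condensate_id", "t") %in% names(dt)))
  lt <- dt[, .(lifetime = max(t) - min(t), t_last = max(t),
               spacing = if (.N >= 2) median(diff(sort(t))) else NA_real_),
           by = .(condition, oocyte_id, condensate_id)]
  lt[, censored := if (is.null(horizon)) FALSE else
    t_last >= horizon - pmax(spacing, 0, na.rm = TRUE)]
  diss <- lt[censored == FALSE]
  breaks <- seq(0, max(lt$lifetime) + bin_width, by = bin_width)
  h <- graphics::hist(lt$lifetime, breaks = breaks, plot = FALSE)
  list(lifetimes = lt[], histogram = list(mids = h$mids, counts = h$counts,
                                          density = h$density),
       mean = if (nrow(diss)) mean(diss$lifetime) else NA_real_,
       median = if (nrow(diss)) median(diss$lifetime) else NA_real_,
       n = nrow(lt), n_censored = sum(lt$censored))
}

#' Classify knockdown strength from condensate counts
#'
#' The strength of ARP2/3 knockdown is read from the number of dynamic
#' condensates per oocyte: 30–70 is mild, 70–120 moderate (the boundary 70
#' counts as moderate), zero is strong (no dynamic condensates), anything
#' else control-like. Note the counting intervals are taken exactly as
#' reported even though mild corresponds to *fewer* condensates than
#' moderate.
#'
#' @param count nonnegative integer condensate count(s) per oocyte.
#' @param mild,moderate interval bounds `c(lo, hi)` for the two classes.
#' @return Character vector of labels.
#' @examples
#' classify_rnai_strength(c(0, 50, 100, 300))
#' @export
classify_rnai_strength <- function(count, mild = c(30, 70),
                                   moderate = c(70, 120)) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  ifelse(count == 0, "strong",
         ifelse(count >= moderate[1] & count <= moderate[2], "moderate",
                ifelse(count >= mild[1] & count < mild[2], "mild",
                       "control-like")))
}

#' Convert WSP-1 intensity to molecule counts
#'
#' Uses the intensity calibration 8 IU = 100 WSP-1 molecules, i.e. 12.5
#' molecules per IU by default.
#'
#' @param intensity WSP-1 intensity (IU, >= 0).
#' @param molecules_per_iu calibration constant.
#' @return Molecule counts.
#' @examples
#' wsp1_molecules(8) # 100
#' @export
wsp1_molecules <- function(intensity, molecules_per_iu = 12.5) {
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensity must be finite and nonnegative", call. = FALSE)
  }
  intensity * molecules_per_iu
}

#' Read a pipeline configuration file
#'
#' YAML with flat sections `generator` (fields of [generator_config()];
#' kinetic and volume coefficients as flat keys `k_r`, `k_l`, `k_b`,
#' `k_d`, `v_A`, `v_W`; optional `preset` naming an [rnai_preset()]),
#' `model`, `fitting` and `io`.
#'
#' @param path YAML file path.
#' @return A named list of sections.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("generator", "model", "fitting", "io")) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- list()
  }
  cfg
}

.config_generator <- function(cfg) {
  g <- cfg$generator
  vol <- volume_coefficients(
    v_A = g$v_A %||% 1.54e-7, v_W = g$v_W %||% 2.34e-7)
  params <- if (!is.null(g$preset)) {
    rnai_preset(g$preset, vol = vol)
  } else {
    kinetic_params(k_r = g$k_r %||% 0.1, k_l = g$k_l %||% 1.9529e-8,
                   k_b = g$k_b %||% 2.43e-7, k_d = g$k_d %||% 0.15)
  }
  generator_config(
    params = params, vol = vol,
    nucleation_rate = g$nucleation_rate %||% 7,
    seed_W_median = g$seed_W_median %||% 3,
    seed_W_sdlog = g$seed_W_sdlog %||% 0.5,
    seed_A = g$seed_A %||% 0.2,
    frame_interval = g$frame_interval %||% 0.5,
    duration = g$duration %||% 600,
    intrinsic_noise_sd = g$intrinsic_noise_sd %||% 0.1,
    obs_noise_sd = g$obs_noise_sd %||% 0.05,
    detection_threshold = g$detection_threshold %||% 1,
    rng_seed = g$rng_seed %||% 1L,
    substeps = g$substeps %||% 10L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.kv_report <- function(x, path) {
  lines <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    sprintf("%s\t%s", nm, paste(format(v, digits = 15), collapse = "\t"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (unless `io$tracks` names an existing input file) ->
#' fit-volume -> portrait -> fit-kinetics -> optional comparison against a
#' second configured condition -> report. Every stage logs its inputs,
#' seed and row counts; all outputs are written under `out_dir` (track
#' TSV, ground-truth sidecar, flux-field and growth-curve TSVs, key-value
#' fit reports and a machine-readable `summary.json`). With a fixed seed
#' the numeric outputs are identical across runs.
#'
#' @param config a config list (see [read_pipeline_config()]) or the path
#'   to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the generator seed.
#' @param quiet suppress progress messages.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (sec in c("generator", "model", "fitting", "io")) {
    if (is.null(config[[sec]])) config[[sec]] <- list()
  }
  if (!is.null(seed)) config$generator$rng_seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message(sprintf(...))
  summary <- list(stages = character(0))

  gc_cfg <- .config_generator(config)
  summary$seed <- gc_cfg$rng_seed
  summary$params <- unclass(gc_cfg$params)
  summary$vol <- unclass(gc_cfg$vol)
  summary$regime_configured <- classify_regime(gc_cfg$params, gc_cfg$vol)

  # --- simulate or load -----------------------------------------------------
  tracks_in <- config$io$tracks
  if (!is.null(tracks_in) && file.exists(tracks_in)) {
    log("[load] reading tracks from %s", tracks_in)
    tracks <- read_tracks(tracks_in)
  } else {
    n <- config$generator$n_condensates
    log("[simulate] seed %d, duration %g s, %s condensates",
        gc_cfg$rng_seed, gc_cfg$duration,
        if (is.null(n)) "Poisson" else as.character(n))
    ens <- generate_ensemble(gc_cfg, n_condensates = n,
                             condition = config$generator$condition %||% "control")
    tracks <- ens$tracks
    write_ensemble(ens, file.path(out_dir, "tracks.tsv"),
                   file.path(out_dir, "ground_truth.yaml"))
    summary$stages <- c(summary$stages, "simulate")
  }
  n_tracks <- length(unique(tracks$condensate_id))
  log("[tracks] %d condensates, %d frames", n_tracks, nrow(tracks))
  summary$n_condensates <- n_tracks
  summary$n_frames <- nrow(tracks)
  summary$rnai_class <- classify_rnai_strength(n_tracks)

  # --- volume fit -----------------------------------------------------------
  window <- config$model$stoich_window %||% c(0.65, 0.93)
  vm <- tryCatch(
    fit_volume_coefficients(tracks, window = window,
                            n_boot = config$fitting$n_boot %||% 200),
    error = function(e) {
      log("[fit-volume] skipped: %s", conditionMessage(e)); NULL
    })
  if (!is.null(vm)) {
    .kv_report(list(v_A = vm$coefficients$v_A, v_W = vm$coefficients$v_W,
                    se_v_A = vm$se["v_A"], se_v_W = vm$se["v_W"],
                    window = vm$window, n_points = vm$n_points),
               file.path(out_dir, "volume_fit.tsv"))
    summary$volume_fit <- list(v_A = vm$coefficients$v_A,
                               v_W = vm$coefficients$v_W)
    summary$stages <- c(summary$stages, "fit-volume")
  }
  vol_use <- if (!is.null(vm) && inherits(vm$coefficients, "volume_coefficients"))
    vm$coefficients else gc_cfg$vol

  # --- portrait -------------------------------------------------------------
  pts <- estimate_derivatives(tracks)
  field <- bin_vector_field(pts, n_bins = config$model$n_bins %||% 24,
                            min_count = config$model$min_count %||% 20)
  fwrite(field$bins, file.path(out_dir, "flux_field.tsv"), sep = "\t")
  ncs <- list()
  for (comp in c("W", "A")) {
    ncs[[comp]] <- tryCatch(extract_nullcline(field, comp),
                            error = function(e) {
                              log("[portrait] %s nullcline: %s", comp,
                                  conditionMessage(e))
                              NULL
                            })
  }
  nc_tab <- data.table(
    component = c("W", "A"),
    stoichiometry = vapply(ncs, function(x)
      if (is.null(x)) NA_real_ else x$stoichiometry, numeric(1)),
    se = vapply(ncs, function(x)
      if (is.null(x)) NA_real_ else x$se, numeric(1)))
  fwrite(nc_tab, file.path(out_dir, "nullclines.tsv"), sep = "\t")
  gcur <- growth_vs_stoichiometry(pts)
  fwrite(gcur$curves, file.path(out_dir, "growth_vs_stoichiometry.tsv"),
         sep = "\t")
  summary$empirical_nullclines <- list(
    s_W = nc_tab$stoichiometry[1], s_A = nc_tab$stoichiometry[2])
  summary$stages <- c(summary$stages, "portrait")
  log("[portrait] %d rate points; nullclines s_W = %s, s_A = %s",
      nrow(pts), format(nc_tab$stoichiometry[1], digits = 4),
      format(nc_tab$stoichiometry[2], digits = 4))

  # --- kinetics -------------------------------------------------------------
  fit <- tryCatch(
    fit_kinetics(pts, vol_use, window_s = window,
                 n_boot = config$fitting$n_boot %||% 200),
    error = function(e) {
      log("[fit-kinetics] skipped: %s", conditionMessage(e)); NULL
    })
  if (!is.null(fit)) {
    .kv_report(c(as.list(setNames(
      vapply(c("k_r", "k_l", "k_b", "k_d"), function(k) fit$params[[k]],
             numeric(1)), c("k_r", "k_l", "k_b", "k_d"))),
      list(r2_w = fit$r2["w"], r2_a = fit$r2["a"], n_points = fit$n_points)),
      file.path(out_dir, "kinetic_fit.tsv"))
    summary$kinetics <- setNames(lapply(c("k_r", "k_l", "k_b", "k_d"),
                                        function(k) fit$params[[k]]),
                                 c("k_r", "k_l", "k_b", "k_d"))
    summary$regime_fitted <- tryCatch(
      classify_regime(as_kinetic_params(fit$params), vol_use),
      error = function(e) NA_character_)
    summary$critical_kd <- tryCatch(
      critical_kd(as_kinetic_params(fit$params), vol_use),
      error = function(e) NA_real_)
    summary$stages <- c(summary$stages, "fit-kinetics")
    log("[fit-kinetics] regime (fitted) = %s", summary$regime_fitted)
  }

  # --- lifetimes ------------------------------------------------------------
  lif <- lifetime_distribution(tracks,
                               horizon = gc_cfg$duration)
  summary$lifetime_mean <- lif$mean
  summary$lifetime_median <- lif$median
  summary$n_censored <- lif$n_censored

  # --- report ---------------------------------------------------------------
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  summary$stages <- c(summary$stages, "report")
  log("[report] written to %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}
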