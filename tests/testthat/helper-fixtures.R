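# Shared fixtures, memoised per test session. The heavy ensembles are
# generated once and reused across test files.

library(data.table)

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

canonical_params <- function() kinetic_params()
paper_vol <- function() volume_coefficients()

# the reference noisy ensemble: canonical coefficients, observation-process
# defaults (0.5 s frames, 600 s window, intrinsic sd 0.1, observation sd
# 0.05), 2000 condensates
big_noisy_ensemble <- function() {
  memo("big_noisy", {
    cfg <- generator_config(rng_seed = 42L)
    generate_ensemble(cfg, n_condensates = 2000)
  })
}

big_noisy_points <- function() {
  memo("big_noisy_pts", estimate_derivatives(big_noisy_ensemble()$tracks))
}

big_noisy_field <- function() {
  memo("big_noisy_field", bin_vector_field(big_noisy_points()))
}

# noise-free ensemble at fine frame interval: isolates finite-difference
# bias for the exact-recovery checks
noise_free_ensemble <- function() {
  memo("noise_free", {
    cfg <- generator_config(intrinsic_noise_sd = 0, obs_noise_sd = 0,
                            frame_interval = 0.05, duration = 60,
                            rng_seed = 5L)
    generate_ensemble(cfg, n_condensates = 150, nucleation_window = 1)
  })
}

noise_free_points <- function() {
  memo("noise_free_pts", estimate_derivatives(noise_free_ensemble()$tracks))
}

# exact rate points sampled from the vector field itself (no tracks):
# states across stoichiometries at several overall scales
exact_rate_points <- function(params = kinetic_params(),
                              vol = volume_coefficients(),
                              s_grid = seq(0.3, 0.95, by = 0.005),
                              scales = c(5, 50, 500)) {
  grid <- expand.grid(s = s_grid, m = scales)
  a <- grid$s * grid$m
  w <- (1 - grid$s) * grid$m
  r <- growth_rates(a, w, params, vol)
  data.table::data.table(
    condition = "exact", oocyte_id = "oo1",
    condensate_id = sprintf("x%04d", seq_along(a)),
    t = 0, a_iu = a, w_iu = w, dw = r$dW, da = r$dA)
}
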