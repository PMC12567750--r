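# Shared fixtures. Heavy simulations are memoized so several test files can
# reuse the same tallies without re-running the engine.

.cache <- new.env(parent = emptyenv())

# single-medium optical property set (all tissue layers identical)
uniform_props <- function(mu_a, mu_s, g, n, n_void = 1) {
  p <- list(mu_a = mu_a, mu_s = mu_s, g = g, n = n)
  list(void = list(mu_a = 0, mu_s = 0, g = 0, n = n_void),
       scalp_muscle = p, cranium = p, csf = p, brain = p)
}

# reference head #1 run shared by transport, SAD and tally tests
ref_sim <- function() {
  if (is.null(.cache$ref_sim)) {
    ph <- build_phantom(8, 6.8, 5.55)
    .cache$ref_sim <- run_simulation(ph, sds = 29, n_photons = 1e5, seed = 7)
  }
  .cache$ref_sim
}

# the full desk-scale calibration pipeline (8 heads x 11 separations at
# 1e5 photons); computed once and shared by the acceptance tests
desk_pipeline <- function() {
  if (is.null(.cache$pipeline)) {
    .cache$pipeline <- run_calibration_pipeline(n_photons = 1e5, seed = 1,
                                                verbose = FALSE)
  }
  .cache$pipeline
}

# deterministic smooth SAD surface used for surrogate recovery tests
smooth_surface_data <- function(sds = seq(19, 39, by = 2), depths = 10:20) {
  gr <- expand.grid(sds = sds, depth = depths)
  gr$sad <- 0.01 * gr$sds * (20 - gr$depth)
  gr
}

# synthetic mean profiles following a known closed form, for dataset tests
synthetic_mean_profiles <- function(sds = seq(19, 39, by = 2),
                                    f = function(s, z) 0.01 * s * (20 - z)) {
  lapply(sds, function(s) {
    out <- data.frame(depth_mm = 0:63, sad_pct = pmax(0, f(s, 0:63)))
    attr(out, "head") <- "mean"
    attr(out, "sds") <- s
    class(out) <- c("sad_profile", "data.frame")
    out
  })
}
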