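# Shared fixtures: built in code, deterministic under fixed seeds.

# A small but complete synthetic experiment reused across test files.
default_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_experiment(synthetic_config(seed = 7))
    cache
  }
})

# Noise-free configuration: deterministic ln-linear structure everywhere.
noiseless_config <- function(seed = 1) {
  cfg <- synthetic_config(seed = seed)
  cfg$temp_model$weekly_noise_sd <- 0
  cfg$chla_model$var_group <- 0
  cfg$chla_model$var_resid <- 0
  cfg$flux_model$nep$var_group <- 0
  cfg$flux_model$nep$var_resid <- 0
  cfg$flux_model$er$var_group <- 0
  cfg$flux_model$er$var_resid <- 0
  cfg$missing_diel <- 0
  cfg
}

# Hand-built design table with known structure for LMM unit tests.
toy_design <- function(n_groups = 8, n_per = 6, beta = c(1, 0.5, -0.25),
                       sd_group = 0.3, sd_resid = 0.2, seed = 99) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", seq_len(n_groups)), each = n_per)
  xw <- stats::rnorm(n_groups * n_per)
  xb <- rep(stats::rnorm(n_groups), each = n_per)
  u <- rep(stats::rnorm(n_groups, 0, sd_group), each = n_per)
  y <- beta[1] + beta[2] * xw + beta[3] * xb + u +
    stats::rnorm(n_groups * n_per, 0, sd_resid)
  data.frame(y = y, inv_kT_within = xw, inv_kT_between = xb, tank_id = g,
             stringsAsFactors = FALSE)
}
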