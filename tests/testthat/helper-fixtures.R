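# shared fixtures, all built in code

# two-component length sample with known truth
two_component_sample <- function(n = 300, w = c(0.6, 0.4), mu = c(70, 120),
                                 sd = c(8, 12), seed = 7) {
  sample_mixture_lengths(n, w, mu, sd, seed = seed)
}

# deterministic hatch-to-October temperature series (no noise)
october_temps <- function() {
  cfg <- scenario_config(temp_noise_sd = 0)
  td <- generate_temperature(cfg, "S1", 2000)
  td$temp_C[td$date <= as.Date("2000-10-15")]
}

# annual inputs with known transition truth; adults forward-computed
make_cohort_inputs <- function(q = c(1.178, 0.594), n_years = 18,
                               noise_sd = 0, seed = 1,
                               J_range = c(100, 3000),
                               C_range = c(50, 1500)) {
  withr::with_seed(seed, {
    years <- seq(2000, length.out = n_years)
    Js <- runif(n_years, J_range[1], J_range[2])
    Cs <- runif(n_years, C_range[1], C_range[2])
    split <- c(0.53, 0.47)
    A <- rep(NA_real_, n_years)
    for (i in 3:n_years) {
      A[i] <- q[1] * (split[1] * Js[i - 1] + split[2] * Js[i - 2]) +
        q[2] * (split[1] * Cs[i - 1] + split[2] * Cs[i - 2])
    }
    if (noise_sd > 0) A[3:n_years] <- A[3:n_years] +
        rnorm(n_years - 2, 0, noise_sd)
    A[1:2] <- 400
    cohort_inputs(years, A, Js, Cs, Js, Cs)
  })
}
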