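#' Scenario configuration for the synthetic monitoring-data generator
#'
#' Defines the study conditions of a simulated steelhead monitoring
#' program: an October electrofishing survey at a ladder of sites, daily
#' water temperatures, and annual series of adult counts, captive releases,
#' translocations and end-of-summer streamflow. Defaults emulate the
#' observed structure of a long-term coastal-California program: mean YOY
#' density 1.96 fish per metre of channel, 77% of juveniles young-of-year,
#' annual CV 46% and spatial CV 28% of YOY density, a 40 km expansion
#' channel, and adult returns split 53%/47% between one and two ocean
#' years.
#'
#' @param years inclusive survey year range.
#' @param sites ordered site identifiers (downstream to upstream).
#' @param channel_length_m expansion length (upper dam to estuary), metres.
#' @param site_length_m surveyed reach length per site, metres.
#' @param seed integer master seed; every draw is derived from it.
#' @param yoy_density_mean mean YOY density, fish per metre.
#' @param yoy_fraction proportion of the sample that is YOY, in (0, 1].
#' @param annual_cv,spatial_cv coefficients of variation of YOY density
#'   across years and across sites (>= 0).
#' @param capture_prob per-pass electrofishing capture probability, (0, 1].
#' @param n_passes removal passes per site (2 or 3).
#' @param temp_mean,temp_amplitude,temp_noise_sd sinusoidal daily
#'   temperature model, degrees C (annual peak in early August).
#' @param true_growth list: `beta` (competition asymmetry, mm^-1),
#'   `eta_mean` (median food availability), `eta_sdlog` (lognormal sd of
#'   year-to-year food variation), `eta_trend` (additive trend in log
#'   eta_H per year, 0 for none).
#' @param lifecycle_truth generating adult model, `"size_conditional"`
#'   (default) or `"fixed_rate"`.
#' @param true_transitions named pair of generating transition rates;
#'   defaults to `c(q3 = 1.178, q4 = 0.594)` under size-conditional truth
#'   and `c(q1 = 0.0076, q2 = 0.004)` under fixed-rate truth.
#' @param ocean_age_split proportions returning after 1 and 2 ocean years.
#' @param adult_noise_sd sd of additive Gaussian observation noise on adult
#'   counts (truncated at zero).
#' @param initial_adults adult counts for the first two years (no lags
#'   available there).
#' @param older_ages list describing the age-1 and age-2+ mixture
#'   components: `split` (shares of the non-YOY fraction), `means`, `sds`
#'   (mm).
#' @param translocation_rule list `mean`, `cv` for annual translocated
#'   counts (lognormal).
#' @param captive_rule list `count_mean`, `count_cv`, `length_start`,
#'   `length_end` (release-length mean ramps linearly across the study,
#'   emulating a change in rearing practice), `length_sd`, `n_measured`.
#' @param flow_rule list `meanlog`, `sdlog` for end-of-summer flow
#'   (ft^3 s^-1, lognormal).
#' @param smolt,survival smolting and marine-survival curve parameters.
#' @param truth_cohort_n fish per site-year in the generating growth
#'   simulation.
#' @param g_max maximum specific growth rate of the growth kernel, per day.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(
    years = 1996:2013,
    sites = sprintf("S%d", 1:9),
    channel_length_m = 40000,
    site_length_m = 100,
    seed = 1,
    yoy_density_mean = 1.96,
    yoy_fraction = 0.77,
    annual_cv = 0.46,
    spatial_cv = 0.28,
    capture_prob = 0.6,
    n_passes = 3,
    temp_mean = 14, temp_amplitude = 6, temp_noise_sd = 0.5,
    true_growth = list(beta = 0.04, eta_mean = 3.0, eta_sdlog = 0.15,
                       eta_trend = 0),
    lifecycle_truth = c("size_conditional", "fixed_rate"),
    true_transitions = NULL,
    ocean_age_split = c(0.53, 0.47),
    adult_noise_sd = 25,
    initial_adults = c(400, 400),
    older_ages = list(split = c(0.78, 0.22), means = c(130, 180),
                      sds = c(14, 18)),
    translocation_rule = list(mean = 15000, cv = 0.4),
    captive_rule = list(count_mean = 12000, count_cv = 0.3,
                        length_start = 110, length_end = 185,
                        length_sd = 15, n_measured = 100),
    flow_rule = list(meanlog = log(8), sdlog = 0.5),
    smolt = smolt_params(), survival = survival_params(),
    truth_cohort_n = 200,
    g_max = 0.025) {
  lifecycle_truth <- match.arg(lifecycle_truth)
  if (is.null(true_transitions)) {
    true_transitions <- if (lifecycle_truth == "size_conditional") {
      c(q3 = 1.178, q4 = 0.594)
    } else {
      c(q1 = 0.0076, q2 = 0.004)
    }
  }
  cfg <- list(years = years, sites = sites,
              channel_length_m = channel_length_m,
              site_length_m = site_length_m, seed = as.integer(seed),
              yoy_density_mean = yoy_density_mean,
              yoy_fraction = yoy_fraction,
              annual_cv = annual_cv, spatial_cv = spatial_cv,
              capture_prob = capture_prob, n_passes = n_passes,
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_noise_sd = temp_noise_sd,
              true_growth = true_growth,
              lifecycle_truth = lifecycle_truth,
              true_transitions = true_transitions,
              ocean_age_split = ocean_age_split,
              adult_noise_sd = adult_noise_sd,
              initial_adults = initial_adults,
              older_ages = older_ages,
              translocation_rule = translocation_rule,
              captive_rule = captive_rule,
              flow_rule = flow_rule,
              smolt = smolt, survival = survival,
              truth_cohort_n = truth_cohort_n,
              g_max = g_max)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  stopifnot(
    length(cfg$years) >= 1, length(cfg$sites) >= 1,
    cfg$channel_length_m > 0, cfg$site_length_m > 0,
    cfg$yoy_fraction > 0, cfg$yoy_fraction <= 1,
    cfg$capture_prob > 0, cfg$capture_prob <= 1,
    cfg$annual_cv >= 0, cfg$spatial_cv >= 0,
    cfg$n_passes %in% c(2, 3),
    abs(sum(cfg$ocean_age_split) - 1) < 1e-8,
    cfg$adult_noise_sd >= 0,
    cfg$true_growth$beta >= 0, cfg$true_growth$eta_mean > 0
  )
  invisible(cfg)
}

# deterministic sub-seed from the master seed and a stream label
derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# key dates of the cohort year: hatch 1 May, October survey 15 Oct,
# smolt window 1 April of the following year
cohort_dates <- function(year) {
  list(hatch = as.Date(sprintf("%d-05-01", year)),
       survey = as.Date(sprintf("%d-10-15", year)),
       april = as.Date(sprintf("%d-04-01", year + 1)))
}

#' Generate a daily water-temperature series for one site-year
#'
#' Sinusoidal annual cycle with Gaussian noise,
#' `T(d) = mean + amplitude * sin(2 pi (doy - 121.75) / 365) + eps`,
#' peaking in early August, over the cohort window from hatch (1 May) to
#' 1 April of the following year.
#'
#' @param cfg a [scenario_config()].
#' @param site,year site identifier and cohort year.
#' @return data.frame with `site`, `year`, `date`, `temp_C`.
#' @export
generate_temperature <- function(cfg, site, year) {
  d <- cohort_dates(year)
  dates <- seq(d$hatch, d$april, by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  temp <- cfg$temp_mean +
    cfg$temp_amplitude * sin(2 * pi * (doy - 121.75) / 365)
  if (cfg$temp_noise_sd > 0) {
    local_rng({
      set.seed(derive_seed(cfg$seed, "temp", site, year))
      temp <- temp + stats::rnorm(length(temp), 0, cfg$temp_noise_sd)
    })
  }
  data.frame(site = site, year = year, date = dates, temp_C = temp)
}

#' Sample fish lengths from a normal mixture
#'
#' @param n number of fish.
#' @param weights component weights (sum 1).
#' @param means,sds component parameters, mm.
#' @param seed RNG seed (global state preserved).
#' @return list with `lengths_mm` and `component` (true labels).
#' @export
sample_mixture_lengths <- function(n, weights, means, sds, seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-8,
            length(weights) == length(means),
            length(means) == length(sds))
  comp <- lengths <- NULL
  local_rng({
    set.seed(seed)
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    lengths <- stats::rnorm(n, means[comp], sds[comp])
  })
  lengths <- pmax(lengths, 5)
  list(lengths_mm = lengths, component = comp)
}

#' Generate sequential removal-pass counts
#'
#' Binomial removals with equal per-pass capture probability: each pass
#' captures `Binomial(remaining, p)` fish.
#'
#' @param true_N fish present (>= 0).
#' @param capture_prob per-pass capture probability, (0, 1].
#' @param n_passes 2 or 3.
#' @param seed RNG seed.
#' @return integer vector of per-pass catches (sums to <= `true_N`), with
#'   attribute `remaining`.
#' @export
generate_depletion_passes <- function(true_N, capture_prob, n_passes = 3,
                                      seed = 1) {
  stopifnot(true_N >= 0, n_passes %in% c(2, 3))
  if (capture_prob <= 0 || capture_prob > 1) {
    stop("capture_prob must be in (0, 1]")
  }
  counts <- integer(n_passes)
  remaining <- true_N
  local_rng({
    set.seed(seed)
    for (i in seq_len(n_passes)) {
      counts[i] <- stats::rbinom(1, remaining, capture_prob)
      remaining <- remaining - counts[i]
    }
  })
  attr(counts, "remaining") <- remaining
  counts
}

# -- per-site-year generating truth -----------------------------------------

# lognormal multiplier with mean 1 and the given CV
ln_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# density and food-availability truth for all site-years; deterministic in cfg
scenario_truth_grid <- function(cfg) {
  ny <- length(cfg$years)
  ns <- length(cfg$sites)
  year_f <- site_f <- eta <- NULL
  local_rng({
    set.seed(derive_seed(cfg$seed, "grid"))
    year_f <- ln_factor(ny, cfg$annual_cv)
    site_f <- matrix(ln_factor(ny * ns, cfg$spatial_cv), ns, ny)
    meanlog <- log(cfg$true_growth$eta_mean) +
      cfg$true_growth$eta_trend * (seq_len(ny) - 1)
    eta_year <- stats::rlnorm(ny, meanlog, cfg$true_growth$eta_sdlog)
    eta <- matrix(rep(eta_year, each = ns), ns, ny) *
      matrix(stats::rlnorm(ns * ny, 0, cfg$true_growth$eta_sdlog / 2), ns, ny)
  })
  list(density = cfg$yoy_density_mean * sweep(site_f, 2, year_f, "*"),
       eta = eta)
}

# generating growth truth for one site-year: October mean/sd of the YOY
# component and the 1 April length distribution
site_year_growth_truth <- function(cfg, site, year, eta) {
  d <- cohort_dates(year)
  temps <- generate_temperature(cfg, site, year)
  to_oct <- temps$temp_C[temps$date <= d$survey]
  to_apr <- temps$temp_C[temps$date > d$survey]
  init <- NULL
  local_rng({
    set.seed(derive_seed(cfg$seed, "cohort", site, year))
    init <- stats::rnorm(cfg$truth_cohort_n, 28, 2)
  })
  oct <- sim_growth_core(pmax(init, 5), to_oct, cfg$true_growth$beta, eta,
                         cfg$g_max)
  apr <- sim_growth_core(oct, to_apr, cfg$true_growth$beta, eta, cfg$g_max)
  list(oct_mean = mean(oct), oct_sd = stats::sd(oct), april_lengths = apr,
       temps = temps)
}

#' Generate the October length sample for one site-year
#'
#' Fish lengths are drawn from a K-component normal mixture: the YOY
#' component (weight `yoy_fraction`) has the October mean and sd produced
#' by the generating growth simulation at the site-year's true (beta,
#' eta_H); the age-1 and age-2+ components follow `cfg$older_ages`. The
#' sample size is the site's true fish count, `round(density * site_length
#' / yoy_fraction)`.
#'
#' @param cfg a [scenario_config()].
#' @param site,year site identifier and cohort year.
#' @return list of class `length_sample`: `site`, `year`, `lengths_mm`,
#'   `component` (true age labels), `truth` (generating parameters). A
#'   zero target density yields an empty sample with a warning.
#' @export
generate_site_year_lengths <- function(cfg, site, year) {
  grid <- scenario_truth_grid(cfg)
  si <- match(site, cfg$sites)
  yi <- match(year, cfg$years)
  stopifnot(!is.na(si), !is.na(yi))
  density <- grid$density[si, yi]
  gt <- site_year_growth_truth(cfg, site, year, grid$eta[si, yi])
  site_year_sample(cfg, site, year, density, gt)
}

site_year_sample <- function(cfg, site, year, density, growth_truth) {
  n <- round(density * cfg$site_length_m / cfg$yoy_fraction)
  mix <- mixture_truth(cfg, growth_truth)
  if (n == 0) {
    warning("zero target density at ", site, " ", year, ": empty sample")
    return(structure(list(site = site, year = year, lengths_mm = numeric(0),
                          component = integer(0),
                          truth = c(mix, density = density)),
                     class = "length_sample"))
  }
  s <- sample_mixture_lengths(n, mix$weights, mix$means, mix$sds,
                              seed = derive_seed(cfg$seed, "lengths", site,
                                                 year))
  structure(list(site = site, year = year, lengths_mm = s$lengths_mm,
                 component = s$component,
                 truth = c(mix, density = density)),
            class = "length_sample")
}

mixture_truth <- function(cfg, growth_truth) {
  if (cfg$yoy_fraction >= 1) {
    list(weights = 1, means = growth_truth$oct_mean,
         sds = growth_truth$oct_sd)
  } else {
    ow <- (1 - cfg$yoy_fraction) * cfg$older_ages$split
    list(weights = c(cfg$yoy_fraction, ow),
         means = c(growth_truth$oct_mean, cfg$older_ages$means),
         sds = c(growth_truth$oct_sd, cfg$older_ages$sds))
  }
}

#' Simulate a complete synthetic monitoring dataset
#'
#' Generates every table a monitoring program would supply, with full
#' generating truth recorded: the October survey (individual lengths with
#' pass labels from binomial removals), daily site temperatures, the
#' annual series (adults, captive releases, translocations, flow) and the
#' captive release-length samples. Adult counts are forward-simulated from
#' the configured life-cycle truth: under size-conditional truth,
#' `A_t = q3 (0.53 J*_{t-1} + 0.47 J*_{t-2}) + q4 (0.53 C*_{t-1} + 0.47
#' C*_{t-2}) + noise` (truncated at zero), with the smolt-equivalents J*,
#' C* computed from the true 1 April length distributions; under
#' fixed-rate truth the raw abundances J, C replace the starred
#' predictors. The first two years of adults are seeded from the config.
#' Regeneration with the same seed is bit-identical.
#'
#' @param cfg a [scenario_config()].
#' @return object of class `steelhead_scenario`: data.frames `survey`
#'   (site, year, pass, length_mm), `temperature` (site, year, date,
#'   temp_C), `annual` (year, adults, captives_released, translocated,
#'   flow_cfs), `captive_lengths` (year, length_mm), and `truth` (config
#'   plus every generating quantity).
#' @export
simulate_scenario <- function(cfg) {
  validate_scenario_config(cfg)
  years <- cfg$years
  ny <- length(years)
  grid <- scenario_truth_grid(cfg)

  survey <- list()
  temperature <- list()
  april_by_year <- vector("list", ny)
  site_truth <- list()

  for (yi in seq_len(ny)) {
    year <- years[yi]
    april_pool <- list()
    for (si in seq_along(cfg$sites)) {
      site <- cfg$sites[si]
      gt <- site_year_growth_truth(cfg, site, year, grid$eta[si, yi])
      temperature[[length(temperature) + 1]] <- gt$temps
      samp <- site_year_sample(cfg, site, year, grid$density[si, yi], gt)
      n <- length(samp$lengths_mm)
      if (n > 0) {
        caps <- depletion_capture(samp$lengths_mm, cfg$capture_prob,
                                  cfg$n_passes,
                                  derive_seed(cfg$seed, "passes", site, year))
        if (nrow(caps) > 0) {
          caps$site <- site; caps$year <- year
          survey[[length(survey) + 1]] <- caps
        }
      }
      april_pool[[si]] <- gt$april_lengths
      site_truth[[length(site_truth) + 1]] <- data.frame(
        site = site, year = year, density = grid$density[si, yi],
        eta_H = grid$eta[si, yi], beta = cfg$true_growth$beta,
        oct_mean = gt$oct_mean, oct_sd = gt$oct_sd,
        april_mean = mean(gt$april_lengths),
        n_fish = n)
    }
    april_by_year[[yi]] <- unlist(april_pool)
  }

  # annual covariates and captive program
  R_t <- flow <- C_t <- NULL
  captive_lengths <- list()
  local_rng({
    set.seed(derive_seed(cfg$seed, "annual"))
    tr <- cfg$translocation_rule
    R_t <- round(cfg$translocation_rule$mean * ln_factor(ny, tr$cv))
    flow <- stats::rlnorm(ny, cfg$flow_rule$meanlog, cfg$flow_rule$sdlog)
    cr <- cfg$captive_rule
    C_t <- round(cr$count_mean * ln_factor(ny, cr$count_cv))
    ramp <- if (ny == 1) 0 else (seq_len(ny) - 1) / (ny - 1)
    for (yi in seq_len(ny)) {
      mu <- cr$length_start + ramp[yi] * (cr$length_end - cr$length_start)
      captive_lengths[[yi]] <- data.frame(
        year = years[yi],
        length_mm = pmax(stats::rnorm(cr$n_measured, mu, cr$length_sd), 20))
    }
  })

  # true annual wild abundance and smolt-equivalents
  J_t <- colMeans(grid$density) * cfg$channel_length_m
  J_star <- vapply(seq_len(ny), function(yi) {
    smolt_equivalents(april_by_year[[yi]], J_t[yi], cfg$smolt, cfg$survival)
  }, numeric(1))
  C_star <- vapply(seq_len(ny), function(yi) {
    smolt_equivalents(captive_lengths[[yi]]$length_mm, C_t[yi],
                      cfg$smolt, cfg$survival)
  }, numeric(1))

  q <- cfg$true_transitions
  split <- cfg$ocean_age_split
  wild <- if (cfg$lifecycle_truth == "size_conditional") J_star else J_t
  cap <- if (cfg$lifecycle_truth == "size_conditional") C_star else C_t
  adults_expected <- rep(NA_real_, ny)
  adults <- numeric(ny)
  local_rng({
    set.seed(derive_seed(cfg$seed, "adults"))
    for (yi in seq_len(ny)) {
      if (yi <= 2) {
        adults[yi] <- cfg$initial_adults[yi]
      } else {
        adults_expected[yi] <- q[1] * (split[1] * wild[yi - 1] +
                                         split[2] * wild[yi - 2]) +
          q[2] * (split[1] * cap[yi - 1] + split[2] * cap[yi - 2])
        adults[yi] <- max(0, adults_expected[yi] +
                            stats::rnorm(1, 0, cfg$adult_noise_sd))
      }
    }
  })

  structure(list(
    survey = collapse_rows(survey, c("site", "year", "pass", "length_mm")),
    temperature = do.call(rbind, temperature),
    annual = data.frame(year = years, adults = adults,
                        captives_released = C_t, translocated = R_t,
                        flow_cfs = flow),
    captive_lengths = do.call(rbind, captive_lengths),
    truth = list(config = unclass(cfg),
                 site_year = do.call(rbind, site_truth),
                 J_t = J_t, J_star = J_star, C_star = C_star,
                 april_lengths = stats::setNames(april_by_year,
                                                 as.character(years)),
                 adults_expected = adults_expected)
  ), class = "steelhead_scenario")
}

collapse_rows <- function(lst, cols) {
  if (length(lst) == 0) {
    return(stats::setNames(data.frame(character(0), integer(0), integer(0),
                                      numeric(0)), cols))
  }
  out <- do.call(rbind, lst)
  out[, cols]
}

# apply sequential binomial removal to individual fish; returns captured
# fish with their pass label
depletion_capture <- function(lengths_mm, p, n_passes, seed) {
  remaining <- seq_along(lengths_mm)
  rows <- list()
  local_rng({
    set.seed(seed)
    for (pass in seq_len(n_passes)) {
      if (length(remaining) == 0) break
      caught <- remaining[stats::runif(length(remaining)) < p]
      remaining <- setdiff(remaining, caught)
      if (length(caught) > 0) {
        rows[[pass]] <- data.frame(pass = pass,
                                   length_mm = lengths_mm[caught])
      }
    }
  })
  if (length(rows) == 0) {
    return(data.frame(pass = integer(0), length_mm = numeric(0)))
  }
  do.call(rbind, rows)
}

#' @export
print.steelhead_scenario <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "Synthetic steelhead scenario: %d sites x %d years (%s truth)\n",
    length(cfg$sites), length(cfg$years), cfg$lifecycle_truth))
  cat(sprintf("  survey: %d fish; adults %0.f-%0.f\n",
              nrow(x$survey), min(x$annual$adults), max(x$annual$adults)))
  invisible(x)
}

#' Write a synthetic scenario to CSV files plus a truth record
#'
#' Emits `survey.csv`, `temperature.csv`, `annual.csv`,
#' `captive_lengths.csv` (UTF-8, header row, ISO dates) and `truth.json`
#' (the full generating configuration; the config suffices to regenerate
#' every intermediate quantity bit-for-bit).
#'
#' @param x a `steelhead_scenario`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(x, dir) {
  stopifnot(inherits(x, "steelhead_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$survey, file.path(dir, "survey.csv"),
                   row.names = FALSE)
  utils::write.csv(x$temperature, file.path(dir, "temperature.csv"),
                   row.names = FALSE)
  utils::write.csv(x$annual, file.path(dir, "annual.csv"),
                   row.names = FALSE)
  utils::write.csv(x$captive_lengths, file.path(dir, "captive_lengths.csv"),
                   row.names = FALSE)
  cfg <- x$truth$config
  cfg$smolt <- unclass(cfg$smolt)
  cfg$survival <- unclass(cfg$survival)
  jsonlite::write_json(cfg, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scenario's tables back from a directory
#'
#' @param dir directory written by [write_scenario()].
#' @return list with `survey`, `temperature`, `annual`, `captive_lengths`
#'   and `config` (reconstructed [scenario_config()]).
#' @export
read_scenario <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
  cfg <- do.call(scenario_config, cfg_raw[setdiff(names(cfg_raw),
                                                  c("smolt", "survival"))])
  cfg$smolt <- do.call(smolt_params, as.list(cfg_raw$smolt))
  cfg$survival <- do.call(survival_params, as.list(cfg_raw$survival))
  temp <- utils::read.csv(file.path(dir, "temperature.csv"))
  temp$date <- as.Date(temp$date)
  list(survey = utils::read.csv(file.path(dir, "survey.csv")),
       temperature = temp,
       annual = utils::read.csv(file.path(dir, "annual.csv")),
       captive_lengths = utils::read.csv(file.path(dir,
                                                   "captive_lengths.csv")),
       config = cfg)
}
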