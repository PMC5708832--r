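#' Competitive load on a focal fish
#'
#' Size-asymmetric competition: the cost imposed on a fish of length L by a
#' competitor of length lambda is `exp(beta * (lambda - L))`, so larger
#' competitors weigh more heavily and a large fish facing small competitors
#' bears a load below 1. The total load is the mean over all competitors;
#' with no competitors the load is neutral (1). `beta = 0` recovers
#' symmetric competition (load exactly 1).
#'
#' @param focal_length fork length of the focal fish, mm.
#' @param competitor_lengths fork lengths of its competitors, mm (may be
#'   empty).
#' @param beta asymmetry coefficient, mm^-1 (>= 0).
#' @return dimensionless load (numeric scalar).
#' @export
competition_load <- function(focal_length, competitor_lengths, beta) {
  if (beta < 0) stop("beta must be non-negative")
  n <- length(competitor_lengths)
  if (n == 0) return(1)
  sum(exp(beta * (competitor_lengths - focal_length))) / max(1, n)
}

#' Temperature response of the growth rate
#'
#' Unimodal Gaussian response `exp(-(T - 15)^2 / 55.4)`: peak growth (1) at
#' 15 degrees C, at least 85% of maximum on 12-18 degrees C, declining into
#' the thermal-stress band above 21 degrees C.
#'
#' @param temp_c water temperature, degrees C (vectorized).
#' @return multiplier in `[0, 1]`.
#' @export
temperature_response <- function(temp_c) {
  exp(-(temp_c - 15)^2 / 55.4)
}

#' One day of cohort growth
#'
#' Advances every fish in a cohort by one day: specific mass growth rate
#' `r_i = g_max * phi(T) * eta_h * (L_ref / L_i) / (1 + load_i)` with the
#' competitive load of [competition_load()] (competitors of fish i are all
#' other fish), the temperature response `phi` of
#' [temperature_response()], and an allometric damping `L_ref / L_i`
#' (reference length 28 mm, the emergence length) that renders length
#' growth near-linear in time, as observed in young-of-year salmonids.
#' Mass is updated multiplicatively and length recovered from the
#' condition-factor coupling `mass_g = 1e-5 * length_mm^3`.
#' Deterministic; lengths never decrease.
#'
#' @param lengths_mm current fork lengths of the cohort, mm.
#' @param temp_c water temperature for the day, degrees C.
#' @param beta asymmetry coefficient, mm^-1.
#' @param eta_h food availability (dimensionless intake scalar).
#' @param g_max maximum specific growth rate, per day.
#' @return updated fork lengths (same order).
#' @export
daily_growth_step <- function(lengths_mm, temp_c, beta, eta_h,
                              g_max = 0.025) {
  n <- length(lengths_mm)
  stopifnot(n >= 1, beta >= 0)
  mass <- 1e-5 * lengths_mm^3
  base <- g_max * temperature_response(temp_c) * eta_h
  if (base <= 0) return(lengths_mm)
  e <- exp(beta * lengths_mm)
  load <- if (n > 1) (sum(e) - e) / ((n - 1) * e) else rep(1, n)
  mass <- mass * (1 + base * (28 / lengths_mm) / (1 + load))
  (mass / 1e-5)^(1 / 3)
}

#' Simulate cohort growth over a daily temperature series
#'
#' Runs [daily_growth_step()] over consecutive days (compiled core).
#'
#' @param init_lengths_mm starting fork lengths, mm.
#' @param temps_c daily water temperatures, degrees C, one per day.
#' @inheritParams daily_growth_step
#' @return final fork lengths.
#' @export
simulate_growth <- function(init_lengths_mm, temps_c, beta, eta_h,
                            g_max = 0.025) {
  stopifnot(length(init_lengths_mm) >= 1, beta >= 0, eta_h >= 0)
  sim_growth_core(as.numeric(init_lengths_mm), as.numeric(temps_c),
                  beta, eta_h, g_max)
}

#' Control settings for growth fitting
#'
#' @param n_fish simulated cohort size.
#' @param n_starts Latin-hypercube multi-starts for the optimizer.
#' @param init_mean,init_sd emergence length distribution, mm (1 May
#'   hatch; spawning runs January-April so emergence is late spring).
#' @param g_max maximum specific growth rate, per day (fixed constant,
#'   not fitted).
#' @param beta_bounds,eta_bounds optimization box for (beta, eta_H).
#' @param reltol relative convergence tolerance of the local optimizer.
#' @return list of class `growth_control`.
#' @export
growth_control <- function(n_fish = 200, n_starts = 8, init_mean = 28,
                           init_sd = 2, g_max = 0.025,
                           beta_bounds = c(0, 0.2),
                           eta_bounds = c(1e-3, 10), reltol = 1e-6) {
  structure(list(n_fish = n_fish, n_starts = n_starts, init_mean = init_mean,
                 init_sd = init_sd, g_max = g_max, beta_bounds = beta_bounds,
                 eta_bounds = eta_bounds, reltol = reltol),
            class = "growth_control")
}

#' Fit the growth model to an observed October YOY size distribution
#'
#' Estimates the two free parameters of the growth model for one site-year
#' -- the competition asymmetry `beta` and the food availability `eta_H` --
#' by matching the simulated cohort's October mean and standard deviation
#' of fork length to the observed YOY component. The objective is the sum
#' of squared relative errors of mean and sd (equal weight). A cohort of
#' `control$n_fish` fish is initialized at emergence (`N(init_mean,
#' init_sd)` mm, fixed seed) and grown over the supplied hatch-to-October
#' temperature series. Optimization uses `control$n_starts` Latin-hypercube
#' starts with bounded local refinement (L-BFGS-B).
#'
#' @param obs_mean,obs_sd observed YOY mean and sd in October, mm
#'   (`obs_sd > 0`).
#' @param temps_c daily temperatures from hatch to the October survey.
#' @param control a [growth_control()] object.
#' @param seed RNG seed for the initial cohort and start points (global
#'   RNG state preserved).
#' @param site,year optional labels carried into the result.
#' @return object of class `growth_fit`: `params` (beta, eta_H),
#'   `objective_value`, `october_mean`, `october_sd`, `october_lengths`,
#'   `init_lengths`, `at_bound` flag, labels.
#' @export
fit_site_year <- function(obs_mean, obs_sd, temps_c,
                          control = growth_control(), seed = 1,
                          site = NA, year = NA) {
  stopifnot(obs_sd > 0, obs_mean > 0, length(temps_c) >= 1)
  lb <- c(control$beta_bounds[1], control$eta_bounds[1])
  ub <- c(control$beta_bounds[2], control$eta_bounds[2])

  init <- NULL
  starts <- NULL
  local_rng({
    set.seed(seed)
    init <- stats::rnorm(control$n_fish, control$init_mean, control$init_sd)
    u <- lhs::randomLHS(control$n_starts, 2)
    starts <- sweep(sweep(u, 2, ub - lb, "*"), 2, lb, "+")
  })
  init <- pmax(init, 5)  # guard against absurd emergence draws

  objective <- function(par) {
    fin <- sim_growth_core(init, temps_c, par[1], par[2], control$g_max)
    ((mean(fin) - obs_mean) / obs_mean)^2 +
      ((stats::sd(fin) - obs_sd) / obs_sd)^2
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(factr = control$reltol / 1e-15)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("growth optimization failed from every start")

  par <- best$par
  tol <- 1e-6 * (ub - lb)
  # beta = 0 is the legitimate no-competition limit, not a boundary failure
  at_bound <- par[2] <= lb[2] + tol[2] || any(par >= ub - tol)
  oct <- sim_growth_core(init, temps_c, par[1], par[2], control$g_max)
  structure(list(
    site = site, year = year,
    params = c(beta = unname(par[1]), eta_H = unname(par[2])),
    objective_value = best$value,
    october_mean = mean(oct), october_sd = stats::sd(oct),
    obs_mean = obs_mean, obs_sd = obs_sd,
    october_lengths = oct, init_lengths = init,
    g_max = control$g_max, at_bound = at_bound
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Growth fit%s: beta = %.4f, eta_H = %.3f (objective %.2e)\n",
    if (is.na(x$site)) "" else sprintf(" [%s %s]", x$site, x$year),
    x$params["beta"], x$params["eta_H"], x$objective_value))
  cat(sprintf("  October mean %.1f mm (obs %.1f), sd %.1f mm (obs %.1f)\n",
              x$october_mean, x$obs_mean, x$october_sd, x$obs_sd))
  invisible(x)
}

#' Project an October cohort forward to 1 April
#'
#' Continues the daily growth simulation from the fitted October state with
#' frozen (beta, eta_H) -- seasonal changes in competition and food are
#' taken as negligible -- and applies no overwinter mortality, which is
#' absorbed into the corresponding apparent transition rate downstream.
#'
#' @param fit a `growth_fit`.
#' @param temps_c daily temperatures from the October survey to 1 April.
#' @return numeric vector of 1 April fork lengths (one per simulated fish,
#'   count preserved).
#' @export
project_to_april <- function(fit, temps_c) {
  stopifnot(inherits(fit, "growth_fit"))
  sim_growth_core(fit$october_lengths, as.numeric(temps_c),
                  fit$params["beta"], fit$params["eta_H"], fit$g_max)
}
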