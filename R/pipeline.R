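#' Control settings for the end-to-end report
#'
#' @param k_max largest number of age classes considered per site-year.
#' @param em_restarts EM restarts per mixture fit.
#' @param growth a [growth_control()] for the per-site-year growth fits.
#' @param exclude_years adult years excluded from the life-cycle fits
#'   (e.g. years with migration fully blocked).
#' @param smolt,survival curve parameters for the smolt-equivalents.
#' @param ocean_age_split proportions returning after 1 and 2 ocean years.
#' @param channel_length_m expansion length; `NULL` to take it from the
#'   scenario truth/config.
#' @param site_length_m surveyed reach length; `NULL` as above.
#' @param recruitment_starts multi-starts for the nonlinear recruitment
#'   fits.
#' @param seed seed for the deterministic restart/initialization streams.
#' @return list of class `report_control`.
#' @export
report_control <- function(k_max = 4, em_restarts = 20,
                           growth = growth_control(),
                           exclude_years = NULL,
                           smolt = smolt_params(),
                           survival = survival_params(),
                           ocean_age_split = c(0.53, 0.47),
                           channel_length_m = NULL, site_length_m = NULL,
                           recruitment_starts = 16, seed = 1) {
  structure(list(k_max = k_max, em_restarts = em_restarts, growth = growth,
                 exclude_years = exclude_years, smolt = smolt,
                 survival = survival, ocean_age_split = ocean_age_split,
                 channel_length_m = channel_length_m,
                 site_length_m = site_length_m,
                 recruitment_starts = recruitment_starts, seed = seed),
            class = "report_control")
}

#' Run the full analysis pipeline on a monitoring dataset
#'
#' Chains every stage of the retrospective analysis: age-structure
#' decomposition of the October length samples (normal mixtures,
#' BIC-selected K), removal abundance estimation and river-wide YOY
#' expansion, per-site-year growth fitting and projection to 1 April,
#' size-conditional versus fixed-rate adult models compared by AICc with
#' origin decomposition, recruitment (density-regulation) model ranking,
#' and the YOY-length covariate regressions.
#'
#' @param data a `steelhead_scenario` from [simulate_scenario()], or the
#'   list returned by [read_scenario()].
#' @param control a [report_control()].
#' @param out_dir optional directory; when given, every table is written
#'   as CSV together with a machine-readable run manifest.
#' @return object of class `steelhead_report`: `ages` (per-site-year
#'   mixture summaries), `abundance` (annual J_t), `growth` (per-site-year
#'   beta/eta_H and April projections), `lifecycle` (model comparison,
#'   fits, origin decomposition), `recruitment`, `lengths`, `manifest`.
#' @export
run_report <- function(data, control = report_control(), out_dir = NULL) {
  cfg <- if (inherits(data, "steelhead_scenario")) data$truth$config else
    data$config
  channel_m <- control$channel_length_m %||% cfg$channel_length_m
  site_m <- control$site_length_m %||% cfg$site_length_m
  survey <- data$survey
  stopifnot(all(c("site", "year", "pass", "length_mm") %in% names(survey)))
  n_passes <- max(survey$pass)

  # --- stage 1: age structure ----------------------------------------------
  keys <- unique(survey[, c("site", "year")])
  age_rows <- list()
  fits <- list()
  for (i in seq_len(nrow(keys))) {
    site <- keys$site[i]; year <- keys$year[i]
    lengths <- survey$length_mm[survey$site == site & survey$year == year]
    if (length(lengths) < 3) next
    fit <- select_age_model(lengths, k_max = control$k_max,
                            n_restarts = control$em_restarts,
                            seed = control$seed)
    ys <- yoy_summary(fit)
    fits[[paste(site, year)]] <- fit
    age_rows[[length(age_rows) + 1]] <- data.frame(
      site = site, year = year, n = fit$n, K = fit$K,
      yoy_mean_mm = ys$yoy_mean_mm, yoy_sd_mm = ys$yoy_sd_mm,
      yoy_fraction = ys$yoy_fraction, yoy_weight = ys$yoy_weight)
  }
  ages <- do.call(rbind, age_rows)

  # --- stage 2: abundance --------------------------------------------------
  ab_rows <- lapply(seq_len(nrow(ages)), function(i) {
    site <- ages$site[i]; year <- ages$year[i]
    sub <- survey[survey$site == site & survey$year == year, ]
    counts <- tabulate(sub$pass, nbins = n_passes)
    est <- removal_estimate(counts)
    data.frame(site = site, year = year, n_hat = est$n_hat,
               p_hat = est$p_hat, method = est$method,
               density_per_m = est$n_hat * ages$yoy_fraction[i] / site_m)
  })
  site_abund <- do.call(rbind, ab_rows)
  annual_J <- annual_yoy_abundance(site_abund, channel_m)

  # --- stage 3: growth and April projection --------------------------------
  temperature <- data$temperature
  growth_rows <- list()
  april_pool <- list()
  for (i in seq_len(nrow(ages))) {
    site <- ages$site[i]; year <- ages$year[i]
    td <- temperature[temperature$site == site & temperature$year == year, ]
    if (nrow(td) == 0) next
    survey_date <- cohort_dates(year)$survey
    to_oct <- td$temp_C[td$date <= survey_date]
    to_apr <- td$temp_C[td$date > survey_date]
    gf <- fit_site_year(ages$yoy_mean_mm[i], max(ages$yoy_sd_mm[i], 1),
                        to_oct, control = control$growth,
                        seed = control$seed, site = site, year = year)
    april <- project_to_april(gf, to_apr)
    growth_rows[[length(growth_rows) + 1]] <- data.frame(
      site = site, year = year, beta = gf$params["beta"],
      eta_H = gf$params["eta_H"], objective = gf$objective_value,
      at_bound = gf$at_bound,
      october_mean = gf$october_mean, october_sd = gf$october_sd,
      april_mean = mean(april), april_sd = stats::sd(april))
    april_pool[[length(april_pool) + 1]] <-
      data.frame(year = year, length_mm = april)
  }
  growth_tab <- do.call(rbind, growth_rows)
  rownames(growth_tab) <- NULL
  april_all <- do.call(rbind, april_pool)

  # --- stage 4: life-cycle models ------------------------------------------
  annual <- data$annual
  years <- annual$year
  J <- annual_J$J_t[match(years, annual_J$year)]
  J_star <- vapply(seq_along(years), function(i) {
    al <- april_all$length_mm[april_all$year == years[i]]
    if (length(al) == 0 || is.na(J[i])) return(NA_real_)
    smolt_equivalents(al, J[i], control$smolt, control$survival)
  }, numeric(1))
  C <- annual$captives_released
  C_star <- vapply(seq_along(years), function(i) {
    cl <- data$captive_lengths$length_mm[data$captive_lengths$year ==
                                           years[i]]
    if (length(cl) == 0) return(if (C[i] == 0) 0 else NA_real_)
    smolt_equivalents(cl, C[i], control$smolt, control$survival)
  }, numeric(1))
  inputs <- cohort_inputs(years, annual$adults, J, C, J_star, C_star,
                          control$ocean_age_split)
  lifecycle <- compare_lifecycle_models(inputs,
                                        exclude_years = control$exclude_years)
  origin <- decompose_origin(lifecycle$fits$size_conditional)

  # --- stage 5: recruitment ------------------------------------------------
  rec_data <- data.frame(J = J, A = annual$adults, R = annual$translocated)
  rec_data <- rec_data[stats::complete.cases(rec_data), ]
  recruitment <- compare_recruitment_models(rec_data,
                                            n_starts =
                                              control$recruitment_starts)

  # --- stage 6: YOY length covariates --------------------------------------
  len_data <- data.frame(
    length_mm = vapply(years, function(y) {
      m <- ages$yoy_mean_mm[ages$year == y]
      if (length(m) == 0) NA_real_ else mean(m)
    }, numeric(1)),
    adults = annual$adults, translocations = annual$translocated,
    flow = annual$flow_cfs)
  len_data <- len_data[stats::complete.cases(len_data), ]
  lengths_cmp <- if (nrow(len_data) >= 6) fit_length_models(len_data) else
    NULL

  report <- structure(list(
    ages = ages, site_abundance = site_abund, abundance = annual_J,
    growth = growth_tab, inputs = inputs,
    lifecycle = lifecycle, origin = origin,
    recruitment = recruitment, lengths = lengths_cmp,
    manifest = report_manifest(cfg, control)
  ), class = "steelhead_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

report_manifest <- function(cfg, control) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(list(config = cfg, control = unclass(control)), tf,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(package = "condsmolt",
       version = as.character(utils::packageVersion("condsmolt")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = control$seed,
       config_hash = unname(tools::md5sum(tf)))
}

#' @export
print.steelhead_report <- function(x, ...) {
  cat("Steelhead pipeline report\n")
  cat(sprintf("  %d site-year age fits, %d years of abundance\n",
              nrow(x$ages), nrow(x$abundance)))
  cat("\nAdult-model comparison (AICc):\n")
  print(x$lifecycle$table[, c("name", "k", "n", "aicc", "delta", "weight",
                              "evidence_ratio")], digits = 4)
  cat("\nRecruitment-model comparison (AICc):\n")
  print(x$recruitment$table[, c("name", "k", "aicc", "delta", "weight",
                                "evidence_ratio")], digits = 4)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(report$ages, "ages.csv")
  w(report$site_abundance, "site_abundance.csv")
  w(report$abundance, "annual_abundance.csv")
  w(report$growth, "growth_fits.csv")
  w(report$lifecycle$table, "adult_model_comparison.csv")
  w(cbind(report$origin,
          adults = report$lifecycle$fits$size_conditional$predictions$adults),
    "adult_origin_decomposition.csv")
  w(report$recruitment$table, "recruitment_model_comparison.csv")
  if (!is.null(report$lengths)) {
    w(report$lengths$table, "length_model_comparison.csv")
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
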