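#' Assemble annual cohort inputs for the adult-return models
#'
#' @param year calendar years (return years for adults).
#' @param adults adult counts at the counting station, A_t.
#' @param J wild YOY abundance the previous October (indexed by the same
#'   year vector; lagging is done at prediction time).
#' @param C captively-reared fish released in year t.
#' @param J_star,C_star smolt-equivalents of J and C (see
#'   [smolt_equivalents()]); may be `NULL` if only the fixed-rate model is
#'   fitted.
#' @param ocean_age_split proportions returning after 1 and 2 ocean years
#'   (must sum to 1).
#' @return data.frame of class `cohort_inputs`.
#' @export
cohort_inputs <- function(year, adults, J, C, J_star = NULL, C_star = NULL,
                          ocean_age_split = c(0.53, 0.47)) {
  stopifnot(length(ocean_age_split) == 2,
            abs(sum(ocean_age_split) - 1) < 1e-8,
            all(adults >= 0, na.rm = TRUE), all(J >= 0, na.rm = TRUE),
            all(C >= 0, na.rm = TRUE))
  out <- data.frame(year = year, adults = adults, J = J, C = C)
  out$J_star <- if (is.null(J_star)) NA_real_ else J_star
  out$C_star <- if (is.null(C_star)) NA_real_ else C_star
  attr(out, "ocean_age_split") <- ocean_age_split
  class(out) <- c("cohort_inputs", "data.frame")
  out
}

# split-weighted lagged predictors for each year with both lags available
lagged_predictors <- function(inputs, model = c("size_conditional",
                                                "fixed_rate"),
                              exclude_years = NULL) {
  model <- match.arg(model)
  split <- attr(inputs, "ocean_age_split")
  wild <- if (model == "size_conditional") inputs$J_star else inputs$J
  cap <- if (model == "size_conditional") inputs$C_star else inputs$C
  yrs <- inputs$year
  rows <- lapply(seq_along(yrs), function(i) {
    i1 <- match(yrs[i] - 1, yrs)
    i2 <- match(yrs[i] - 2, yrs)
    if (is.na(i1) || is.na(i2)) return(NULL)
    vals <- c(wild[i1], wild[i2], cap[i1], cap[i2], inputs$adults[i])
    if (anyNA(vals)) return(NULL)
    data.frame(year = yrs[i],
               adults = inputs$adults[i],
               x_wild = split[1] * wild[i1] + split[2] * wild[i2],
               x_captive = split[1] * cap[i1] + split[2] * cap[i2])
  })
  out <- do.call(rbind, rows)
  if (!is.null(exclude_years) && !is.null(out)) {
    out <- out[!out$year %in% exclude_years, , drop = FALSE]
  }
  out
}

#' Predict adult returns from juvenile production
#'
#' Linear-in-q prediction
#' `A_t = q_wild (0.53 P_{t-1} + 0.47 P_{t-2}) + q_cap (0.53 Q_{t-1} + 0.47 Q_{t-2})`
#' where the predictors P, Q are raw abundances (J, C) under the fixed-rate
#' model and smolt-equivalents (J*, C*) under the size-conditional model.
#' Years lacking either lag are excluded.
#'
#' @param inputs a [cohort_inputs()] data.frame.
#' @param q numeric pair: wild and captive apparent transition rates.
#' @param model `"size_conditional"` or `"fixed_rate"`.
#' @param exclude_years years to drop (e.g. migration fully blocked).
#' @return data.frame with `year`, `adults` (observed), `predicted`.
#' @export
predict_adults <- function(inputs, q, model = c("size_conditional",
                                                "fixed_rate"),
                           exclude_years = NULL) {
  model <- match.arg(model)
  stopifnot(length(q) == 2)
  d <- lagged_predictors(inputs, model, exclude_years)
  if (is.null(d) || nrow(d) == 0) stop("no years with both lags available")
  d$predicted <- q[1] * d$x_wild + q[2] * d$x_captive
  d[, c("year", "adults", "x_wild", "x_captive", "predicted")]
}

#' Fit apparent transition rates by least squares
#'
#' Ordinary least squares with no intercept (the adult models have none)
#' and coefficients unconstrained in sign. The fitted pair is (q3, q4) for
#' the size-conditional model and (q1, q2) for the fixed-rate model: each
#' is an *apparent* rate, confounding survival and smolting with the fixed
#' sampling biases of the monitoring series. A singular design (e.g. an
#' all-zero captive series) drops that coefficient with a flag.
#'
#' @inheritParams predict_adults
#' @return object of class `transition_fit` with `model`, `q`, `se`, `rss`,
#'   `n_years`, `k` (coefficients + residual variance), `aicc`,
#'   `predictions` (per-year observed/predicted), `dropped` (names of
#'   dropped coefficients), and the underlying `lm` fit.
#' @export
fit_transition_rates <- function(inputs, model = c("size_conditional",
                                                   "fixed_rate"),
                                 exclude_years = NULL) {
  model <- match.arg(model)
  d <- lagged_predictors(inputs, model, exclude_years)
  if (is.null(d) || nrow(d) < 4) {
    stop("need at least 4 usable years (2 coefficients + residual df)")
  }
  qn <- if (model == "size_conditional") c("q3", "q4") else c("q1", "q2")
  dropped <- character(0)
  use_captive <- stats::sd(d$x_captive) > 0 && any(d$x_captive != 0)
  if (!use_captive) dropped <- qn[2]
  fml <- if (use_captive) adults ~ 0 + x_wild + x_captive else
    adults ~ 0 + x_wild
  fit <- stats::lm(fml, data = d)
  # summary.lm warns on zero-residual (noise-free) data; that case is valid
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  q <- se <- stats::setNames(rep(NA_real_, 2), qn)
  q[1] <- cf["x_wild", 1]; se[1] <- cf["x_wild", 2]
  if (use_captive) {
    q[2] <- cf["x_captive", 1]; se[2] <- cf["x_captive", 2]
  }
  rss <- sum(stats::residuals(fit)^2)
  n <- nrow(d)
  k <- length(stats::coef(fit)) + 1
  d$predicted <- as.numeric(stats::fitted(fit))
  structure(list(model = model, q = q, se = se, rss = rss, n_years = n,
                 k = k, aicc = aicc_from_rss(rss, n, k),
                 predictions = d[, c("year", "adults", "x_wild", "x_captive",
                                     "predicted")],
                 dropped = dropped, lm_fit = fit),
            class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf("%s adult model (%d years, AICc = %.2f)\n",
              gsub("_", "-", x$model), x$n_years, x$aicc))
  for (i in seq_along(x$q)) {
    cat(sprintf("  %s = %.4g (SE %.4g)\n", names(x$q)[i], x$q[i], x$se[i]))
  }
  if (length(x$dropped)) cat("  dropped:", x$dropped, "\n")
  invisible(x)
}

#' Decompose predicted adult returns by juvenile origin
#'
#' Splits each year's prediction into the wild-reared and captively-reared
#' contributions; the two sum to the total prediction exactly.
#'
#' @param fit a `transition_fit`.
#' @return data.frame with `year`, `wild_pred`, `captive_pred`, `predicted`.
#' @export
decompose_origin <- function(fit) {
  stopifnot(inherits(fit, "transition_fit"))
  p <- fit$predictions
  qw <- fit$q[1]
  qc <- if (is.na(fit$q[2])) 0 else fit$q[2]
  data.frame(year = p$year,
             wild_pred = qw * p$x_wild,
             captive_pred = qc * p$x_captive,
             predicted = p$predicted)
}

#' Compare the size-conditional and fixed-rate adult models by AICc
#'
#' @inheritParams fit_transition_rates
#' @return list with `table` (an [aic_table()] over the two models) and
#'   `fits` (named list of `transition_fit` objects).
#' @export
compare_lifecycle_models <- function(inputs, exclude_years = NULL) {
  fits <- list(
    size_conditional = fit_transition_rates(inputs, "size_conditional",
                                            exclude_years),
    fixed_rate = fit_transition_rates(inputs, "fixed_rate", exclude_years)
  )
  tab <- data.frame(
    name = names(fits),
    k = vapply(fits, `[[`, numeric(1), "k"),
    n = vapply(fits, `[[`, numeric(1), "n_years"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc")
  )
  list(table = aic_table(tab), fits = fits)
}
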