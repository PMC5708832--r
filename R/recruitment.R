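#' Names of the competing recruitment (YOY-abundance) models
#'
#' Three density-regulation concepts -- fixed production (`J = K`),
#' proportional (`J = r A`), logistic capacity (`J = r A (1 - r A / K)`) --
#' each with and without an additive translocation term `s R`.
#'
#' @return character vector of the six model names.
#' @export
recruitment_model_names <- function() {
  c("fixed_production", "proportional", "logistic_capacity",
    "fixed_production_translocations", "proportional_translocations",
    "logistic_capacity_translocations")
}

recruitment_param_names <- function(name) {
  base <- switch(sub("_translocations$", "", name),
                 fixed_production = "K",
                 proportional = "r",
                 logistic_capacity = c("r", "K"),
                 stop("unknown recruitment model: ", name))
  if (grepl("_translocations$", name)) c(base, "s") else base
}

#' Expected October YOY abundance under a recruitment model
#'
#' @param name one of [recruitment_model_names()].
#' @param params named vector with the model's parameters among `K`
#'   (capacity, fish), `r` (YOY per adult), `s` (translocation survival).
#' @param A adult spawner counts the previous spring.
#' @param R translocated juvenile counts (ignored by models without the
#'   translocation term).
#' @return expected YOY abundances; logistic predictions that would go
#'   negative (r A > K) are floored at 0 with attribute `floored`.
#' @export
predict_recruitment <- function(name, params, A, R = 0) {
  name <- match.arg(name, recruitment_model_names())
  pn <- recruitment_param_names(name)
  stopifnot(all(pn %in% names(params)), all(A >= 0), all(R >= 0))
  base <- switch(sub("_translocations$", "", name),
                 fixed_production = rep(params[["K"]], length(A)),
                 proportional = params[["r"]] * A,
                 logistic_capacity = params[["r"]] * A *
                   (1 - params[["r"]] * A / params[["K"]]))
  floored <- base < 0
  base[floored] <- 0
  out <- if (grepl("_translocations$", name)) base + params[["s"]] * R else
    base
  attr(out, "floored") <- any(floored)
  out
}

recruitment_bounds <- list(K = c(1e-6, 1e7), r = c(1e-6, 1e4), s = c(0, 10))

#' Fit one recruitment model by least squares
#'
#' Linear model families (fixed production and proportional, with or
#' without translocations) are solved exactly by ordinary least squares.
#' The logistic-capacity families use bounded nonlinear least squares with
#' 16 multi-starts over log-spaced parameter grids (bounds K in (0, 1e7],
#' r in (0, 1e4], s in [0, 10]), refined with `nls` (port algorithm) for
#' standard errors; a Gauss-Newton covariance fallback is used if `nls`
#' declines to converge.
#'
#' @param name one of [recruitment_model_names()].
#' @param data data.frame with columns `J` (October YOY abundance), `A`
#'   (adults the previous spring) and `R` (translocated fish).
#' @param n_starts multi-starts for the nonlinear families.
#' @return object of class `recruitment_fit`: `name`, `params`, `se`,
#'   `rss`, `n`, `k` (parameters + residual variance), `aicc`, `log_lik`
#'   (Gaussian, constant-inclusive), `predictions`, `converged`.
#' @export
fit_recruitment <- function(name, data, n_starts = 16) {
  name <- match.arg(name, recruitment_model_names())
  pn <- recruitment_param_names(name)
  stopifnot(all(c("J", "A", "R") %in% names(data)))
  n <- nrow(data)
  k <- length(pn) + 1
  if (n < length(pn) + 2) stop("need at least k + 2 years for ", name)

  if (!grepl("^logistic", name)) {
    fml <- switch(name,
                  fixed_production = J ~ 1,
                  proportional = J ~ 0 + A,
                  fixed_production_translocations = J ~ R,
                  proportional_translocations = J ~ 0 + A + R)
    fit <- stats::lm(fml, data = data)
    cf <- summary(fit)$coefficients
    map <- c("(Intercept)" = "K", A = "r", R = "s")
    params <- stats::setNames(cf[, 1], map[rownames(cf)])[pn]
    se <- stats::setNames(cf[, 2], map[rownames(cf)])[pn]
    pred <- as.numeric(stats::fitted(fit))
    rss <- sum(stats::residuals(fit)^2)
    converged <- TRUE
  } else {
    obj <- function(logpar) {
      p <- stats::setNames(exp(logpar), pn)
      if ("s" %in% pn) p["s"] <- exp(logpar[match("s", pn)]) - 1e-6
      sum((data$J - predict_recruitment(name, p, data$A, data$R))^2)
    }
    lb <- log(vapply(pn, function(p) recruitment_bounds[[p]][1] +
                       if (p == "s") 1e-6 else 0, numeric(1)))
    ub <- log(vapply(pn, function(p) recruitment_bounds[[p]][2] +
                       if (p == "s") 1e-6 else 0, numeric(1)))
    grids <- lapply(seq_along(pn), function(i) {
      seq(lb[i] + 0.05 * (ub[i] - lb[i]), ub[i] - 0.05 * (ub[i] - lb[i]),
          length.out = max(2, ceiling(n_starts^(1 / length(pn)))))
    })
    starts <- as.matrix(expand.grid(grids))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                     lower = lb, upper = ub),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    if (is.null(best)) {
      return(structure(list(name = name, params = NULL, se = NULL,
                            rss = NA_real_, n = n, k = k, aicc = NA_real_,
                            log_lik = NA_real_, predictions = NULL,
                            converged = FALSE),
                       class = "recruitment_fit"))
    }
    params <- stats::setNames(exp(best$par), pn)
    if ("s" %in% pn) params["s"] <- params["s"] - 1e-6

    nls_fml <- if ("s" %in% pn) {
      J ~ pmax(0, r * A * (1 - r * A / K)) + s * R
    } else {
      J ~ pmax(0, r * A * (1 - r * A / K))
    }
    # warnOnly: the port refinement starts at the multi-start optimum, so a
    # "false convergence" report there is expected and harmless
    nfit <- tryCatch(
      suppressWarnings(
        stats::nls(nls_fml, data = data, start = as.list(params),
                   algorithm = "port",
                   lower = vapply(pn, function(p) recruitment_bounds[[p]][1],
                                  numeric(1)),
                   upper = vapply(pn, function(p) recruitment_bounds[[p]][2],
                                  numeric(1)),
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(nfit)) {
      cf <- summary(nfit)$coefficients
      params <- stats::setNames(cf[pn, 1], pn)
      se <- stats::setNames(cf[pn, 2], pn)
      pred <- as.numeric(stats::predict(nfit))
      rss <- sum(stats::residuals(nfit)^2)
    } else {
      pred <- as.numeric(predict_recruitment(name, params, data$A, data$R))
      rss <- sum((data$J - pred)^2)
      se <- gauss_newton_se(name, params, data, rss)
    }
    converged <- TRUE
  }

  log_lik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  structure(list(name = name, params = params, se = se, rss = rss, n = n,
                 k = k, aicc = aicc_from_rss(rss, n, k), log_lik = log_lik,
                 predictions = data.frame(year = seq_len(n), J = data$J,
                                          predicted = pred),
                 converged = converged),
            class = "recruitment_fit")
}

# central-difference Gauss-Newton standard errors for a recruitment model
gauss_newton_se <- function(name, params, data, rss) {
  pn <- names(params)
  n <- nrow(data)
  jac <- vapply(pn, function(p) {
    h <- max(1e-6, abs(params[p]) * 1e-6)
    up <- params; up[p] <- up[p] + h
    dn <- params; dn[p] <- dn[p] - h
    (as.numeric(predict_recruitment(name, up, data$A, data$R)) -
       as.numeric(predict_recruitment(name, dn, data$A, data$R))) / (2 * h)
  }, numeric(n))
  sigma2 <- rss / (n - length(pn))
  v <- tryCatch(sigma2 * solve(crossprod(jac)),
                error = function(e) matrix(NA_real_, length(pn), length(pn)))
  stats::setNames(sqrt(diag(v)), pn)
}

#' @export
print.recruitment_fit <- function(x, ...) {
  cat(sprintf("Recruitment model '%s' (n = %d, AICc = %.2f)\n",
              x$name, x$n, x$aicc))
  if (!is.null(x$params)) {
    for (p in names(x$params)) {
      cat(sprintf("  %s = %.4g (SE %.4g)\n", p, x$params[p], x$se[p]))
    }
  } else cat("  did not converge\n")
  invisible(x)
}

#' Fit and rank all six recruitment models
#'
#' @inheritParams fit_recruitment
#' @return list with `table` (an [aic_table()] including log-likelihoods)
#'   and `fits` (named list of `recruitment_fit`).
#' @export
compare_recruitment_models <- function(data, n_starts = 16) {
  fits <- lapply(recruitment_model_names(), fit_recruitment, data = data,
                 n_starts = n_starts)
  names(fits) <- recruitment_model_names()
  ok <- vapply(fits, `[[`, logical(1), "converged")
  tab <- data.frame(
    name = names(fits)[ok],
    k = vapply(fits[ok], `[[`, numeric(1), "k"),
    n = vapply(fits[ok], `[[`, numeric(1), "n"),
    aicc = vapply(fits[ok], `[[`, numeric(1), "aicc"),
    log_lik = vapply(fits[ok], `[[`, numeric(1), "log_lik")
  )
  list(table = aic_table(tab), fits = fits,
       excluded = names(fits)[!ok])
}

#' Sampling-bias constants of the monitoring series
#'
#' Adult counts omit spawning below the counting dam (44.8% of accessible
#' stream km, proportional bias -0.448 under spatially even spawning);
#' October surveys omit 61.5% of stream km (bias -0.615). The divisor
#' applied to the per-adult production rate r is kept at the printed 1.41,
#' alongside the analogous transition-rate ratio
#' `(1 - 0.448)/(1 - 0.615) = 1.43`; both are retained exactly where each
#' is used, and the small discrepancy is surfaced in output notes.
#'
#' @param adult_bias,juvenile_bias proportional biases, in (-1, 0).
#' @param correction_ratio divisor applied to r.
#' @return list of class `bias_constants`.
#' @export
bias_constants <- function(adult_bias = -0.448, juvenile_bias = -0.615,
                           correction_ratio = 1.41) {
  stopifnot(adult_bias > -1, adult_bias < 0,
            juvenile_bias > -1, juvenile_bias < 0)
  structure(list(adult_bias = adult_bias, juvenile_bias = juvenile_bias,
                 correction_ratio = correction_ratio),
            class = "bias_constants")
}

#' Correct fitted recruitment parameters for sampling bias
#'
#' Under the spatial-evenness assumption: `r` is divided by the correction
#' ratio, `K` by `(1 + juvenile_bias)`, `s` is multiplied by
#' `(1 + juvenile_bias)`. Also reports the expected apparent wild
#' transition rate `(1 + adult_bias) / (1 + juvenile_bias)` implied by the
#' biases alone (i.e. with negligible overwinter mortality).
#'
#' @param params named vector with any of `r`, `K`, `s`.
#' @param constants a [bias_constants()] object.
#' @param inverse if `TRUE`, undo the correction (round-trip identity).
#' @return list with `corrected` (named vector) and
#'   `expected_wild_transition`.
#' @export
bias_correct <- function(params, constants = bias_constants(),
                         inverse = FALSE) {
  out <- params
  jb <- 1 + constants$juvenile_bias
  if (!inverse) {
    if ("r" %in% names(out)) out["r"] <- out["r"] / constants$correction_ratio
    if ("K" %in% names(out)) out["K"] <- out["K"] / jb
    if ("s" %in% names(out)) out["s"] <- out["s"] * jb
  } else {
    if ("r" %in% names(out)) out["r"] <- out["r"] * constants$correction_ratio
    if ("K" %in% names(out)) out["K"] <- out["K"] * jb
    if ("s" %in% names(out)) out["s"] <- out["s"] / jb
  }
  list(corrected = out,
       expected_wild_transition = (1 + constants$adult_bias) / jb)
}

length_model_formulas <- list(
  flow = length_mm ~ flow,
  adults_translocations = length_mm ~ adults + translocations,
  adults_flow = length_mm ~ adults + flow,
  translocations_flow = length_mm ~ translocations + flow,
  translocations = length_mm ~ translocations,
  intercept_only = length_mm ~ 1,
  adults = length_mm ~ adults
)

#' Rank linear models for mean October YOY length
#'
#' Ordinary least squares with intercept for the seven combinations of the
#' candidate predictors -- end-of-summer streamflow, adult spawners the
#' previous spring, and juveniles translocated the previous summer --
#' ranked by AICc (`k` = coefficients + 1). Collinearity is reported via
#' the design-matrix condition number; fits are always returned.
#'
#' @param data data.frame with columns `length_mm` (annual mean YOY
#'   length), `adults`, `translocations`, `flow` (ft^3 s^-1); at least 6
#'   years.
#' @return list with `table` (an [aic_table()]), `fits` (named `lm` list)
#'   and `condition_numbers`.
#' @export
fit_length_models <- function(data) {
  stopifnot(all(c("length_mm", "adults", "translocations", "flow") %in%
                  names(data)))
  if (nrow(data) < 6) stop("need at least 6 years for the length models")
  fits <- lapply(length_model_formulas, stats::lm, data = data)
  n <- nrow(data)
  tab <- data.frame(
    name = names(fits),
    k = vapply(fits, function(f) length(stats::coef(f)) + 1, numeric(1)),
    n = n,
    rss = vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1)),
    adj_r2 = vapply(fits, function(f) summary(f)$adj.r.squared, numeric(1))
  )
  tab$aicc <- mapply(aicc_from_rss, tab$rss, tab$n, tab$k)
  list(table = aic_table(tab), fits = fits,
       condition_numbers = vapply(fits, function(f)
         kappa(stats::model.matrix(f)), numeric(1)))
}
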