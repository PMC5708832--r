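#' Smolting-curve parameters
#'
#' Logistic length threshold for the smolting decision: the threshold
#' `L_s` is the fork length at which smolting probability is 0.5 and
#' `sigma_s` sets the steepness of the curve at that point. Defaults are
#' the literature values for coastal steelhead (120 mm, 10 mm).
#'
#' @param L_s threshold length, mm.
#' @param sigma_s dispersion, mm (> 0).
#' @return list of class `smolt_params`.
#' @export
smolt_params <- function(L_s = 120, sigma_s = 10) {
  stopifnot(sigma_s > 0)
  structure(list(L_s = L_s, sigma_s = sigma_s), class = "smolt_params")
}

#' Marine-survival curve parameters
#'
#' Size-dependent early marine survival: a logistic in fork length with
#' asymptote 0.84, truncated at a ceiling of 0.35,
#' \deqn{s(L) = \min\{0.35,\; 0.84 / (1 + e^{8.657 - 0.0369 L})\}.}
#'
#' @param ceiling maximum survival after truncation.
#' @param asymptote untruncated logistic asymptote.
#' @param intercept,slope logistic shape parameters (slope in mm^-1).
#' @return list of class `survival_params`.
#' @export
survival_params <- function(ceiling = 0.35, asymptote = 0.84,
                            intercept = 8.657, slope = 0.0369) {
  stopifnot(ceiling > 0, ceiling <= asymptote, slope > 0)
  structure(list(ceiling = ceiling, asymptote = asymptote,
                 intercept = intercept, slope = slope),
            class = "survival_params")
}

#' Smolting probability at a given fork length
#'
#' @param length_mm fork length(s), mm (> 0).
#' @param params a [smolt_params()] object.
#' @return probability in `[0, 1]`, strictly increasing in length.
#' @export
smolt_probability <- function(length_mm, params = smolt_params()) {
  stopifnot(all(length_mm > 0))
  stats::plogis((length_mm - params$L_s) / params$sigma_s)
}

#' Size-dependent marine survival
#'
#' @param length_mm fork length(s), mm (> 0).
#' @param params a [survival_params()] object.
#' @return survival in `[0, ceiling]`, non-decreasing in length.
#' @export
marine_survival <- function(length_mm, params = survival_params()) {
  stopifnot(all(length_mm > 0))
  s <- params$asymptote / (1 + exp(params$intercept - params$slope * length_mm))
  pmin(params$ceiling, s)
}

#' Length at which the marine-survival ceiling starts to bind
#'
#' Smallest whole-millimetre length at which the untruncated logistic
#' reaches the truncation ceiling; closed form
#' `ceil((intercept - ln(asymptote/ceiling - 1)) / slope)`.
#'
#' @param params a [survival_params()] object with `ceiling < asymptote`.
#' @return integer length in mm.
#' @export
cap_binding_length <- function(params = survival_params()) {
  if (params$ceiling >= params$asymptote) {
    stop("ceiling >= asymptote: truncation never binds")
  }
  as.integer(ceiling((params$intercept -
                        log(params$asymptote / params$ceiling - 1)) /
                       params$slope))
}

#' Smolt-equivalents of a juvenile cohort
#'
#' Abundance weighted by each fish's product of smolting probability and
#' size-dependent marine survival, evaluated on the 1 April length
#' distribution: `abundance * mean_i p(L_i) s(L_i)`. This is the predictor
#' (J* for wild fish, C* for captively-reared fish) of the size-conditional
#' adult model.
#'
#' @param april_lengths_mm individual fork lengths on 1 April, mm.
#' @param total_abundance cohort abundance the lengths represent (>= 0).
#' @param smolt a [smolt_params()] object.
#' @param survival a [survival_params()] object.
#' @return expected smolt-equivalents (numeric scalar).
#' @export
smolt_equivalents <- function(april_lengths_mm, total_abundance,
                              smolt = smolt_params(),
                              survival = survival_params()) {
  stopifnot(total_abundance >= 0)
  if (total_abundance == 0) return(0)
  if (length(april_lengths_mm) == 0) {
    stop("positive abundance but no length information")
  }
  per_capita <- mean(smolt_probability(april_lengths_mm, smolt) *
                       marine_survival(april_lengths_mm, survival))
  total_abundance * per_capita
}
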