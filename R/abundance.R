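#' Zippin removal estimate from 3-pass depletion counts
#'
#' Maximum-likelihood estimate of site abundance and per-pass capture
#' probability under the constant-probability removal model. The capture
#' probability is found by a 1-D search maximizing the profile likelihood
#' (with N profiled out as `T / (1 - q^3)`, `q = 1 - p`). When the catches
#' carry no depletion signal (the interior maximum does not exist, which
#' happens when `sum((i-1) c_i) >= T`), the estimate falls back to the total
#' catch with a method flag.
#'
#' @param counts integer vector of 3 per-pass catches.
#' @return list of class `abundance_estimate` with `n_hat`, `p_hat`,
#'   `method`, `counts`.
#' @export
zippin_three_pass <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) {
    return(new_abundance_estimate(0, NA_real_, "all_zero", counts))
  }
  # exhaustion: nothing caught after some pass and catch strictly declined to 0
  if (counts[2] == 0 && counts[3] == 0) {
    return(new_abundance_estimate(total, 1, "zippin3", counts))
  }
  x <- sum((seq_along(counts) - 1) * counts)
  k <- 3
  # interior MLE exists only if catches decline on average: x/T < (k-1)/2
  if (x / total >= (k - 1) / 2) {
    return(new_abundance_estimate(total, NA_real_, "total_catch_fallback",
                                  counts))
  }
  opt <- stats::optimize(function(p) removal_profile_loglik(counts, p),
                         interval = c(0.01, 0.9999), maximum = TRUE,
                         tol = 1e-8)
  p_hat <- opt$maximum
  n_hat <- total / (1 - (1 - p_hat)^k)
  new_abundance_estimate(n_hat, p_hat, "zippin3", counts)
}

# profile log-likelihood of the removal model at capture probability p:
# conditional on the total catch, pass counts are multinomial with cell
# probabilities p q^(i-1) / (1 - q^k), which profiles N out (the
# unconditional MLE then recovers N as T / (1 - q^k))
removal_profile_loglik <- function(counts, p) {
  k <- length(counts)
  q <- 1 - p
  cell <- p * q^(seq_len(k) - 1) / (1 - q^k)
  sum(counts * log(cell))
}

#' Seber-LeCren removal estimate from 2-pass depletion counts
#'
#' Closed form `N = c1^2 / (c1 - c2)`, `p = 1 - c2/c1`, valid when the
#' second-pass catch is below the first. Otherwise falls back to the total
#' catch with a method flag.
#'
#' @param counts integer vector of 2 per-pass catches.
#' @return list of class `abundance_estimate`.
#' @export
seber_lecren_two_pass <- function(counts) {
  stopifnot(length(counts) == 2, all(counts >= 0))
  c1 <- counts[1]; c2 <- counts[2]
  if (c1 == 0 && c2 == 0) {
    return(new_abundance_estimate(0, NA_real_, "all_zero", counts))
  }
  if (c1 <= c2) {
    return(new_abundance_estimate(c1 + c2, NA_real_, "total_catch_fallback",
                                  counts))
  }
  new_abundance_estimate(c1^2 / (c1 - c2), 1 - c2 / c1, "seber_lecren2",
                         counts)
}

new_abundance_estimate <- function(n_hat, p_hat, method, counts) {
  structure(list(n_hat = n_hat, p_hat = p_hat, method = method,
                 counts = counts),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Removal estimate (%s): N = %.1f, p = %s, catches = %s\n",
              x$method, x$n_hat,
              if (is.na(x$p_hat)) "NA" else sprintf("%.3f", x$p_hat),
              paste(x$counts, collapse = ", ")))
  invisible(x)
}

#' Estimate abundance from removal counts, dispatching on pass number
#'
#' @param counts per-pass catches (length 2 or 3).
#' @return list of class `abundance_estimate`.
#' @export
removal_estimate <- function(counts) {
  switch(as.character(length(counts)),
         "2" = seber_lecren_two_pass(counts),
         "3" = zippin_three_pass(counts),
         stop("removal estimation requires 2 or 3 passes"))
}

#' River-wide annual YOY abundance from site estimates
#'
#' Expands the mean young-of-the-year density across survey sites (fish per
#' longitudinal metre of channel) by the channel length between the upper
#' dam and the estuary: `J_t = mean_site(density) * channel_length_m`.
#'
#' @param site_estimates data.frame with columns `year`, `site`,
#'   `density_per_m` (YOY per metre at each surveyed site).
#' @param channel_length_m expansion length, metres (> 0).
#' @return data.frame with `year`, `J_t`, `n_sites`, `mean_density`.
#' @export
annual_yoy_abundance <- function(site_estimates, channel_length_m) {
  stopifnot(channel_length_m > 0,
            all(c("year", "density_per_m") %in% names(site_estimates)))
  keep <- !is.na(site_estimates$density_per_m)
  if (any(!keep)) {
    warning(sum(!keep), " site-year(s) without a density estimate excluded")
  }
  se <- site_estimates[keep, , drop = FALSE]
  years <- sort(unique(se$year))
  out <- data.frame(
    year = years,
    mean_density = vapply(years, function(y) {
      mean(se$density_per_m[se$year == y])
    }, numeric(1)),
    n_sites = vapply(years, function(y) sum(se$year == y), numeric(1))
  )
  out$J_t <- out$mean_density * channel_length_m
  out[, c("year", "J_t", "n_sites", "mean_density")]
}
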