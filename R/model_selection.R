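#' Small-sample Akaike information criterion from a residual sum of squares
#'
#' Computes AICc under the Gaussian likelihood for a least-squares fit,
#' \deqn{AICc = n \ln(RSS/n) + 2k + \frac{2k(k+1)}{n-k-1},}
#' where `k` counts all estimated parameters including the residual variance
#' (so a two-coefficient regression has `k = 3`).
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations.
#' @param k number of estimated parameters, coefficients plus one for the
#'   residual variance.
#' @return AICc value (numeric scalar).
#' @export
aicc_from_rss <- function(rss, n, k) {
  stopifnot(rss > 0, k >= 1)
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  }
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc from a Gaussian log-likelihood
#'
#' @param log_lik maximized log-likelihood.
#' @inheritParams aicc_from_rss
#' @return AICc value.
#' @export
aicc_from_loglik <- function(log_lik, n, k) {
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  }
  -2 * log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank a set of models by AICc
#'
#' Given per-model AICc scores, computes the AICc difference from the best
#' model (delta), Akaike weights, and evidence ratios against each model
#' (weight of the top model divided by the model's weight).
#'
#' @param scores data.frame with at least columns `name` and `aicc`; any
#'   other columns (e.g. `k`, `n`, `rss`) are carried through.
#' @return the input data.frame sorted by AICc with columns `delta`,
#'   `weight`, `evidence_ratio` and `support` appended.
#' @export
aic_table <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1,
            all(c("name", "aicc") %in% names(scores)))
  scores <- scores[order(scores$aicc), , drop = FALSE]
  scores$delta <- scores$aicc - min(scores$aicc)
  w <- exp(-scores$delta / 2)
  scores$weight <- w / sum(w)
  scores$evidence_ratio <- scores$weight[1] / scores$weight
  scores$support <- vapply(scores$delta, support_category, character(1))
  rownames(scores) <- NULL
  scores
}

#' Verbal support category for an AICc difference
#'
#' Delta below 2 indicates substantial support for a model despite not being
#' top-ranked; above 4, considerably less support; above 10, essentially no
#' support. Deltas in `[2, 4]` are labelled intermediate.
#'
#' @param delta AICc difference from the best model (>= 0).
#' @return one of `"substantial"`, `"intermediate"`, `"considerably_less"`,
#'   `"essentially_none"`.
#' @export
support_category <- function(delta) {
  stopifnot(delta >= 0)
  if (delta < 2) "substantial"
  else if (delta <= 4) "intermediate"
  else if (delta <= 10) "considerably_less"
  else "essentially_none"
}

#' Summed Akaike weight for a subset of models, expressed as odds
#'
#' @param tab output of [aic_table()].
#' @param names model names in the subset.
#' @return list with `summed_weight` and `odds` (= w / (1 - w)).
#' @export
summed_weight_odds <- function(tab, names) {
  w <- sum(tab$weight[tab$name %in% names])
  list(summed_weight = w, odds = w / (1 - w))
}
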