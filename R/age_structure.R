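#' Fit a K-component normal mixture to a length-frequency sample
#'
#' EM fit of the age-structure mixture: fish fork lengths are modelled as a
#' mixture of K normal components, one per age class, with weights alpha_k,
#' means mu_k and standard deviations sigma_k. Components are returned in
#' ascending order of mean; the smallest-mean component is interpreted as
#' young-of-the-year (YOY).
#'
#' Initialization is quantile-seeded k-means with `n_restarts` jittered
#' restarts (the first restart unjittered, so the fit is deterministic given
#' `seed`). Component standard deviations are floored at `var_floor` mm
#' (the measurement resolution of fork length) to prevent singular
#' components.
#'
#' @param lengths_mm positive fork lengths, mm; `n >= 3 K` required.
#' @param K number of age classes, 1-4.
#' @param n_restarts number of EM restarts.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per restart.
#' @param var_floor minimum component standard deviation, mm.
#' @param seed RNG seed for restart jitter (global RNG state is preserved).
#' @return object of class `mixture_fit`: `K`, `alpha`, `mu`, `sigma`,
#'   `log_likelihood`, `bic` (parameter count `3K - 1`), `assignments`
#'   (max-posterior component per fish), `posterior`, `yoy_index`,
#'   `loglik_trace` (per-iteration log-likelihood of the winning restart),
#'   `sigma_floored`, `n`.
#' @export
fit_mixture <- function(lengths_mm, K, n_restarts = 20, tol = 1e-6,
                        max_iter = 500, var_floor = 1, seed = 1) {
  stopifnot(all(lengths_mm > 0), K >= 1, K <= 4)
  x <- as.numeric(lengths_mm)
  n <- length(x)
  if (n < 3 * K) {
    stop("insufficient sample for K = ", K, " (n = ", n, " < ", 3 * K, ")")
  }
  if (K == 1) {
    mu <- mean(x)
    sigma <- max(var_floor, stats::sd(x) * sqrt((n - 1) / n))
    if (is.na(sigma)) sigma <- var_floor
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(new_mixture_fit(1, 1, mu, sigma, ll, rep(1L, n),
                           matrix(1, n, 1), ll, sigma == var_floor, n))
  }

  base_centers <- stats::quantile(x, probs = (2 * seq_len(K) - 1) / (2 * K),
                                  names = FALSE)
  jitter_sd <- max(stats::sd(x), var_floor) / 4

  best <- NULL
  local_rng({
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      centers <- if (r == 1) base_centers else
        sort(base_centers + stats::rnorm(K, 0, jitter_sd))
      fit <- em_mixture_once(x, centers, tol, max_iter, var_floor)
      if (is.null(best) || fit$log_likelihood > best$log_likelihood + 1e-12) {
        best <- fit
      }
    }
  })

  ord <- order(best$mu)
  post <- best$posterior[, ord, drop = FALSE]
  new_mixture_fit(K, best$alpha[ord], best$mu[ord], best$sigma[ord],
                  best$log_likelihood,
                  max.col(post, ties.method = "first"),
                  post, best$loglik_trace, best$sigma_floored, n)
}

# one EM run from given centers (k-means refinement, then compiled EM
# iterations); returns unordered components
em_mixture_once <- function(x, centers, tol, max_iter, var_floor) {
  n <- length(x)
  K <- length(centers)
  km <- tryCatch(
    stats::kmeans(x, centers = matrix(centers, ncol = 1), iter.max = 50),
    error = function(e) NULL)
  if (!is.null(km) && all(km$size > 0)) {
    mu <- as.numeric(km$centers)
    alpha <- km$size / n
    sigma <- vapply(seq_len(K), function(k) {
      xs <- x[km$cluster == k]
      s <- if (length(xs) > 1) stats::sd(xs) else 0
      max(s, var_floor)
    }, numeric(1))
  } else {
    mu <- centers
    alpha <- rep(1 / K, K)
    sigma <- rep(max(stats::sd(x) / K, var_floor), K)
  }
  em_mix_core(x, alpha, mu, sigma, tol, max_iter, var_floor)
}

new_mixture_fit <- function(K, alpha, mu, sigma, log_likelihood, assignments,
                            posterior, loglik_trace, sigma_floored, n) {
  p <- 3 * K - 1
  structure(list(
    K = K, alpha = alpha, mu = mu, sigma = sigma,
    log_likelihood = log_likelihood,
    bic = -2 * log_likelihood + p * log(n),
    assignments = assignments, posterior = posterior,
    yoy_index = 1L, loglik_trace = loglik_trace,
    sigma_floored = sigma_floored, n = n
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Normal mixture, K = %d age classes (n = %d, BIC = %.1f)\n",
              x$K, x$n, x$bic))
  for (k in seq_len(x$K)) {
    cat(sprintf("  class %d: weight %.3f, mean %.1f mm, sd %.1f mm\n",
                k, x$alpha[k], x$mu[k], x$sigma[k]))
  }
  invisible(x)
}

#' Select the number of age classes by BIC
#'
#' Fits mixtures with 1 to `k_max` components to a site-year length sample
#' and returns the fit minimizing BIC (`-2 logL + (3K - 1) ln n`). Values of
#' K with fewer than `3 K` fish are skipped; BIC ties are broken toward the
#' smaller K (parsimony).
#'
#' @inheritParams fit_mixture
#' @param k_max largest number of age classes considered.
#' @param ... passed to [fit_mixture()].
#' @return the selected `mixture_fit`, with `bic_by_k` (named vector over
#'   the candidate K) attached.
#' @export
select_age_model <- function(lengths_mm, k_max = 4, ...) {
  n <- length(lengths_mm)
  ks <- seq_len(k_max)[3 * seq_len(k_max) <= n]
  if (length(ks) == 0) stop("sample too small to fit even one age class")
  fits <- lapply(ks, function(K) fit_mixture(lengths_mm, K, ...))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]  # which.min returns the first (smallest K)
  best$bic_by_k <- stats::setNames(bics, ks)
  best
}

#' Summarize the YOY component of a mixture fit
#'
#' Counts are from hard (max-posterior) assignments; the fraction is the
#' assigned-YOY count over the sample size. Mean and sd are the fitted YOY
#' component parameters, which also describe uncaptured fish under the
#' assumption that they share the observed length distribution.
#'
#' @param fit a `mixture_fit`.
#' @return list with `yoy_count`, `yoy_mean_mm`, `yoy_sd_mm`, `yoy_fraction`
#'   and `yoy_weight` (the posterior-weighted fraction, i.e. the fitted
#'   component weight).
#' @export
yoy_summary <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  idx <- fit$yoy_index
  count <- sum(fit$assignments == idx)
  list(yoy_count = count,
       yoy_mean_mm = fit$mu[idx],
       yoy_sd_mm = fit$sigma[idx],
       yoy_fraction = count / fit$n,
       yoy_weight = fit$alpha[idx])
}

# evaluate a block with a private RNG stream, restoring global state after
local_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  eval.parent(substitute(expr))
}
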