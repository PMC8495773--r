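#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Unequal-variance mixture with `n_components` components. Initialization is
#' deterministic: component means at evenly spaced quantiles of the data,
#' equal weights, and the pooled sample variance for every component, so a
#' given input always yields the same fit; `n_restarts` adds seeded
#' mean-jittered restarts and keeps the best log-likelihood. Variances are
#' floored at `1e-6 * var(values)` to prevent components collapsing onto
#' single points.
#'
#' @param values Numeric vector of finite observations.
#' @param n_components Number of mixture components (>= 1).
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default `1e-6`).
#' @param max_iter Maximum EM iterations (default 500).
#' @param n_restarts Additional randomly initialized runs (default 0).
#' @param seed Seed for the restart jitter; ignored when `n_restarts = 0`.
#' @return A `gmm_fit` object: tibble `components` (columns `weight`, `mean`,
#'   `variance`, sorted by mean), `log_likelihood`, the per-iteration
#'   `loglik_trace`, `n_iter`, and `converged`.
#' @examples
#' fit <- fit_gmm(c(rnorm(100), rnorm(100, 8)), 2)
#' tidy(fit)
#' @export
fit_gmm <- function(values, n_components, tol = 1e-6, max_iter = 500L,
                    n_restarts = 0L, seed = NULL) {
  if (!is.numeric(values) || !all(is.finite(values))) {
    abort("`values` must be a finite numeric vector.")
  }
  if (n_components < 1 || n_components > length(values)) {
    abort("`n_components` must be between 1 and the number of observations.")
  }
  if (length(unique(values)) == 1L) {
    abort("all values are identical; a Gaussian mixture cannot be fit.")
  }
  k <- as.integer(n_components)
  init0 <- list(
    means = unname(quantile(values, probs = seq_len(k) / (k + 1))),
    weights = rep(1 / k, k),
    variances = rep(var(values), k)
  )
  best <- em_run(values, init0, tol, max_iter)
  if (n_restarts > 0) {
    spread <- sd(values)
    jitters <- withr::with_seed(seed %||% 1L, {
      replicate(n_restarts, rnorm(k, 0, spread / 2), simplify = FALSE)
    })
    for (jit in jitters) {
      init <- init0
      init$means <- sort(init0$means + jit)
      cand <- try(em_run(values, init, tol, max_iter), silent = TRUE)
      if (!inherits(cand, "try-error") &&
        cand$log_likelihood > best$log_likelihood) {
        best <- cand
      }
    }
  }
  best
}

em_run <- function(x, init, tol, max_iter) {
  n <- length(x)
  k <- length(init$means)
  w <- init$weights
  mu <- init$means
  v <- init$variances
  floor_v <- 1e-6 * var(x)
  v <- pmax(v, floor_v)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  ll_prev <- -Inf
  repeat {
    iter <- iter + 1L
    # E step in log space for numerical stability
    logd <- vapply(seq_len(k), function(j) {
      log(w[j]) + dnorm(x, mu[j], sqrt(v[j]), log = TRUE)
    }, numeric(n))
    logd <- matrix(logd, nrow = n)
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    # M step
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- vapply(seq_len(k), function(j) {
      sum(resp[, j] * (x - mu[j])^2) / nk[j]
    }, numeric(1))
    v <- pmax(v, floor_v)
    if (is.finite(ll_prev) &&
      abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  ord <- order(mu)
  structure(
    list(
      components = tibble(weight = w[ord], mean = mu[ord], variance = v[ord]),
      log_likelihood = trace[length(trace)],
      loglik_trace = trace,
      n_iter = iter,
      converged = converged,
      n_obs = n
    ),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> ", nrow(x$components), " component(s), logLik ",
    signif(x$log_likelihood, 6),
    if (x$converged) ", converged" else ", NOT converged",
    " in ", x$n_iter, " iteration(s)\n",
    sep = ""
  )
  print(x$components)
  invisible(x)
}

#' @describeIn fit_gmm Component table (weight, mean, variance) as a tibble.
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gmm_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(), .before = 1L)
}

#' @describeIn fit_gmm One-row fit summary.
#' @exportS3Method generics::glance
glance.gmm_fit <- function(x, ...) {
  tibble(
    n_components = nrow(x$components),
    log_likelihood = x$log_likelihood,
    n_iter = x$n_iter,
    converged = x$converged,
    n_obs = x$n_obs
  )
}

#' Posterior component assignments under a fitted mixture
#'
#' Bayes-rule posterior probabilities of each component for every sample; the
#' hard label is the argmax. The reported `posterior` is the classification
#' reliability (1 minus the classification uncertainty).
#'
#' @param fit A `gmm_fit`.
#' @param values Numeric observations.
#' @param sample_ids Character ids aligned with `values`.
#' @return Tibble with `sample_id`, `value`, `component` (argmax), `posterior`
#'   (its probability), and one `p<j>` column per component.
#' @export
posterior_assignments <- function(fit, values, sample_ids) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (length(values) != length(sample_ids)) {
    abort("`values` and `sample_ids` must have the same length.")
  }
  comp <- fit$components
  k <- nrow(comp)
  logd <- vapply(seq_len(k), function(j) {
    log(comp$weight[j]) + dnorm(values, comp$mean[j], sqrt(comp$variance[j]), log = TRUE)
  }, numeric(length(values)))
  logd <- matrix(logd, nrow = length(values))
  m <- apply(logd, 1L, max)
  post <- exp(logd - (m + log(rowSums(exp(logd - m)))))
  hard <- max.col(post, ties.method = "first")
  out <- tibble(
    sample_id = as.character(sample_ids),
    value = as.numeric(values),
    component = hard,
    posterior = post[cbind(seq_along(hard), hard)]
  )
  colnames(post) <- paste0("p", seq_len(k))
  dplyr::bind_cols(out, as_tibble(post))
}

#' Apply the reliability, cluster-size and extra-cluster filters
#'
#' The `k` detected density peaks are matched to the `k + 1` fitted components
#' by nearest mean (greedy, closest pair first, without replacement). The one
#' unmatched component is the extra, outlier-absorbing cluster: all of its
#' samples are discarded. Samples whose classification reliability (maximum
#' posterior) is not above `min_posterior` are discarded, and any matched
#' cluster holding fewer than `min_cluster_frac * n_total` samples is
#' discarded wholesale. Every discarded sample carries one reason:
#' `extra_cluster`, `small_cluster`, or `low_reliability`.
#'
#' @param assignments Tibble from [posterior_assignments()].
#' @param fit The `gmm_fit` behind the assignments (k + 1 components).
#' @param peak_locations The k detected peak locations, on the same scale as
#'   the fitted data.
#' @param min_posterior Retain samples with posterior strictly above this
#'   (default 0.46).
#' @param min_cluster_frac Minimum matched-cluster size as a fraction of
#'   `n_total` (default 0.10).
#' @param n_total Denominator for the cluster-size rule; defaults to the
#'   number of assigned samples.
#' @return A list with tibbles `retained` (`sample_id`, `value`, `component`,
#'   `peak`, `posterior`) and `discarded` (same plus `reason`), and the
#'   peak-to-component `matching` tibble.
#' @export
select_retained_samples <- function(assignments, fit, peak_locations,
                                    min_posterior = 0.46,
                                    min_cluster_frac = 0.10,
                                    n_total = nrow(assignments)) {
  stopifnot(inherits(fit, "gmm_fit"))
  k <- length(peak_locations)
  if (k < 1) abort("`peak_locations` must hold at least one peak.")
  if (nrow(fit$components) != k + 1L) {
    abort(sprintf(
      "fit has %d components but %d peaks were supplied; expected k + 1 = %d.",
      nrow(fit$components), k, k + 1L
    ))
  }
  means <- fit$components$mean
  # greedy nearest-mean matching, closest pair first, without replacement
  dist <- abs(outer(peak_locations, means, "-"))
  match_comp <- rep(NA_integer_, k)
  free_p <- seq_len(k)
  free_c <- seq_len(k + 1L)
  for (step in seq_len(k)) {
    sub <- dist[free_p, free_c, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    match_comp[free_p[ij[1L]]] <- free_c[ij[2L]]
    free_p <- free_p[-ij[1L]]
    free_c <- free_c[-ij[2L]]
  }
  extra <- free_c
  peak_of_comp <- rep(NA_integer_, k + 1L)
  peak_of_comp[match_comp] <- seq_len(k)

  a <- assignments
  sizes <- tabulate(a$component, nbins = k + 1L)
  small <- setdiff(which(sizes < min_cluster_frac * n_total), extra)

  reason <- rep(NA_character_, nrow(a))
  reason[a$component == extra] <- "extra_cluster"
  reason[is.na(reason) & a$component %in% small] <- "small_cluster"
  reason[is.na(reason) & a$posterior <= min_posterior] <- "low_reliability"

  a$peak <- peak_of_comp[a$component]
  keep <- is.na(reason)
  retained <- dplyr::select(
    a[keep, , drop = FALSE],
    "sample_id", "value", "component", "peak", "posterior"
  )
  discarded <- dplyr::mutate(
    dplyr::select(
      a[!keep, , drop = FALSE],
      "sample_id", "value", "component", "peak", "posterior"
    ),
    reason = reason[!keep]
  )
  list(
    retained = retained,
    discarded = discarded,
    matching = tibble(
      peak = seq_len(k),
      component = match_comp,
      peak_location = peak_locations,
      component_mean = means[match_comp]
    ),
    extra_component = extra
  )
}
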