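test_that("EM recovers a well-separated two-component mixture", {
  x <- withr::with_seed(3, c(rnorm(200, 0), rnorm(200, 8)))
  fit <- fit_gmm(x, 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$components$mean[1] - 0), 0.3)
  expect_lt(abs(fit$components$mean[2] - 8), 0.3)
  expect_lt(abs(fit$components$weight[1] - 0.5), 0.1)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-8)
})

test_that("a single component reduces to the closed-form Gaussian MLE", {
  x <- withr::with_seed(4, rnorm(150, 3, 2))
  fit <- fit_gmm(x, 1)
  expect_equal(fit$components$mean, mean(x), tolerance = 1e-8)
  expect_equal(fit$components$variance, mean((x - mean(x))^2), tolerance = 1e-6)
  expect_equal(fit$components$weight, 1)
})

test_that("the log-likelihood trace is non-decreasing on varied inputs", {
  for (s in 1:8) {
    x <- withr::with_seed(s, c(
      rlnorm(120, 0, 0.6),
      rnorm(80, 5 + s, 1 + s / 10)
    ))
    fit <- fit_gmm(x, 3)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("EM rejects degenerate inputs", {
  expect_error(fit_gmm(c(1, 2), 3), "between 1 and")
  expect_error(fit_gmm(rep(2, 10), 2), "identical")
  expect_error(fit_gmm(c(1, NA, 3), 2), "finite")
})

test_that("EM reaches a near-global optimum on tiny inputs (restart oracle)", {
  for (s in 1:3) {
    x <- withr::with_seed(100 + s, c(rnorm(6, 0, 0.5), rnorm(6, 4, 0.5)))
    for (k in 1:2) {
      fit <- fit_gmm(x, k)
      best <- max(vapply(1:200, function(r) {
        jfit <- try(
          withr::with_seed(r, {
            init <- list(
              means = sort(runif(k, min(x), max(x))),
              weights = rep(1 / k, k),
              variances = rep(var(x) * runif(1, 0.1, 2), k)
            )
            bimodetect:::em_run(x, init, 1e-6, 500)$log_likelihood
          }),
          silent = TRUE
        )
        if (inherits(jfit, "try-error")) -Inf else jfit
      }, numeric(1)))
      expect_gte(fit_gmm(x, k, n_restarts = 25, seed = 9)$log_likelihood, best - 1e-4)
      expect_gte(fit$log_likelihood, best - 0.5) # deterministic init is close
    }
  }
})

test_that("fitted mixture agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- withr::with_seed(11, c(rnorm(250, 1, 0.7), rnorm(250, 6, 1.2)))
  fit <- fit_gmm(x, 2)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$components$mean), sort(unname(mc$parameters$mean)),
    tolerance = 0.05
  )
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 1e-3)
})

test_that("posteriors follow Bayes rule: symmetry, certainty, normalization", {
  fit <- structure(
    list(
      components = tibble::tibble(
        weight = c(0.5, 0.5), mean = c(0, 4), variance = c(1, 1)
      ),
      log_likelihood = 0, loglik_trace = 0, n_iter = 1L,
      converged = TRUE, n_obs = 2L
    ),
    class = "gmm_fit"
  )
  a <- posterior_assignments(fit, c(2, 0, 8), c("mid", "at_mean", "far"))
  expect_equal(a$p1 + a$p2, rep(1, 3))
  expect_equal(a$posterior[a$sample_id == "mid"], 0.5)
  # x at one mean, other mean 8 pooled-sd away (x = 8 vs means 0 and 4... 4 sd)
  fit$components$mean <- c(0, 8)
  a2 <- posterior_assignments(fit, 8, "s")
  expect_gt(a2$posterior, 0.999)
  expect_equal(a2$component, 2L)
  expect_error(posterior_assignments(fit, 1:3, c("a", "b")), "length")
})

test_that("sample filters fire with the documented reasons", {
  # three components 45% / 40% / 15%; peaks sit near the two big ones
  x <- withr::with_seed(21, c(
    rnorm(225, 0, 0.5), rnorm(200, 5, 0.5), rnorm(75, 12, 0.4)
  ))
  fit <- fit_gmm(x, 3)
  a <- posterior_assignments(fit, x, sprintf("S%03d", seq_along(x)))
  sel <- select_retained_samples(a, fit, peak_locations = c(0, 5))
  extra <- dplyr::filter(sel$discarded, reason == "extra_cluster")
  # the 15% component (true members 426:500) is the unmatched extra cluster
  expect_gte(nrow(extra), 70)
  expect_true(all(extra$value > 9))
  expect_true(all(sel$retained$value < 9))

  # low reliability: posterior 0.40 <= 0.46 is discarded
  idx_border <- which(a$posterior <= 0.46)
  if (length(idx_border) > 0) {
    expect_true(all(a$sample_id[idx_border] %in% sel$discarded$sample_id))
  }

  # small matched cluster (8% < 10%) discarded wholesale
  x2 <- withr::with_seed(22, c(
    rnorm(552, 0, 0.4), rnorm(48, 6, 0.3), rnorm(0)
  ))
  fit2 <- fit_gmm(x2, 3)
  a2 <- posterior_assignments(fit2, x2, sprintf("T%03d", seq_along(x2)))
  sel2 <- select_retained_samples(a2, fit2, peak_locations = c(0, 6))
  small <- dplyr::filter(sel2$discarded, reason == "small_cluster")
  expect_gt(nrow(small), 0)
  expect_true(all(small$value > 3))
})

test_that("retained and discarded partition the input and the filter is monotone", {
  x <- withr::with_seed(23, c(rnorm(250, 0), rnorm(250, 6)))
  fit <- fit_gmm(x, 3)
  a <- posterior_assignments(fit, x, sprintf("S%03d", seq_along(x)))
  prev <- -1L
  for (mp in c(0.9, 0.7, 0.46, 0.2, 0)) {
    sel <- select_retained_samples(a, fit, c(0, 6), min_posterior = mp)
    ids <- c(sel$retained$sample_id, sel$discarded$sample_id)
    expect_setequal(ids, a$sample_id)
    expect_false(any(duplicated(ids)))
    expect_gte(nrow(sel$retained), prev)
    prev <- nrow(sel$retained)
  }
  expect_error(
    select_retained_samples(a, fit, c(0, 3, 6)),
    "k \\+ 1"
  )
})

test_that("identical inputs give identical fits and retained sets", {
  x <- withr::with_seed(31, c(rnorm(150), rnorm(150, 5)))
  f1 <- fit_gmm(x, 3, n_restarts = 5, seed = 77)
  f2 <- fit_gmm(x, 3, n_restarts = 5, seed = 77)
  expect_identical(f1$components, f2$components)
  a1 <- posterior_assignments(f1, x, as.character(seq_along(x)))
  s1 <- select_retained_samples(a1, f1, c(0, 5))
  s2 <- select_retained_samples(a1, f2, c(0, 5))
  expect_identical(s1$retained, s2$retained)
})
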