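# Shared fixture builders; everything is generated in code at test time.

two_mode_sample <- function(n_per = 500, mu1 = 0, mu2 = 6, sd = 1, seed = 42) {
  withr::with_seed(seed, c(rnorm(n_per, mu1, sd), rnorm(n_per, mu2, sd)))
}

# Analytic mixture density evaluated directly on a grid (no sampling);
# detection on this curve is checked against the known modes.
analytic_mixture_curve <- function(means, sds, weights,
                                   from = min(means) - 4 * max(sds),
                                   to = max(means) + 4 * max(sds)) {
  grid <- seq(from, to, length.out = 512)
  y <- rowSums(mapply(
    function(m, s, w) w * dnorm(grid, m, s),
    means, sds, weights
  ))
  out <- tibble::tibble(x = grid, y = y)
  class(out) <- c("density_curve", class(out))
  out
}

# Cohort specs with planted bimodal genes at a given log-scale separation
# (in units of the within-mode sd) among log-normal unimodal genes.
planted_cohort_specs <- function(n_bimodal, n_unimodal, separation_sd = 5,
                                 mode_sd = 0.5) {
  delta <- separation_sd * mode_sd
  dplyr::bind_rows(
    purrr::map(seq_len(n_bimodal), function(i) {
      gene_spec(sprintf("BM%03d", i), "bimodal",
        mode1_mean = 1, mode2_mean = exp(delta), mode_sd = mode_sd
      )
    }),
    purrr::map(seq_len(n_unimodal), function(i) {
      gene_spec(sprintf("UM%03d", i), "unimodal",
        mode1_mean = 2 + (i %% 7), mode_sd = 0.5 + 0.02 * (i %% 5)
      )
    })
  )
}

log2_config <- function(seed = 1L, ...) {
  detection_config(use_log = "log2", seed = seed, ...)
}

# Direct product-limit estimator used as an oracle for the survival module.
km_oracle <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(times >= ts[i])
    d_i <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  tibble::tibble(time = ts, survival = out)
}
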