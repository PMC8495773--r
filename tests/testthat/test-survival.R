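test_that("Kaplan-Meier matches the closed-form product-limit estimate", {
  # one event at t = 2 among 4 subjects -> S drops to 0.75
  km <- kaplan_meier(c(2, 5, 6, 8), c(1, 0, 0, 0))
  expect_equal(km$survival[km$time == 2], 0.75)
  expect_true(all(km$survival[km$time < 2] == 1))
  # two events, no censoring
  km2 <- kaplan_meier(c(1, 2), c(1, 1))
  expect_equal(km2$survival, c(0.5, 0))
  # no events at all -> S identically 1
  km0 <- kaplan_meier(c(3, 4, 5), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "positive")
})

test_that("Kaplan-Meier agrees with a direct oracle and is non-increasing", {
  for (s in 1:5) {
    n <- 30 + 5 * s
    tm <- withr::with_seed(s, rexp(n, 0.01))
    ev <- withr::with_seed(s + 100, rbinom(n, 1, 0.7))
    if (sum(ev) == 0) ev[1] <- 1
    km <- kaplan_meier(tm, ev)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    oracle <- km_oracle(tm, ev)
    got <- km$survival[match(oracle$time, km$time)]
    expect_equal(got, oracle$survival, tolerance = 1e-10)
  }
})

test_that("log-rank statistic matches the hand-computed risk-set table", {
  # pooled risk sets: t=1 (4 at risk, event in A), t=2 (3 at risk, event in A),
  # then B's events with A exhausted: O1 = 2, E1 = 5/6, V = 0.25 + 2/9
  res <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(res$chi_square, (2 - 5 / 6)^2 / (0.25 + 2 / 9), tolerance = 1e-6)
  expect_equal(res$chi_square, 2.882, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0896, tolerance = 1e-3)
  expect_equal(res$events_group1, 2L)
  expect_equal(res$events_group2, 2L)
})

test_that("log-rank is symmetric in group labels and null on identical groups", {
  tm <- c(5, 8, 12, 20, 33, 40)
  ev <- c(1, 0, 1, 1, 0, 1)
  same <- logrank_test(tm, ev, tm, ev)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  a <- logrank_test(tm, ev, tm * 2, ev)
  b <- logrank_test(tm * 2, ev, tm, ev)
  expect_equal(a$chi_square, b$chi_square)
  expect_equal(a$p_value, b$p_value)
  expect_warning(
    zero <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
    "no events"
  )
  expect_equal(zero$chi_square, 0)
  expect_equal(zero$p_value, 1)
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("log-rank p-value agrees with a permutation null on small fixtures", {
  n <- 36
  tm <- withr::with_seed(61, rexp(n, 1 / 50))
  ev <- withr::with_seed(62, rbinom(n, 1, 0.8))
  grp <- rep(c(1, 2), each = n / 2)
  obs <- logrank_test(tm[grp == 1], ev[grp == 1], tm[grp == 2], ev[grp == 2])
  perm_chi <- withr::with_seed(63, {
    vapply(seq_len(2000), function(i) {
      g <- sample(grp)
      logrank_test(tm[g == 1], ev[g == 1], tm[g == 2], ev[g == 2])$chi_square
    }, numeric(1))
  })
  p_perm <- mean(perm_chi >= obs$chi_square - 1e-12)
  expect_lt(abs(p_perm - obs$p_value), 0.02)
})

test_that("the prognosis screen flags hazard differences and logs exclusions", {
  strat <- tibble::tibble(
    gene_id = "g1", cohort_label = "SIM",
    sample_id = sprintf("P%03d", 1:300),
    peak = rep(c("peak1", "peak2"), each = 150),
    posterior = 0.99
  )
  labels <- tibble::tibble(
    sample_id = strat$sample_id,
    mode = rep(1:2, each = 150)
  )
  clin <- simulate_survival(labels, hazard_ratio = 3, censoring_rate = 0.2, seed = 5)
  rec <- prognosis_screen(strat, clin, verbose = FALSE)
  expect_equal(nrow(rec), 1L)
  expect_true(rec$significant_01)
  expect_true(rec$significant_05)

  # stratified samples missing from the clinical table are dropped with a log
  clin_part <- clin[-(1:10), ]
  expect_message(
    rec2 <- prognosis_screen(strat, clin_part, verbose = TRUE),
    "absent"
  )
  expect_equal(rec2$n_group1, 140L)

  # a gene whose peak2 group has no clinical overlap is excluded
  strat2 <- dplyr::bind_rows(
    strat,
    tibble::tibble(
      gene_id = "g2", cohort_label = "SIM",
      sample_id = c(strat$sample_id[1:20], sprintf("Q%03d", 1:20)),
      peak = rep(c("peak1", "peak2"), each = 20), posterior = 0.9
    )
  )
  expect_message(
    rec3 <- prognosis_screen(strat2, clin, verbose = TRUE),
    "excluded"
  )
  expect_equal(rec3$gene_id, "g1")
  expect_equal(nrow(attr(rec3, "excluded")), 1L)
  expect_error(
    prognosis_screen(strat, dplyr::mutate(clin, sample_id = paste0("Z", sample_id)),
      verbose = FALSE
    ),
    "no stratified sample"
  )
})

test_that("significance at 1% implies significance at 5% and BH column is optional", {
  strat <- tibble::tibble(
    gene_id = rep(sprintf("g%d", 1:6), each = 60),
    cohort_label = "SIM",
    sample_id = rep(sprintf("P%03d", 1:60), times = 6),
    peak = rep(rep(c("peak1", "peak2"), each = 30), times = 6),
    posterior = 0.9
  )
  labels <- tibble::tibble(sample_id = sprintf("P%03d", 1:60), mode = rep(1:2, each = 30))
  clin <- simulate_survival(labels, hazard_ratio = 2, censoring_rate = 0.1, seed = 8)
  rec <- prognosis_screen(strat, clin, adjust = TRUE, verbose = FALSE)
  expect_true(all(!rec$significant_01 | rec$significant_05))
  expect_true("p_adjusted" %in% names(rec))
  expect_true(all(rec$p_adjusted >= rec$p_value))
})

test_that("barcode truncation reconciles expression and clinical id styles", {
  strat <- tibble::tibble(
    gene_id = "g1", cohort_label = "C",
    sample_id = sprintf("TCGA-%02d-0001-01A", 1:40),
    peak = rep(c("peak1", "peak2"), each = 20), posterior = 0.9
  )
  clin <- tibble::tibble(
    sample_id = sprintf("TCGA-%02d-0001", 1:40),
    os_time = withr::with_seed(9, rexp(40, 1 / 100)),
    os_event = rep(c(1L, 0L), 20)
  )
  expect_error(prognosis_screen(strat, clin, verbose = FALSE), "no stratified")
  rec <- prognosis_screen(strat, clin, truncate_barcode = 12, verbose = FALSE)
  expect_equal(rec$n_group1 + rec$n_group2, 40L)
})
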