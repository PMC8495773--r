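#' Build a one-gene simulation spec
#'
#' Helper constructing one row of the gene-spec table consumed by
#' [simulate_cohort()]. Expression for each mode is log-normal: values are
#' `exp(N(log(mode_mean), mode_sd))`, so `mode_mean` is the mode's median
#' expression (FPKM) and `mode_sd` its spread on the natural-log scale.
#'
#' @param gene_id Gene identifier.
#' @param kind `"bimodal"`, `"unimodal"`, or `"noise_floor"` (a gene expressed
#'   mostly below the 0.02 FPKM floor).
#' @param mode1_mean Median expression of mode 1 (and the only mode for
#'   unimodal / noise_floor genes).
#' @param mode2_mean Median expression of mode 2 (bimodal genes only; must
#'   exceed `mode1_mean`).
#' @param mode_sd Log-scale standard deviation within a mode.
#' @param mixing_weight Probability that a sample belongs to mode 1.
#' @param chromosome Optional chromosome label carried into the truth table.
#' @return One-row tibble.
#' @export
gene_spec <- function(gene_id, kind = c("bimodal", "unimodal", "noise_floor"),
                      mode1_mean = 1, mode2_mean = NA_real_, mode_sd = 0.5,
                      mixing_weight = 0.5, chromosome = NA_character_) {
  kind <- match.arg(kind)
  tibble(
    gene_id = as.character(gene_id), kind = kind,
    mode1_mean = mode1_mean, mode2_mean = mode2_mean,
    mode_sd = mode_sd, mixing_weight = mixing_weight,
    chromosome = as.character(chromosome)
  )
}

validate_gene_specs <- function(specs) {
  need <- c("gene_id", "kind", "mode1_mean", "mode2_mean", "mode_sd", "mixing_weight")
  missing_cols <- setdiff(need, names(specs))
  if (length(missing_cols) > 0L) {
    abort(sprintf("gene spec lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    bad <- function(msg) abort(sprintf("invalid spec for gene '%s': %s", s$gene_id, msg))
    if (!s$kind %in% c("bimodal", "unimodal", "noise_floor")) bad("unknown kind")
    if (!is.finite(s$mode1_mean) || s$mode1_mean <= 0) bad("mode1_mean must be > 0")
    if (!is.finite(s$mode_sd) || s$mode_sd <= 0) bad("mode_sd must be > 0")
    if (s$kind == "bimodal") {
      if (!is.finite(s$mode2_mean) || s$mode2_mean <= s$mode1_mean) {
        bad("bimodal genes need mode2_mean > mode1_mean")
      }
      if (!is.finite(s$mixing_weight) || s$mixing_weight < 0 || s$mixing_weight > 1) {
        bad("mixing_weight must lie in [0, 1]")
      }
    }
  }
  invisible(specs)
}

#' Simulate an expression cohort with known ground truth
#'
#' Generates a gene x sample FPKM matrix from per-gene specs. Each mode is
#' log-normal (positive support, right skew — the shape of real FPKM data);
#' bimodal genes mix two modes with probability `mixing_weight` for mode 1,
#' unimodal genes draw from mode 1 only, and `noise_floor` genes sit mostly
#' below the 0.02 FPKM analysis floor. Any negative value (impossible under
#' the log-normal, but guarded for custom generators) is clipped to 0. The
#' generating mode of every (gene, sample) pair is recorded.
#'
#' @param n_samples Number of samples (>= 2).
#' @param gene_specs Tibble of [gene_spec()] rows.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param cohort_label Label for the resulting matrix.
#' @return A `simulated_cohort` list: `expression` (an `expr_matrix`),
#'   `truth` (the spec table), `mode_labels` (tibble `gene_id`, `sample_id`,
#'   `mode`), and `seed`.
#' @examples
#' specs <- dplyr::bind_rows(
#'   gene_spec("G1", "bimodal", mode1_mean = 1, mode2_mean = 12),
#'   gene_spec("G2", "unimodal", mode1_mean = 5)
#' )
#' sim <- simulate_cohort(100, specs, seed = 1)
#' @export
simulate_cohort <- function(n_samples, gene_specs, seed, cohort_label = "SIM") {
  if (n_samples < 2) abort("`n_samples` must be >= 2.")
  if (nrow(gene_specs) == 0L) abort("`gene_specs` must be non-empty.")
  validate_gene_specs(gene_specs)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  out <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(nrow(gene_specs)), function(i) {
      s <- gene_specs[i, ]
      if (s$kind == "bimodal") {
        mode <- ifelse(runif(n_samples) < s$mixing_weight, 1L, 2L)
      } else {
        mode <- rep(1L, n_samples)
      }
      meanlog <- ifelse(mode == 1L, log(s$mode1_mean), log(s$mode2_mean))
      vals <- exp(rnorm(n_samples, meanlog, s$mode_sd))
      list(values = pmax(vals, 0), mode = mode)
    })
  })
  mat <- do.call(rbind, purrr::map(out, "values"))
  expr <- dplyr::bind_cols(
    tibble(gene_id = gene_specs$gene_id),
    as_tibble(setNames(as.data.frame(mat), sample_ids))
  )
  labels <- tibble(
    gene_id = rep(gene_specs$gene_id, each = n_samples),
    sample_id = rep(sample_ids, times = nrow(gene_specs)),
    mode = unlist(purrr::map(out, "mode"), use.names = FALSE)
  )
  structure(
    list(
      expression = as_expr_matrix(expr, cohort_label),
      truth = gene_specs,
      mode_labels = labels,
      seed = as.integer(seed)
    ),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(
    "<simulated_cohort> ", nrow(x$truth), " gene(s) x ",
    ncol(x$expression) - 1L, " sample(s), seed ", x$seed, "\n",
    sep = ""
  )
  print(table(x$truth$kind))
  invisible(x)
}

# Uniform-censoring horizon T such that P(C < E) hits the target censoring
# fraction when C ~ U(0, T) and E is exponential with the per-sample rates.
censoring_horizon <- function(rates, censoring_rate) {
  p_cens <- function(T) mean((1 - exp(-rates * T)) / (rates * T))
  uniroot(
    function(T) p_cens(T) - censoring_rate,
    lower = 1e-9, upper = 1e9 / mean(rates),
    extendInt = "downX", tol = 1e-10
  )$root
}

#' Simulate survival outcomes linked to expression modes
#'
#' Event times are exponential: rate `baseline_rate` for mode-1 samples and
#' `baseline_rate * hazard_ratio` for mode-2 samples. Censoring times are
#' uniform on `[0, T]` with the horizon `T` solved numerically so the
#' expected censoring fraction matches `censoring_rate`; with
#' `censoring_rate = 0` every record is an event.
#'
#' @param mode_labels Tibble `sample_id`, `mode` (1 or 2) for one gene, e.g. a
#'   slice of `simulate_cohort()$mode_labels`.
#' @param hazard_ratio Mode-2 vs mode-1 hazard ratio (> 0).
#' @param baseline_rate Mode-1 event rate per day (default 1/1000).
#' @param censoring_rate Target censoring fraction in `[0, 1)` (default 0.2).
#' @param seed Integer seed.
#' @return Clinical tibble: `sample_id`, `os_time` (days), `os_event`.
#' @export
simulate_survival <- function(mode_labels, hazard_ratio, baseline_rate = 1 / 1000,
                              censoring_rate = 0.2, seed = 1L) {
  stopifnot(is.data.frame(mode_labels), all(c("sample_id", "mode") %in% names(mode_labels)))
  if (nrow(mode_labels) == 0L) abort("`mode_labels` must be non-empty.")
  if (!is.finite(hazard_ratio) || hazard_ratio <= 0) abort("`hazard_ratio` must be > 0.")
  if (censoring_rate < 0 || censoring_rate >= 1) abort("`censoring_rate` must lie in [0, 1).")
  rates <- ifelse(mode_labels$mode == 2L, baseline_rate * hazard_ratio, baseline_rate)
  withr::with_seed(as.integer(seed), {
    e <- rexp(length(rates), rate = rates)
    if (censoring_rate == 0) {
      tm <- e
      ev <- rep(1L, length(e))
    } else {
      horizon <- censoring_horizon(rates, censoring_rate)
      cns <- runif(length(rates), 0, horizon)
      tm <- pmin(e, cns)
      ev <- as.integer(e <= cns)
    }
    tibble(
      sample_id = as.character(mode_labels$sample_id),
      os_time = pmax(tm, 1e-6),
      os_event = ev
    )
  })
}
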