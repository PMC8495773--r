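#' Detection configuration
#'
#' Bundles the seven tunable parameters of the bimodality detector plus the
#' random seed. Defaults follow the method's reference settings:
#' 0.02 FPKM minimum expression, 50-sample minimum cohort size, 10% minimum
#' cluster size, Threshold Up 10% and Threshold Down 20% of the maximum
#' density, derivative smoothing on, and no log transform.
#'
#' @param min_expression Minimum expression (FPKM); samples below it are
#'   excluded per gene before any analysis (default 0.02).
#' @param min_sample_size Genes with fewer surviving samples are skipped
#'   (default 50).
#' @param min_cluster_frac Minimum matched-cluster size as a fraction of the
#'   samples considered (default 0.10).
#' @param threshold_up Minimum adjacent peak-valley height gap, as a fraction
#'   of the maximum density (default 0.10).
#' @param threshold_down Minimum peak height, as a fraction of the maximum
#'   density (default 0.20).
#' @param smoothing Smooth the density derivative before peak calling
#'   (default `TRUE`).
#' @param use_log Transform expression before analysis: `"none"`, `"log2"`, or
#'   `"log10"` (default `"none"`).
#' @param min_posterior Retain samples whose classification posterior exceeds
#'   this (default 0.46).
#' @param seed Global seed; per-gene seeds are derived from it so results do
#'   not depend on gene order.
#' @return A `detection_config` list.
#' @export
detection_config <- function(min_expression = 0.02, min_sample_size = 50L,
                             min_cluster_frac = 0.10, threshold_up = 0.10,
                             threshold_down = 0.20, smoothing = TRUE,
                             use_log = c("none", "log2", "log10"),
                             min_posterior = 0.46, seed = 1L) {
  use_log <- match.arg(use_log)
  fracs <- c(
    min_cluster_frac = min_cluster_frac, threshold_up = threshold_up,
    threshold_down = threshold_down, min_posterior = min_posterior
  )
  if (any(fracs < 0 | fracs > 1)) {
    abort(sprintf(
      "fraction parameter out of [0, 1]: %s",
      paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", ")
    ))
  }
  if (min_expression < 0) abort("`min_expression` must be >= 0.")
  if (min_sample_size < 2) abort("`min_sample_size` must be >= 2.")
  structure(
    list(
      min_expression = min_expression,
      min_sample_size = as.integer(min_sample_size),
      min_cluster_frac = min_cluster_frac,
      threshold_up = threshold_up,
      threshold_down = threshold_down,
      smoothing = isTRUE(smoothing),
      use_log = use_log,
      min_posterior = min_posterior,
      seed = as.integer(seed)
    ),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' @describeIn detection_config Build a config from a named list (e.g. parsed
#'   from a JSON/YAML/`key = value` file); unknown names are an error.
#' @param x Named list of parameter overrides.
#' @export
as_detection_config <- function(x) {
  if (inherits(x, "detection_config")) {
    return(x)
  }
  stopifnot(is.list(x))
  known <- names(formals(detection_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(detection_config, x)
}

# Deterministic 31-bit hash of a gene id, combined with the global seed so
# per-gene randomness is independent of gene order.
gene_seed <- function(seed, gene_id) {
  h <- 0
  for (code in utf8ToInt(as.character(gene_id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Per-gene preprocessing: expression floor, size gate, log transform
#'
#' Drops samples expressed below `min_expression`, signals a skip when fewer
#' than `min_sample_size` samples survive, and applies the configured log
#' transform to the survivors.
#'
#' @param values Numeric expression values (FPKM) for one gene.
#' @param sample_ids Ids aligned with `values`.
#' @param config A [detection_config()].
#' @return A list: `skip` (logical), `n_used`, `n_dropped`, and — when not
#'   skipped — `values` (possibly log-transformed) and `sample_ids`.
#' @export
preprocess_gene <- function(values, sample_ids, config = detection_config()) {
  if (length(values) != length(sample_ids)) {
    abort("`values` and `sample_ids` must have the same length.")
  }
  keep <- values >= config$min_expression
  v <- values[keep]
  ids <- as.character(sample_ids)[keep]
  if (length(v) < config$min_sample_size) {
    return(list(
      skip = TRUE, n_used = length(v), n_dropped = sum(!keep),
      values = NULL, sample_ids = NULL
    ))
  }
  v <- switch(config$use_log,
    none = v,
    log2 = log2(v),
    log10 = log10(v)
  )
  list(skip = FALSE, n_used = length(v), n_dropped = sum(!keep), values = v, sample_ids = ids)
}

empty_call <- function(gene_id, cohort_label, status, n_used,
                       n_peaks_initial = NA_integer_,
                       n_peaks_confirmed = NA_integer_,
                       peak1_location = NA_real_, peak2_location = NA_real_,
                       peak1_n = NA_integer_, peak2_n = NA_integer_) {
  tibble(
    gene_id = gene_id, cohort_label = cohort_label, status = status,
    n_samples_used = as.integer(n_used),
    n_peaks_initial = as.integer(n_peaks_initial),
    n_peaks_confirmed = as.integer(n_peaks_confirmed),
    peak1_location = peak1_location, peak2_location = peak2_location,
    peak1_n = as.integer(peak1_n), peak2_n = as.integer(peak2_n)
  )
}

#' Analyze one gene for bimodal expression
#'
#' Runs the full three-step detection for a single gene: (a) density
#' estimation with the nrd0 bandwidth and derivative-based peak calling under
#' the two height thresholds; (b) if exactly two peaks are found, a
#' three-component Gaussian mixture is fit (two mode components plus one
#' extra cluster for low-affinity samples) and samples are filtered by the
#' reliability, cluster-size and extra-cluster rules; (c) peak detection is
#' re-run, with a recomputed bandwidth, on the retained samples, and the gene
#' is called bimodal only if two peaks are confirmed.
#'
#' @param values Expression values (FPKM) for the gene across samples.
#' @param sample_ids Ids aligned with `values`.
#' @param config A [detection_config()].
#' @param gene_id,cohort_label Identifiers recorded in the output.
#' @return A `gene_analysis` list: `call` (one-row tibble with `status` in
#'   `bimodal` / `unimodal` / `rejected_confirmation` / `skipped_min_samples`),
#'   `stratification` (tibble mapping retained samples to `peak1`/`peak2`;
#'   `NULL` unless bimodal), plus the `initial_peaks`, `confirmed_peaks`,
#'   `fit` and `selection` objects for inspection.
#' @export
analyze_gene <- function(values, sample_ids, config = detection_config(),
                         gene_id = "gene", cohort_label = "cohort") {
  pre <- preprocess_gene(values, sample_ids, config)
  res <- list(
    call = NULL, stratification = NULL, initial_peaks = NULL,
    confirmed_peaks = NULL, fit = NULL, selection = NULL
  )
  class(res) <- "gene_analysis"
  if (pre$skip) {
    res$call <- empty_call(gene_id, cohort_label, "skipped_min_samples", pre$n_used)
    return(res)
  }
  v <- pre$values
  ids <- pre$sample_ids

  run_peaks <- function(vv) {
    curve <- estimate_density(vv)
    detect_peaks(curve,
      threshold_up = config$threshold_up,
      threshold_down = config$threshold_down,
      smoothing = config$smoothing
    )
  }
  initial <- run_peaks(v)
  res$initial_peaks <- initial
  if (initial$n_peaks != 2L) {
    res$call <- empty_call(gene_id, cohort_label, "unimodal", pre$n_used,
      n_peaks_initial = initial$n_peaks
    )
    return(res)
  }

  fit <- withr::with_seed(
    gene_seed(config$seed, gene_id),
    fit_gmm(v, n_components = 3L)
  )
  res$fit <- fit
  assign <- posterior_assignments(fit, v, ids)
  sel <- select_retained_samples(
    assign, fit,
    peak_locations = initial$peaks$location,
    min_posterior = config$min_posterior,
    min_cluster_frac = config$min_cluster_frac,
    n_total = pre$n_used
  )
  res$selection <- sel

  if (nrow(sel$retained) < 2L || length(unique(sel$retained$value)) < 2L) {
    res$call <- empty_call(gene_id, cohort_label, "rejected_confirmation",
      pre$n_used,
      n_peaks_initial = 2L, n_peaks_confirmed = 0L
    )
    return(res)
  }
  confirmed <- run_peaks(sel$retained$value)
  res$confirmed_peaks <- confirmed
  if (confirmed$n_peaks != 2L) {
    res$call <- empty_call(gene_id, cohort_label, "rejected_confirmation",
      pre$n_used,
      n_peaks_initial = 2L, n_peaks_confirmed = confirmed$n_peaks
    )
    return(res)
  }

  # peak1 must be the lower-expression mode on the retained samples
  grp_mean <- tapply(sel$retained$value, sel$retained$peak, mean)
  relabel <- if (all(c("1", "2") %in% names(grp_mean)) &&
    grp_mean[["1"]] > grp_mean[["2"]]) {
    c(`1` = 2L, `2` = 1L)
  } else {
    c(`1` = 1L, `2` = 2L)
  }
  strat <- dplyr::transmute(
    sel$retained,
    gene_id = gene_id, cohort_label = cohort_label,
    sample_id = .data$sample_id,
    peak = paste0("peak", relabel[as.character(.data$peak)]),
    posterior = .data$posterior
  )
  counts <- table(factor(strat$peak, levels = c("peak1", "peak2")))
  if (any(counts == 0L)) {
    res$call <- empty_call(gene_id, cohort_label, "rejected_confirmation",
      pre$n_used,
      n_peaks_initial = 2L, n_peaks_confirmed = confirmed$n_peaks
    )
    return(res)
  }
  res$stratification <- strat
  res$call <- empty_call(gene_id, cohort_label, "bimodal", pre$n_used,
    n_peaks_initial = 2L, n_peaks_confirmed = 2L,
    peak1_location = confirmed$peaks$location[1L],
    peak2_location = confirmed$peaks$location[2L],
    peak1_n = counts[["peak1"]], peak2_n = counts[["peak2"]]
  )
  res
}

#' @export
print.gene_analysis <- function(x, ...) {
  print(x$call)
  invisible(x)
}

#' Analyze every gene of a cohort
#'
#' Applies [analyze_gene()] to each row of an expression matrix. Per-gene
#' seeds derive from `config$seed` and a stable hash of the gene id, so the
#' result is reproducible and independent of gene order.
#'
#' @param expr An `expr_matrix` (see [read_expression_matrix()]).
#' @param config A [detection_config()].
#' @param verbose Log per-status counts with a message (default `TRUE`).
#' @return List with `calls` (one row per gene) and `stratifications`
#'   (one row per retained sample of each bimodal gene).
#' @export
analyze_cohort <- function(expr, config = detection_config(), verbose = TRUE) {
  stopifnot(is.data.frame(expr))
  if (nrow(expr) == 0L || ncol(expr) < 2L) abort("empty expression matrix.")
  cohort <- attr(expr, "cohort_label") %||% "cohort"
  sample_ids <- names(expr)[-1L]
  rows <- purrr::map(seq_len(nrow(expr)), function(i) {
    g <- expr$gene_id[i]
    vals <- as.numeric(unlist(expr[i, -1L], use.names = FALSE))
    a <- analyze_gene(vals, sample_ids, config, gene_id = g, cohort_label = cohort)
    list(call = a$call, strat = a$stratification)
  })
  calls <- dplyr::bind_rows(purrr::map(rows, "call"))
  strat <- dplyr::bind_rows(purrr::compact(purrr::map(rows, "strat")))
  if (nrow(strat) == 0L) {
    strat <- tibble(
      gene_id = character(), cohort_label = character(),
      sample_id = character(), peak = character(), posterior = numeric()
    )
  }
  if (isTRUE(verbose)) {
    cnt <- table(calls$status)
    inform(sprintf(
      "cohort %s: %s",
      cohort, paste(names(cnt), as.integer(cnt), sep = "=", collapse = ", ")
    ))
  }
  list(calls = calls, stratifications = strat)
}

#' Summarize bimodal calls across cohorts
#'
#' @param calls Bimodal-call tibble (rows from one or more cohorts, e.g.
#'   `bind_rows()` of several [analyze_cohort()] results).
#' @param chrom_map Optional tibble `gene_id`, `chromosome` joined onto the
#'   multi-cohort list.
#' @return List with `per_cohort` (cohort, number of bimodal genes) and
#'   `multi_cohort` (genes bimodal in >= 2 cohorts with their cohort count,
#'   sorted descending).
#' @export
cross_cohort_summary <- function(calls, chrom_map = NULL) {
  stopifnot(is.data.frame(calls), nrow(calls) >= 1L)
  dup <- dplyr::count(calls, .data$gene_id, .data$cohort_label) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf(
      "duplicate (gene, cohort) call pair(s): %s",
      paste(paste(dup$gene_id, dup$cohort_label, sep = "/"), collapse = ", ")
    ))
  }
  bim <- dplyr::filter(calls, .data$status == "bimodal")
  per_cohort <- dplyr::count(
    dplyr::distinct(calls, .data$cohort_label),
    .data$cohort_label,
    name = "n_bimodal"
  )
  per_cohort$n_bimodal <- 0L
  if (nrow(bim) > 0L) {
    cc <- dplyr::count(bim, .data$cohort_label, name = "n_bimodal")
    per_cohort <- dplyr::rows_update(per_cohort, cc, by = "cohort_label")
  }
  multi <- dplyr::count(bim, .data$gene_id, name = "n_cohorts") |>
    dplyr::filter(.data$n_cohorts >= 2L) |>
    dplyr::arrange(dplyr::desc(.data$n_cohorts), .data$gene_id)
  if (!is.null(chrom_map)) {
    multi <- dplyr::left_join(multi, chrom_map, by = "gene_id")
  }
  list(per_cohort = per_cohort, multi_cohort = multi)
}

#' Hypergeometric test for chromosome enrichment
#'
#' Upper-tail probability of observing at least the foreground count of
#' target-chromosome genes when drawing `|foreground|` genes without
#' replacement from the background — the classic enrichment test for a
#' chromosomally biased gene list.
#'
#' @param foreground_genes Character vector of genes of interest (e.g. the
#'   multi-cohort bimodal genes); must be a subset of the background.
#' @param background_genes All genes considered.
#' @param chrom_map Tibble with columns `gene_id`, `chromosome` covering the
#'   background.
#' @param target_chrom Chromosome label to test (e.g. `"chrY"`).
#' @return One-row tibble: `target_chrom`, `observed`, `expected`, `p_value`,
#'   `n_foreground`, `n_background`.
#' @export
chromosome_bias_test <- function(foreground_genes, background_genes, chrom_map,
                                 target_chrom) {
  foreground_genes <- unique(as.character(foreground_genes))
  background_genes <- unique(as.character(background_genes))
  if (length(foreground_genes) == 0L) abort("empty foreground gene set.")
  out_bg <- setdiff(foreground_genes, background_genes)
  if (length(out_bg) > 0L) {
    abort(sprintf(
      "foreground gene(s) not in background: %s",
      paste(out_bg, collapse = ", ")
    ))
  }
  chrom <- setNames(as.character(chrom_map$chromosome), chrom_map$gene_id)
  unmapped <- foreground_genes[!foreground_genes %in% names(chrom)]
  if (length(unmapped) > 0L) {
    abort(sprintf(
      "foreground gene(s) without chromosome annotation: %s",
      paste(unmapped, collapse = ", ")
    ))
  }
  bg_chrom <- chrom[background_genes]
  n_bg <- length(background_genes)
  k_target <- sum(bg_chrom == target_chrom, na.rm = TRUE)
  n_fg <- length(foreground_genes)
  obs <- sum(chrom[foreground_genes] == target_chrom)
  p <- phyper(obs - 1L, k_target, n_bg - k_target, n_fg, lower.tail = FALSE)
  tibble(
    target_chrom = target_chrom, observed = as.integer(obs),
    expected = n_fg * k_target / n_bg, p_value = p,
    n_foreground = as.integer(n_fg), n_background = as.integer(n_bg)
  )
}
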