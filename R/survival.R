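#' Kaplan-Meier product-limit survival curve
#'
#' Product-limit estimate over the distinct observed times:
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`. Times with only censoring shrink
#' the risk set without a step. Backed by [survival::survfit()].
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = death, 0 = censored).
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (non-increasing, starting from 1 at time 0).
#' @examples
#' kaplan_meier(c(2, 5, 6, 8), c(1, 0, 0, 0))
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) abort("empty survival input.")
  if (length(times) != length(events)) {
    abort("`times` and `events` must have the same length.")
  }
  if (any(!is.finite(times) | times <= 0)) abort("all `times` must be finite and positive.")
  if (!all(events %in% c(0, 1))) abort("`events` must be 0 or 1.")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble(
    time = fit$time,
    n_risk = as.integer(fit$n.risk),
    n_event = as.integer(fit$n.event),
    n_censor = as.integer(fit$n.censor),
    survival = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Classic log-rank comparison over the pooled distinct event times: the
#' statistic is `(O1 - E1)^2 / sum(V_i)` with `E1 = sum d_i n1_i / n_i` and
#' the hypergeometric variance
#' `V_i = d_i (n1_i/n_i)(1 - n1_i/n_i)(n_i - d_i)/(n_i - 1)`; the p-value is
#' the upper chi-square (1 df) tail. Backed by [survival::survdiff()]. With
#' no events at all the statistic is 0 and p = 1, with a warning.
#'
#' @param times1,events1 Follow-up times and indicators of group 1.
#' @param times2,events2 Follow-up times and indicators of group 2.
#' @return One-row tibble: `n_group1`, `n_group2`, `events_group1`,
#'   `events_group2`, `chi_square`, `p_value`.
#' @examples
#' logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
#' @export
logrank_test <- function(times1, events1, times2, events2) {
  if (length(times1) == 0L || length(times2) == 0L) {
    abort("both groups must be non-empty.")
  }
  for (v in list(times1, times2)) {
    if (any(!is.finite(v) | v <= 0)) abort("all times must be finite and positive.")
  }
  if (!all(c(events1, events2) %in% c(0, 1))) abort("events must be 0 or 1.")
  res <- tibble(
    n_group1 = length(times1), n_group2 = length(times2),
    events_group1 = as.integer(sum(events1)),
    events_group2 = as.integer(sum(events2))
  )
  if (sum(events1) + sum(events2) == 0) {
    warn("no events in either group; log-rank statistic is 0.")
    return(dplyr::mutate(res, chi_square = 0, p_value = 1))
  }
  time <- c(times1, times2)
  event <- c(events1, events2)
  group <- rep(c(1L, 2L), c(length(times1), length(times2)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  dplyr::mutate(res,
    chi_square = unname(sd$chisq),
    p_value = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE)
  )
}

#' Prognosis screen over bimodal-gene stratifications
#'
#' For every bimodal gene, intersects the peak-1/peak-2 sample labels with the
#' clinical table and runs the log-rank test between the two expression modes,
#' flagging significance at each requested level. Samples discarded by the
#' mixture filters never enter (they carry no label); stratified samples
#' absent from the clinical table are dropped with a logged count, and genes
#' whose intersection leaves an empty group are excluded with a logged reason.
#'
#' @param stratifications Tibble `gene_id`, `cohort_label`, `sample_id`,
#'   `peak` (from [analyze_cohort()]).
#' @param clinical Tibble `sample_id`, `os_time`, `os_event` (from
#'   [read_clinical_table()] or [simulate_survival()]).
#' @param alpha_levels Significance levels flagged (default `c(0.05, 0.01)`).
#' @param truncate_barcode Optional integer: match sample ids on their first
#'   N characters (TCGA barcode reconciliation, see
#'   [normalize_sample_ids()]).
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column
#'   (default `FALSE`; significance flags always use the raw p-values).
#' @param verbose Log dropped-sample counts and excluded genes.
#' @return Tibble with one row per tested gene: group sizes, event counts,
#'   `chi_square`, `p_value`, `significant_05`, `significant_01` (and
#'   `p_adjusted` when `adjust = TRUE`). Excluded genes are recorded in the
#'   `excluded` attribute.
#' @export
prognosis_screen <- function(stratifications, clinical,
                             alpha_levels = c(0.05, 0.01),
                             truncate_barcode = NULL, adjust = FALSE,
                             verbose = TRUE) {
  stopifnot(is.data.frame(stratifications), is.data.frame(clinical))
  if (nrow(stratifications) == 0L) abort("no stratifications supplied.")
  if (nrow(clinical) == 0L) abort("empty clinical table.")
  strat <- dplyr::mutate(
    stratifications,
    .match_id = normalize_sample_ids(.data$sample_id, truncate_barcode)
  )
  clin <- dplyr::mutate(
    clinical,
    .match_id = normalize_sample_ids(.data$sample_id, truncate_barcode)
  ) |>
    dplyr::select(".match_id", "os_time", "os_event")
  if (!any(strat$.match_id %in% clin$.match_id)) {
    abort("no stratified sample matches the clinical table.")
  }
  excluded <- list()
  records <- strat |>
    dplyr::group_by(.data$gene_id, .data$cohort_label) |>
    dplyr::group_map(function(df, key) {
      joined <- dplyr::inner_join(df, clin, by = ".match_id")
      n_drop <- nrow(df) - nrow(joined)
      if (n_drop > 0L && isTRUE(verbose)) {
        inform(sprintf(
          "gene %s: %d stratified sample(s) absent from the clinical table.",
          key$gene_id, n_drop
        ))
      }
      g1 <- dplyr::filter(joined, .data$peak == "peak1")
      g2 <- dplyr::filter(joined, .data$peak == "peak2")
      if (nrow(g1) == 0L || nrow(g2) == 0L) {
        if (isTRUE(verbose)) {
          inform(sprintf(
            "gene %s excluded: a peak group has no clinical overlap.",
            key$gene_id
          ))
        }
        excluded[[length(excluded) + 1L]] <<- key
        return(NULL)
      }
      lr <- logrank_test(g1$os_time, g1$os_event, g2$os_time, g2$os_event)
      dplyr::bind_cols(key, lr)
    }) |>
    dplyr::bind_rows()
  if (nrow(records) == 0L) abort("every gene was excluded: no testable overlap.")
  records <- dplyr::mutate(
    records,
    significant_05 = .data$p_value < max(alpha_levels),
    significant_01 = .data$p_value < min(alpha_levels)
  )
  if (isTRUE(adjust)) {
    records$p_adjusted <- p.adjust(records$p_value, method = "BH")
  }
  attr(records, "excluded") <- dplyr::bind_rows(excluded)
  records
}
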