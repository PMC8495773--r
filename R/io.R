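delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) {
    return(delim)
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene x sample expression matrix
#'
#' Expects genes in rows and samples in columns: a header row of sample ids, a
#' first column of gene ids, and a numeric body of FPKM values. The delimiter
#' is auto-detected from the extension (`.csv` -> comma, otherwise tab) and
#' can be overridden. Validation is strict: duplicate gene or sample ids,
#' non-numeric or negative cells, and an empty body are errors that name the
#' offending id or cell.
#'
#' @param path Path to a TSV/CSV file.
#' @param cohort_label Label attached to the matrix (e.g. a TCGA cohort code).
#' @param delim Optional delimiter override.
#' @return An `expr_matrix`: a tibble whose first column is `gene_id` and
#'   remaining columns are one numeric column per sample, with attribute
#'   `cohort_label`.
#' @export
read_expression_matrix <- function(path, cohort_label, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path,
    delim = delim_for(path, delim),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort(sprintf("expression file %s has an empty body.", path))
  }
  gene_ids <- trimws(raw[[1L]])
  sample_ids <- trimws(names(raw)[-1L])
  body <- raw[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    suppressWarnings(vals[, j] <- as.numeric(body[[j]]))
    bad <- which(is.na(vals[, j]) | !is.finite(vals[, j]))
    if (length(bad) > 0L) {
      abort(sprintf(
        "non-numeric or non-finite cell at gene '%s', sample '%s' (value '%s').",
        gene_ids[bad[1L]], sample_ids[j], body[[j]][bad[1L]]
      ))
    }
  }
  out <- dplyr::bind_cols(
    tibble(gene_id = gene_ids),
    as_tibble(setNames(as.data.frame(vals), sample_ids))
  )
  as_expr_matrix(out, cohort_label)
}

#' Construct / validate an expression matrix tibble
#'
#' @param x Tibble or data frame: first column `gene_id` (character), the rest
#'   numeric sample columns.
#' @param cohort_label Cohort label to attach.
#' @return A validated `expr_matrix` tibble.
#' @export
as_expr_matrix <- function(x, cohort_label) {
  x <- as_tibble(x)
  if (nrow(x) < 1L || ncol(x) < 2L) abort("expression matrix needs >= 1 gene and >= 1 sample.")
  if (names(x)[1L] != "gene_id") names(x)[1L] <- "gene_id"
  dup_g <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup_g) > 0L) {
    abort(sprintf("duplicate gene id(s): %s", paste(dup_g, collapse = ", ")))
  }
  samp <- names(x)[-1L]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s) > 0L) {
    abort(sprintf("duplicate sample id(s): %s", paste(dup_s, collapse = ", ")))
  }
  for (j in samp) {
    v <- x[[j]]
    if (!is.numeric(v)) abort(sprintf("sample column '%s' is not numeric.", j))
    if (any(!is.finite(v))) abort(sprintf("non-finite value in sample column '%s'.", j))
    if (any(v < 0)) abort(sprintf("negative expression value in sample column '%s'.", j))
  }
  attr(x, "cohort_label") <- as.character(cohort_label)
  class(x) <- unique(c("expr_matrix", class(x)))
  x
}

#' @describeIn read_expression_matrix Write an expression matrix back to disk
#'   (round-trip counterpart of the reader).
#' @param x An `expr_matrix`.
#' @export
write_expression_matrix <- function(x, path, delim = NULL) {
  readr::write_delim(x, path, delim = delim_for(path, delim), progress = FALSE)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Requires columns for sample id, overall-survival time and event indicator
#' (0 = censored, 1 = death); header names are configurable. Rows with a
#' missing time or event are dropped with a warning giving the count; an
#' out-of-range event code or a non-positive survival time is an error naming
#' the offending row.
#'
#' @param path Path to a TSV/CSV file.
#' @param id_col,time_col,event_col Header names (defaults `sample_id`,
#'   `os_time`, `os_event`).
#' @param time_unit `"days"` (default) or `"months"`; months are rescaled to
#'   days (x 30.44) so downstream analyses share one unit.
#' @param delim Optional delimiter override.
#' @return Tibble with columns `sample_id`, `os_time` (days), `os_event`;
#'   attribute `n_dropped` counts discarded incomplete rows.
#' @export
read_clinical_table <- function(path, id_col = "sample_id", time_col = "os_time",
                                event_col = "os_event",
                                time_unit = c("days", "months"), delim = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path,
    delim = delim_for(path, delim),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(c(id_col, time_col, event_col), names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  id <- trimws(raw[[id_col]])
  tm <- suppressWarnings(as.numeric(raw[[time_col]]))
  ev_raw <- trimws(raw[[event_col]])
  ev <- suppressWarnings(as.numeric(ev_raw))
  incomplete <- is.na(tm) | is.na(ev_raw) | ev_raw == ""
  bad_event <- which(!incomplete & (!ev %in% c(0, 1)))
  if (length(bad_event) > 0L) {
    abort(sprintf(
      "os_event must be 0 or 1; row %d (sample '%s') has '%s'.",
      bad_event[1L], id[bad_event[1L]], ev_raw[bad_event[1L]]
    ))
  }
  bad_time <- which(!incomplete & (!is.finite(tm) | tm <= 0))
  if (length(bad_time) > 0L) {
    abort(sprintf(
      "os_time must be finite and positive; row %d (sample '%s') has '%s'.",
      bad_time[1L], id[bad_time[1L]], raw[[time_col]][bad_time[1L]]
    ))
  }
  n_dropped <- sum(incomplete)
  if (n_dropped > 0L) {
    warn(sprintf("dropped %d row(s) with missing survival time or event.", n_dropped))
  }
  out <- tibble(
    sample_id = id[!incomplete],
    os_time = tm[!incomplete],
    os_event = as.integer(ev[!incomplete])
  )
  if (nrow(out) == 0L) abort("no valid clinical rows remain.")
  dup <- unique(out$sample_id[duplicated(out$sample_id)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate clinical sample id(s): %s", paste(dup, collapse = ", ")))
  }
  if (time_unit == "months") out$os_time <- out$os_time * 30.44
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @describeIn read_clinical_table Write a clinical table to TSV.
#' @param x Clinical tibble.
#' @export
write_clinical_table <- function(x, path, delim = NULL) {
  readr::write_delim(x, path, delim = delim_for(path, delim), progress = FALSE)
  invisible(path)
}

sigfmt <- function(x) {
  if (is.numeric(x) && !is.integer(x)) signif(x, 6) else x
}

#' Write pipeline result tables
#'
#' Writes up to three TSVs into `out_dir`: `bimodal_calls.tsv`,
#' `stratification.tsv` and `prognosis.tsv`, with a stable column order and
#' floats serialized to 6 significant digits. An empty table still produces a
#' header-only file, and [read_results()] reproduces the inputs.
#'
#' @param calls Bimodal-call tibble from [analyze_cohort()].
#' @param stratifications Stratification tibble (may have zero rows).
#' @param prognosis Optional prognosis tibble from [prognosis_screen()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named character vector of written paths.
#' @export
write_results <- function(calls, stratifications, prognosis = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", out_dir))
  }
  paths <- c(
    bimodal_calls = file.path(out_dir, "bimodal_calls.tsv"),
    stratification = file.path(out_dir, "stratification.tsv")
  )
  readr::write_tsv(dplyr::mutate(calls, dplyr::across(dplyr::everything(), sigfmt)),
    paths[["bimodal_calls"]],
    progress = FALSE
  )
  readr::write_tsv(
    dplyr::mutate(stratifications, dplyr::across(dplyr::everything(), sigfmt)),
    paths[["stratification"]],
    progress = FALSE
  )
  if (!is.null(prognosis)) {
    paths <- c(paths, prognosis = file.path(out_dir, "prognosis.tsv"))
    readr::write_tsv(
      dplyr::mutate(prognosis, dplyr::across(dplyr::everything(), sigfmt)),
      paths[["prognosis"]],
      progress = FALSE
    )
  }
  invisible(paths)
}

#' @describeIn write_results Read the result tables back from a directory.
#' @export
read_results <- function(out_dir) {
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) {
      readr::read_tsv(p, progress = FALSE, show_col_types = FALSE)
    } else {
      NULL
    }
  }
  list(
    calls = rd("bimodal_calls.tsv"),
    stratifications = rd("stratification.tsv"),
    prognosis = rd("prognosis.tsv")
  )
}

#' Match expression sample ids against clinical ids
#'
#' Exact string matching after whitespace trimming, with an optional
#' truncate-to-`n`-characters rule that reconciles TCGA-style barcodes whose
#' suffixes differ between expression (sample-level) and clinical
#' (patient-level) exports.
#'
#' @param ids Character vector of ids to normalize.
#' @param truncate Optional integer: keep only the first `truncate` characters.
#' @return Normalized character vector.
#' @export
normalize_sample_ids <- function(ids, truncate = NULL) {
  ids <- trimws(as.character(ids))
  if (!is.null(truncate)) {
    truncate <- as.integer(truncate)
    if (truncate < 1L) abort("`truncate` must be a positive integer.")
    ids <- substr(ids, 1L, truncate)
  }
  ids
}
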