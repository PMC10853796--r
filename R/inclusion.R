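# Exon inclusion levels: percent-spliced-in (PSI, 0-100) from RNA-seq-style
# tables and EST-derived inclusion levels, treated on the same scale.

check_psi_values <- function(value) {
  if (anyNA(value) || any(value < 0 | value > 100)) {
    abort("inclusion values must lie in [0, 100]",
          class = "metalsplice_value_error")
  }
}

#' Mean inclusion levels
#'
#' Averages inclusion records by exon, exon x tissue, or group. Missing
#' tissues are simply absent; nothing is imputed, and the stratum n is
#' reported with every mean.
#'
#' @param records Tibble with columns `exon_id`, `value` (percent, 0-100)
#'   and, as required by `by`, `tissue` and/or `group`.
#' @param by `"exon"`, `"exon_tissue"` or `"group"`.
#' @return Tibble of strata with `n`, `mean`, `sem`.
#' @export
mean_inclusion <- function(records, by = c("exon", "exon_tissue", "group")) {
  by <- match.arg(by)
  if (!nrow(records)) abort("no records supplied",
                            class = "metalsplice_value_error")
  check_psi_values(records$value)
  keys <- switch(by, exon = "exon_id", exon_tissue = c("exon_id", "tissue"),
                 group = "group")
  if (!all(keys %in% names(records))) {
    abort(sprintf("records needs column(s) %s", paste(keys, collapse = ", ")),
          class = "metalsplice_value_error")
  }
  records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value), .groups = "drop")
}

#' Drop small exons and microexons from inclusion records
#'
#' Very small exons are generally less efficiently included, biasing PSI
#' comparisons. The default cutoff of 28 nt is a package choice
#' (configurable); records for exons shorter than `min_len` are removed.
#'
#' @param records Inclusion tibble with `exon_id`.
#' @param lengths Tibble with `exon_id`, `length` (nt).
#' @param min_len Minimum exon length retained (inclusive).
#' @return Filtered records; dropped-exon count in `attr(, "n_dropped")`.
#' @export
exclude_small_exons <- function(records, lengths, min_len = 28L) {
  if (!all(c("exon_id", "length") %in% names(lengths))) {
    abort("lengths needs columns exon_id, length",
          class = "metalsplice_value_error")
  }
  keep_ids <- lengths$exon_id[lengths$length >= min_len]
  out <- dplyr::filter(records, .data$exon_id %in% keep_ids)
  attr(out, "n_dropped") <- dplyr::n_distinct(records$exon_id) -
    dplyr::n_distinct(out$exon_id)
  out
}

#' Select low-inclusion candidate exons
#'
#' An exon is a candidate for regulated-splicing validation when its mean
#' PSI in at least one tissue of the target set falls below the threshold
#' (default rule: mean PSI < 90% in neural or muscle tissue, testis or
#' embryonal stem cells).
#'
#' @param records Tibble with `exon_id`, `tissue`, `value`.
#' @param threshold PSI percent threshold (default 90).
#' @param tissue_set Character vector of tissues to scan.
#' @return Tibble of candidates: `exon_id`, `min_tissue_mean` and the
#'   qualifying `tissue`.
#' @export
select_candidates <- function(records, threshold = 90,
                              tissue_set = c("neural", "muscle", "testis",
                                             "esc")) {
  if (!length(tissue_set)) abort("tissue_set must be non-empty",
                                 class = "metalsplice_value_error")
  check_psi_values(records$value)
  per <- records %>%
    dplyr::filter(.data$tissue %in% tissue_set) %>%
    dplyr::group_by(.data$exon_id, .data$tissue) %>%
    dplyr::summarise(mean_psi = mean(.data$value), .groups = "drop")
  per %>%
    dplyr::filter(.data$mean_psi < threshold) %>%
    dplyr::group_by(.data$exon_id) %>%
    dplyr::slice_min(.data$mean_psi, n = 1L, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::rename(min_tissue_mean = "mean_psi")
}

#' Summarize splicing-validation outcomes
#'
#' Counts tested exons that showed skipping in at least one assayed
#' transcriptome, and in all of them, reporting the any-skipping percentage
#' rounded to the nearest integer.
#'
#' @param outcomes Tibble with `exon_id`, `transcriptome`, `skipped`
#'   (logical); at most one record per exon x transcriptome.
#' @param n_tested Total number of exons tested.
#' @param n_transcriptomes Number of assay contexts required for the
#'   "skipping in all" count (default 4).
#' @return One-row tibble: `n_tested`, `n_skipping_any`, `percent_any`,
#'   `n_skipping_all`.
#' @export
validation_summary <- function(outcomes, n_tested, n_transcriptomes = 4L) {
  if (n_tested < 1L) abort("n_tested must be >= 1",
                           class = "metalsplice_value_error")
  if (dplyr::n_distinct(outcomes$exon_id) > n_tested) {
    abort("outcomes contain more exons than were tested",
          class = "metalsplice_value_error")
  }
  if (anyDuplicated(outcomes[c("exon_id", "transcriptome")])) {
    abort("at most one outcome per exon and transcriptome",
          class = "metalsplice_value_error")
  }
  per <- outcomes %>%
    dplyr::group_by(.data$exon_id) %>%
    dplyr::summarise(any = any(.data$skipped),
                     all_n = sum(.data$skipped), .groups = "drop")
  n_any <- sum(per$any)
  tibble::tibble(
    n_tested = as.integer(n_tested),
    n_skipping_any = as.integer(n_any),
    percent_any = round(100 * n_any / n_tested),
    n_skipping_all = as.integer(sum(per$all_n >= n_transcriptomes)))
}
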