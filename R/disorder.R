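# Amino-acid-level splicing propensities and their correlation with
# protein-disorder scales, with optional codon-usage weighting.

#' Build a codon-usage table
#'
#' @param weights Named non-negative numeric vector over the 61 sense
#'   codons (DNA alphabet). `NULL` gives equal usage.
#' @param context Label (e.g. `"equal"`, `"dividing"`, `"differentiated"`).
#' @return Tibble: `codon`, `weight`, with the context in
#'   `attr(, "context")`.
#' @export
codon_usage <- function(weights = NULL, context = "equal") {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  if (is.null(weights)) weights <- setNames(rep(1, length(sense)), sense)
  names(weights) <- normalize_seq(names(weights), "codon")
  miss <- setdiff(sense, names(weights))
  if (length(miss)) {
    abort(sprintf("usage weights missing for codon(s): %s",
                  paste(utils::head(miss, 3L), collapse = ", ")),
          class = "metalsplice_value_error")
  }
  if (any(weights < 0)) abort("usage weights must be non-negative",
                              class = "metalsplice_value_error")
  out <- tibble::tibble(codon = sense, weight = unname(weights[sense]))
  attr(out, "context") <- context
  out
}

#' Read a codon-usage table from TSV (columns codon, weight)
#'
#' @param path TSV path.
#' @param context Label stored with the table.
#' @return A codon-usage tibble.
#' @export
read_codon_usage <- function(path, context = basename(path)) {
  df <- readr::read_tsv(path, col_types = readr::cols(codon = "c",
                                                      weight = "d"),
                        progress = FALSE)
  codon_usage(setNames(df$weight, df$codon), context = context)
}

#' Amino-acid-level splicing log-ratios
#'
#' Collapses the 61 sense-codon `ln_f_ratio` values of a codon frequency
#' profile to the 20 amino acids by a usage-weighted mean over each amino
#' acid's synonymous codons. Equal usage (the default) is the unweighted
#' mean; stop codons are excluded throughout.
#'
#' @param profile Tibble from [codon_frequency_profile()].
#' @param usage Codon-usage tibble from [codon_usage()]; `NULL` = equal.
#' @return Tibble: `aa` (one-letter, 20 rows), `value`, `n_codons`.
#' @export
aa_level_lnratio <- function(profile, usage = NULL) {
  if (is.null(usage)) usage <- codon_usage()
  gc <- genetic_code()
  df <- profile %>%
    dplyr::inner_join(usage, by = "codon") %>%
    dplyr::mutate(aa = unname(gc[.data$codon])) %>%
    dplyr::filter(.data$aa != "*")
  zero <- df %>%
    dplyr::group_by(.data$aa) %>%
    dplyr::summarise(w = sum(.data$weight), .groups = "drop") %>%
    dplyr::filter(.data$w <= 0)
  if (nrow(zero)) {
    abort(sprintf("zero total usage weight for amino acid(s): %s",
                  paste(zero$aa, collapse = ", ")),
          class = "metalsplice_value_error")
  }
  df %>%
    dplyr::group_by(.data$aa) %>%
    dplyr::summarise(
      value = sum(.data$ln_f_ratio * .data$weight) / sum(.data$weight),
      n_codons = dplyr::n(), .groups = "drop")
}

#' Build a disorder scale
#'
#' @param values Named numeric vector over exactly the 20 standard
#'   one-letter amino acids.
#' @param name Scale name.
#' @return Tibble: `aa`, `value`, with `attr(, "scale_name")`.
#' @export
disorder_scale <- function(values, name = "scale") {
  aas <- sort(setdiff(unique(unname(genetic_code())), "*"))
  if (!setequal(names(values), aas)) {
    abort("scale must cover exactly the 20 standard amino acids",
          class = "metalsplice_value_error")
  }
  out <- tibble::tibble(aa = aas, value = unname(values[aas]))
  attr(out, "scale_name") <- name
  out
}

#' Read a disorder scale from TSV (columns aa, value)
#'
#' @param path TSV path.
#' @param name Scale name (defaults to the file name).
#' @return A disorder-scale tibble.
#' @export
read_disorder_scale <- function(path, name = basename(path)) {
  df <- readr::read_tsv(path, col_types = readr::cols(aa = "c",
                                                      value = "d"),
                        progress = FALSE)
  disorder_scale(setNames(df$value, df$aa), name = name)
}

#' Correlate amino-acid splicing values with a disorder scale
#'
#' Pearson correlation over the 20 amino acids, with the two-sided p-value
#' from the exact t transform on n - 2 = 18 degrees of freedom. Scales are
#' used as supplied; no sign normalization (some published scales
#' correlate negatively by construction).
#'
#' @param aa_values Tibble from [aa_level_lnratio()] (`aa`, `value`).
#' @param scale Disorder-scale tibble (`aa`, `value`).
#' @return One-row tibble: `scale`, `r`, `p_value`, `n`, `df`.
#' @export
correlate_scale <- function(aa_values, scale) {
  df <- dplyr::inner_join(aa_values, scale, by = "aa",
                          suffix = c("_splice", "_scale"))
  if (nrow(df) != 20L) {
    abort("aa_values and scale must cover the same 20 amino acids",
          class = "metalsplice_value_error")
  }
  if (stats::var(df$value_splice) == 0 || stats::var(df$value_scale) == 0) {
    abort("zero variance on one side; correlation undefined",
          class = "metalsplice_value_error")
  }
  ct <- stats::cor.test(df$value_splice, df$value_scale, method = "pearson")
  tibble::tibble(
    scale = attr(scale, "scale_name") %||% "scale",
    r = unname(ct$estimate), p_value = ct$p.value,
    n = nrow(df), df = unname(ct$parameter))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
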