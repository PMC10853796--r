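#' Filter coordinating-residue annotations by dataset mode
#'
#' Mirrors the tiered dataset design used for metal-site curation: the
#' stringent mode keeps only residues with direct structural evidence
#' (drops homology-extended records), and the metal-site validation filter
#' drops records whose validation status is `not_validated`.
#'
#' @param residues Tibble with columns `homology_extended` (logical) and
#'   `cmm_status` (one of `plausible`, `problematic`, `not_validated`,
#'   `unassessed`).
#' @param mode `"stringent"` (drop homology-extended) or `"extended"`.
#' @param cmm_filter Flag; when TRUE, drop `not_validated` records.
#' @return The filtered tibble, with a count report in
#'   `attr(, "filter_report")` (`n_codons`, `n_proteins`).
#' @export
apply_dataset_filters <- function(residues, mode = c("stringent", "extended"),
                                  cmm_filter = FALSE) {
  mode <- match.arg(mode)
  out <- residues
  if (mode == "stringent") out <- dplyr::filter(out, !.data$homology_extended)
  if (cmm_filter) out <- dplyr::filter(out, .data$cmm_status != "not_validated")
  attr(out, "filter_report") <- tibble::tibble(
    mode = mode, cmm_filter = cmm_filter,
    n_codons = nrow(out),
    n_proteins = if ("protein_id" %in% names(out))
      dplyr::n_distinct(out$protein_id) else NA_integer_)
  out
}

#' Trim the splice-site consensus off an exon
#'
#' Removes the first and last three nucleotides, which shape the 3'ss and
#' 5'ss consensus rather than the auxiliary exonic code. Exons of 6 nt or
#' fewer trim to the empty string.
#'
#' @param seq Nucleotide string (vectorized).
#' @return Trimmed core string(s).
#' @export
trim_exon <- function(seq) {
  seq <- normalize_seq(seq, "exon")
  n <- nchar(seq)
  ifelse(n <= 6L, "", substring(seq, 4L, n - 3L))
}

#' Whole-exon enhancer/silencer profile
#'
#' Averages the per-hexamer `ln(ese_score/ess_score)` over every overlapping
#' hexamer of the trimmed exon core, excluding splicing-neutral hexamers.
#' The default averages the per-hexamer log ratios (`mean_of_ln`); the
#' alternative takes the log of the ratio of averaged scores
#' (`ln_of_means`).
#'
#' @param table Score-table tibble (complete over the core's hexamers).
#' @param exons Tibble of exon records with `exon_id` and `seq`; extra
#'   columns (e.g. `group`) are carried through.
#' @param mean_mode `"mean_of_ln"` or `"ln_of_means"`.
#' @return Tibble: input columns minus `seq`, plus `trimmed_len`,
#'   `n_hexamers` (all windows of the core, `max(0, trimmed_len - 5)`),
#'   `n_scored` (non-neutral windows used) and `mean_ln_ratio` (NA when no
#'   scorable window exists).
#' @export
exon_profile <- function(table, exons, mean_mode = c("mean_of_ln",
                                                     "ln_of_means")) {
  mean_mode <- match.arg(mean_mode)
  if (!all(c("exon_id", "seq") %in% names(exons))) {
    abort("exons needs columns exon_id, seq",
          class = "metalsplice_value_error")
  }
  lk <- table_lookup(table)
  core <- trim_exon(exons$seq)
  prof <- purrr::map2_dfr(core, nchar(core), function(s, n) {
    n_hex <- max(0L, n - 5L)
    if (n_hex == 0L) {
      return(tibble::tibble(trimmed_len = n, n_hexamers = 0L,
                            n_scored = 0L, mean_ln_ratio = NA_real_))
    }
    win <- substring(s, seq_len(n_hex), seq_len(n_hex) + 5L)
    cls <- lk$cls[win]
    if (anyNA(cls)) {
      abort(sprintf("hexamer '%s' absent from score table",
                    win[is.na(cls)][1L]),
            class = "metalsplice_value_error")
    }
    use <- cls != "N"
    m <- if (!any(use)) NA_real_
    else if (mean_mode == "mean_of_ln") mean(lk$lnr[win][use])
    else {
      me <- mean(lk$ese[win][use]); ms <- mean(lk$ess[win][use])
      if (me > 0 && ms > 0) log(me / ms) else NA_real_
    }
    tibble::tibble(trimmed_len = n, n_hexamers = n_hex,
                   n_scored = sum(use), mean_ln_ratio = m)
  })
  out <- dplyr::bind_cols(exons[setdiff(names(exons),
                                        c("seq", "upstream_intron",
                                          "downstream_intron"))], prof)
  attr(out, "mean_mode") <- mean_mode
  out
}

#' Drop over-long exons before group comparison
#'
#' Terminal and very large exons dilute the coordinating-codon signal; the
#' comparison cohort keeps exons of at most `max_len` nucleotides
#' (inclusive; default 350).
#'
#' @param exons Tibble with a `seq` column (length taken from it) or an
#'   explicit `length` column.
#' @param max_len Maximum exon length retained.
#' @return Filtered tibble; the number dropped is in `attr(, "n_dropped")`.
#' @export
filter_exons_for_comparison <- function(exons, max_len = 350L) {
  if (max_len <= 0) abort("max_len must be positive",
                          class = "metalsplice_value_error")
  len <- if ("length" %in% names(exons)) exons$length else nchar(exons$seq)
  keep <- len <= max_len
  out <- exons[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Compare whole-exon profiles between groups
#'
#' Summarizes `mean_ln_ratio` per group and runs a one-way ANOVA with
#' Tukey-Kramer post-hoc contrasts plus a Kruskal-Wallis test across
#' groups.
#'
#' @param profiles Tibble from [exon_profile()] with a grouping column;
#'   rows with undefined means are dropped (count reported).
#' @param group Name of the grouping column (default `"group"`).
#' @return An object of class `"exon_group_comparison"`: a list with
#'   `summary` (per-group n/mean/sem/median), `anova`, `kruskal` (one-row
#'   test tibbles) and `tukey` (pairwise contrasts). Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
compare_exon_groups <- function(profiles, group = "group") {
  if (!group %in% names(profiles)) {
    abort(sprintf("grouping column '%s' not found", group),
          class = "metalsplice_value_error")
  }
  df <- tibble::tibble(group = as.character(profiles[[group]]),
                       value = profiles$mean_ln_ratio)
  n_undefined <- sum(is.na(df$value))
  df <- df[!is.na(df$value), ]
  counts <- table(df$group)
  if (length(counts) < 2L) {
    abort("need at least two groups with defined profiles",
          class = "metalsplice_value_error")
  }
  if (any(counts < 2L)) {
    abort(sprintf("group(s) with fewer than 2 defined profiles: %s",
                  paste(names(counts)[counts < 2L], collapse = ", ")),
          class = "metalsplice_value_error")
  }
  smry <- df %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value),
                     median = stats::median(.data$value), .groups = "drop")
  av <- one_way_anova(df, value, group)
  tk <- tukey_kramer(df, value, group)
  kw <- kruskal_wallis(df, value, group)
  structure(list(summary = smry, anova = av, kruskal = kw, tukey = tk,
                 n_undefined = n_undefined),
            class = "exon_group_comparison")
}

#' @export
print.exon_group_comparison <- function(x, ...) {
  cat("Exon group comparison\n")
  print(x$summary)
  cat(sprintf("ANOVA: F = %.4g, p = %.3g; Kruskal-Wallis: H = %.4g, p = %.3g\n",
              x$anova$statistic, x$anova$p_value,
              x$kruskal$statistic, x$kruskal$p_value))
  if (x$n_undefined > 0)
    cat(sprintf("(%d profile(s) with undefined mean dropped)\n",
                x$n_undefined))
  invisible(x)
}

#' @rdname compare_exon_groups
#' @param x An `"exon_group_comparison"` object.
#' @param ... Unused.
#' @method tidy exon_group_comparison
#' @export
tidy.exon_group_comparison <- function(x, ...) x$tukey

#' @rdname compare_exon_groups
#' @method glance exon_group_comparison
#' @export
glance.exon_group_comparison <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$summary), n = sum(x$summary$n),
    f_statistic = x$anova$statistic, anova_p = x$anova$p_value,
    h_statistic = x$kruskal$statistic, kruskal_p = x$kruskal$p_value)
}

#' @rdname compare_exon_groups
#' @param object An `"exon_group_comparison"` object.
#' @method autoplot exon_group_comparison
#' @export
autoplot.exon_group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean exon ln(ESE/ESS)") +
    ggplot2::theme_minimal()
}
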