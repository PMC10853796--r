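#' Build a hexamer enhancer/silencer score table
#'
#' A score table assigns each hexamer an enhancer score (`ese_score`), a
#' silencer score (`ess_score`) and a class: `"E"` (enhancer), `"S"`
#' (silencer) or `"N"` (splicing-neutral). Neutral hexamers are ignored by
#' every averaging step downstream.
#'
#' @param hexamer Character vector of distinct 6-mers over \{A,C,G,T,U\}.
#' @param ese_score,ess_score Numeric score vectors.
#' @param class Optional character vector over \{E,S,N\}. When `NULL`, the
#'   `class_rule` is applied.
#' @param class_rule Function `(ese_score, ess_score) -> class` used when no
#'   class column is supplied. The default classifies by the sign of
#'   `ese_score - ess_score`, ties becoming neutral.
#' @return A tibble with columns `hexamer`, `ese_score`, `ess_score`,
#'   `class`, one row per hexamer.
#' @export
score_table <- function(hexamer, ese_score, ess_score, class = NULL,
                        class_rule = default_class_rule) {
  hexamer <- normalize_seq(hexamer, "hexamer")
  if (any(nchar(hexamer) != 6L)) {
    abort("every hexamer must have length 6", class = "metalsplice_value_error")
  }
  if (anyDuplicated(hexamer)) {
    abort(sprintf("duplicate hexamer: %s",
                  hexamer[duplicated(hexamer)][1L]),
          class = "metalsplice_value_error")
  }
  if (length(hexamer) > 4096L) {
    abort("a score table can hold at most 4096 hexamers",
          class = "metalsplice_value_error")
  }
  ese_score <- as.numeric(ese_score)
  ess_score <- as.numeric(ess_score)
  if (is.null(class)) class <- class_rule(ese_score, ess_score)
  class <- as.character(class)
  if (!all(class %in% c("E", "S", "N"))) {
    abort("class must be one of E, S, N", class = "metalsplice_value_error")
  }
  tibble::tibble(hexamer = hexamer, ese_score = ese_score,
                 ess_score = ess_score, class = class)
}

#' @rdname score_table
#' @export
default_class_rule <- function(ese_score, ess_score) {
  d <- ese_score - ess_score
  dplyr::case_when(d > 0 ~ "E", d < 0 ~ "S", TRUE ~ "N")
}

#' Read a hexamer score table from TSV
#'
#' Expects a header row with columns `hexamer`, `ese_score`, `ess_score` and
#' optionally `class`. Malformed or duplicate hexamers and missing columns
#' fail with the offending data line number (header = line 1).
#'
#' @param path Path to a tab-separated file.
#' @inheritParams score_table
#' @return A score-table tibble (see [score_table()]).
#' @export
read_score_table <- function(path, class_rule = default_class_rule) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("hexamer", "ese_score", "ess_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("%s: missing required column(s): %s (header line 1)",
                  path, paste(miss, collapse = ", ")),
          class = "metalsplice_parse_error")
  }
  hx <- toupper(gsub("U", "T", df$hexamer, fixed = TRUE))
  bad <- which(!grepl("^[ACGT]{6}$", hx))
  if (length(bad)) {
    abort(sprintf("%s line %d: malformed hexamer '%s'",
                  path, bad[1L] + 1L, df$hexamer[bad[1L]]),
          class = "metalsplice_parse_error")
  }
  dup <- which(duplicated(hx))
  if (length(dup)) {
    abort(sprintf("%s line %d: duplicate hexamer '%s'",
                  path, dup[1L] + 1L, df$hexamer[dup[1L]]),
          class = "metalsplice_parse_error")
  }
  score_table(hx,
              as.numeric(df$ese_score),
              as.numeric(df$ess_score),
              class = if ("class" %in% names(df)) df$class else NULL,
              class_rule = class_rule)
}

#' High-confidence enhancer and silencer hexamer sets
#'
#' Holds the two disjoint hexamer collections used for codon frequency
#' profiles. The reference resource carries 1182 high-confidence enhancers
#' and 1090 high-confidence silencers.
#'
#' @param ese_set,ess_set Character vectors of distinct 6-mers; the two sets
#'   must be disjoint.
#' @return A list with elements `ese_set`, `ess_set` of class
#'   `"hexamer_sets"`.
#' @export
hexamer_sets <- function(ese_set, ess_set) {
  ese_set <- normalize_seq(ese_set, "ese_set hexamer")
  ess_set <- normalize_seq(ess_set, "ess_set hexamer")
  if (any(nchar(c(ese_set, ess_set)) != 6L)) {
    abort("set members must be 6-mers", class = "metalsplice_value_error")
  }
  if (anyDuplicated(ese_set) || anyDuplicated(ess_set)) {
    abort("hexamer sets must not contain duplicates",
          class = "metalsplice_value_error")
  }
  if (length(intersect(ese_set, ess_set))) {
    abort("ese_set and ess_set must be disjoint",
          class = "metalsplice_value_error")
  }
  structure(list(ese_set = ese_set, ess_set = ess_set),
            class = "hexamer_sets")
}

#' Read enhancer/silencer hexamer sets from TSV
#'
#' Expects columns `hexamer` and `set` (values `ese`/`ess`).
#'
#' @param path Path to a tab-separated file.
#' @return A `"hexamer_sets"` object.
#' @export
read_hexamer_sets <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("hexamer", "set") %in% names(df))) {
    abort(sprintf("%s: need columns hexamer, set", path),
          class = "metalsplice_parse_error")
  }
  s <- tolower(df$set)
  if (!all(s %in% c("ese", "ess"))) {
    abort(sprintf("%s: set column must be 'ese' or 'ess'", path),
          class = "metalsplice_parse_error")
  }
  hexamer_sets(df$hexamer[s == "ese"], df$hexamer[s == "ess"])
}

#' Hexamer windows covering a codon
#'
#' The up-to-four hexamer windows that contain a whole codon start at
#' offsets `codon_start - 3 .. codon_start`; windows extending beyond the
#' sequence are dropped. Returned 5' to 3'.
#'
#' @param seq A nucleotide string.
#' @param codon_start 0-based offset of the codon's first nucleotide
#'   (BED-style).
#' @return Character vector of 1 to 4 hexamers.
#' @export
codon_windows <- function(seq, codon_start) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (codon_start < 0 || codon_start + 3L > n) {
    abort("codon not fully inside sequence",
          class = "metalsplice_value_error")
  }
  starts <- (codon_start - 3L):codon_start
  starts <- starts[starts >= 0L & starts + 6L <= n]
  if (!length(starts)) return(character(0))
  substring(seq, starts + 1L, starts + 6L)
}

#' In-frame triplet tokens of a hexamer
#'
#' Every hexamer contains exactly four complete triplet substrings, at start
#' offsets 0 through 3; these are the "codon tokens" counted in codon
#' frequency profiles (1182 hexamers yield 4728 tokens, 1090 yield 4360).
#'
#' @param hexamer A single 6-mer (vectorized over inputs).
#' @return Character vector of `4 * length(hexamer)` triplets, in order.
#' @export
codon_tokens <- function(hexamer) {
  hexamer <- normalize_seq(hexamer, "hexamer")
  if (any(nchar(hexamer) != 6L)) {
    abort("codon_tokens expects 6-mers", class = "metalsplice_value_error")
  }
  as.vector(vapply(hexamer, function(h) substring(h, 1:4, 3:6),
                   character(4L)))
}

# Named score/ln-ratio lookups for fast repeated scoring. ln ratio is NA for
# neutral hexamers and for non-positive score pairs.
table_lookup <- function(table) {
  ese <- setNames(table$ese_score, table$hexamer)
  ess <- setNames(table$ess_score, table$hexamer)
  cls <- setNames(table$class, table$hexamer)
  lnr <- ifelse(cls != "N" & ese > 0 & ess > 0, log(ese / ess), NA_real_)
  list(ese = ese, ess = ess, cls = cls, lnr = setNames(lnr, table$hexamer))
}

#' Score one codon by averaging its covering hexamer windows
#'
#' Averages the enhancer and silencer scores of the non-neutral hexamer
#' windows containing the codon and reports `ln_ratio = ln(mean_ese /
#' mean_ess)`. Splicing-neutral windows are excluded from both means. With
#' `require_full_context = TRUE` (the default) codons that do not have all
#' four windows inside the sequence are flagged `undefined_no_context`
#' rather than scored; these boundary codons shape the splice-site consensus
#' and typically make up a few percent of genome-scale samples.
#'
#' @param table A score-table tibble covering every window hexamer.
#' @param seq Nucleotide string containing the codon.
#' @param codon_start 0-based codon offset within `seq`.
#' @param require_full_context Flag; see Details.
#' @param offset Additive offset applied to both scores before averaging,
#'   for tables containing non-positive raw scores. Default 0.
#' @return One-row tibble: `codon`, `mean_ese`, `mean_ess`, `ln_ratio`,
#'   `n_windows_used`, `status` (`ok`, `undefined_all_neutral`,
#'   `undefined_no_context`).
#' @export
score_codon <- function(table, seq, codon_start,
                        require_full_context = TRUE, offset = 0) {
  lk <- table_lookup(table)
  score_codon_lk(lk, normalize_seq(seq), codon_start,
                 require_full_context, offset)
}

# Internal worker against a prebuilt lookup (seq already normalized).
score_codon_lk <- function(lk, seq, codon_start,
                           require_full_context = TRUE, offset = 0) {
  win <- codon_windows(seq, codon_start)
  codon <- substring(seq, codon_start + 1L, codon_start + 3L)
  out <- function(me, ms, lr, n, status) {
    tibble::tibble(codon = codon, mean_ese = me, mean_ess = ms,
                   ln_ratio = lr, n_windows_used = n, status = status)
  }
  if (require_full_context && length(win) < 4L) {
    return(out(NA_real_, NA_real_, NA_real_, 0L, "undefined_no_context"))
  }
  cls <- lk$cls[win]
  if (anyNA(cls)) {
    abort(sprintf("hexamer '%s' absent from score table",
                  win[is.na(cls)][1L]),
          class = "metalsplice_value_error")
  }
  use <- cls != "N"
  if (!any(use)) {
    return(out(NA_real_, NA_real_, NA_real_, 0L, "undefined_all_neutral"))
  }
  me <- mean(lk$ese[win][use]) + offset
  ms <- mean(lk$ess[win][use]) + offset
  lr <- if (me > 0 && ms > 0) log(me / ms) else NA_real_
  out(me, ms, lr, sum(use), "ok")
}

#' Score all annotated coordinating codons in a cohort
#'
#' Joins residue annotations to their exon records and scores each
#' coordinating codon with [score_codon()]. With `context = "extended"` the
#' flanking intron sequence is appended on both sides before windowing, so
#' boundary codons regain full hexamer context (emulating replacement of
#' terminal triplets with extended native motifs); with the default
#' `"exon_only"` they are flagged `undefined_no_context`.
#'
#' @param residues Tibble of residue annotations with at least `exon_id` and
#'   `codon_start_in_exon` (0-based); extra columns (e.g. `metal`, `group`)
#'   are carried through.
#' @param exons Tibble of exon records with `exon_id`, `seq` and (for
#'   extended context) `upstream_intron`, `downstream_intron`.
#' @param table Score-table tibble.
#' @param context `"exon_only"` or `"extended"`.
#' @param require_full_context Passed to [score_codon()].
#' @param offset Passed to [score_codon()].
#' @return Tibble: the input annotation columns plus the [score_codon()]
#'   columns.
#' @export
score_codons <- function(residues, exons, table, context = "exon_only",
                         require_full_context = TRUE, offset = 0) {
  context <- match.arg(context, c("exon_only", "extended"))
  need <- c("exon_id", "codon_start_in_exon")
  if (!all(need %in% names(residues))) {
    abort("residues needs columns exon_id, codon_start_in_exon",
          class = "metalsplice_value_error")
  }
  ex_cols <- c("exon_id", "seq",
               if (context == "extended") c("upstream_intron",
                                            "downstream_intron"))
  if (!all(ex_cols %in% names(exons))) {
    abort(sprintf("exons needs columns %s", paste(ex_cols, collapse = ", ")),
          class = "metalsplice_value_error")
  }
  joined <- dplyr::inner_join(residues, exons[ex_cols], by = "exon_id")
  lk <- table_lookup(table)
  scored <- purrr::pmap_dfr(
    list(joined$seq, joined$codon_start_in_exon,
         if (context == "extended") joined$upstream_intron else
           rep("", nrow(joined)),
         if (context == "extended") joined$downstream_intron else
           rep("", nrow(joined))),
    function(s, cs, up, dn) {
      s <- normalize_seq(s)
      if (nzchar(up) || nzchar(dn)) {
        up <- normalize_seq(up); dn <- normalize_seq(dn)
        s <- paste0(up, s, dn)
        cs <- cs + nchar(up)
      }
      score_codon_lk(lk, s, cs, require_full_context, offset)
    })
  dplyr::bind_cols(
    joined[setdiff(names(joined), c("seq", "upstream_intron",
                                    "downstream_intron"))],
    scored)
}

#' Codon frequency profile over enhancer/silencer hexamer sets
#'
#' Tokenizes each set with [codon_tokens()], counts the 64 codon types and
#' converts counts to additively smoothed frequencies: `f(c) = (count(c) +
#' alpha) / (total + 64 * alpha)`. Reports `ln_f_ratio = ln(ese_f / ess_f)`
#' per codon.
#'
#' @param sets A `"hexamer_sets"` object.
#' @param alpha Additive smoothing constant (default 0.5); `alpha = 0` is
#'   allowed only when neither set has a zero codon count.
#' @return Tibble with 64 rows (codons in alphabetical order): `codon`,
#'   `ese_count`, `ess_count`, `ese_f`, `ess_f`, `ln_f_ratio`; the smoothing
#'   constant is recorded in `attr(, "smoothing_alpha")`.
#' @export
codon_frequency_profile <- function(sets, alpha = 0.5) {
  if (!inherits(sets, "hexamer_sets")) {
    abort("sets must be created with hexamer_sets()",
          class = "metalsplice_value_error")
  }
  if (!length(sets$ese_set) || !length(sets$ess_set)) {
    abort("both hexamer sets must be non-empty",
          class = "metalsplice_value_error")
  }
  if (alpha < 0) abort("alpha must be >= 0", class = "metalsplice_value_error")
  codons <- all_codons()
  cnt <- function(set) {
    tk <- codon_tokens(set)
    tab <- table(factor(tk, levels = codons))
    as.integer(tab)
  }
  ese_count <- cnt(sets$ese_set)
  ess_count <- cnt(sets$ess_set)
  if (alpha == 0 && (any(ese_count == 0L) || any(ess_count == 0L))) {
    abort(paste("zero codon count with alpha = 0 gives infinite log ratios;",
                "set alpha > 0"),
          class = "metalsplice_value_error")
  }
  ese_f <- (ese_count + alpha) / (sum(ese_count) + 64 * alpha)
  ess_f <- (ess_count + alpha) / (sum(ess_count) + 64 * alpha)
  out <- tibble::tibble(
    codon = codons, ese_count = ese_count, ess_count = ess_count,
    ese_f = ese_f, ess_f = ess_f, ln_f_ratio = log(ese_f / ess_f))
  attr(out, "smoothing_alpha") <- alpha
  out
}

#' Write a codon frequency profile to TSV
#'
#' 64 rows in stable (alphabetical) codon order.
#'
#' @param profile Output of [codon_frequency_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_frequency_profile <- function(profile, path) {
  readr::write_tsv(dplyr::arrange(profile, .data$codon), path)
  invisible(path)
}

#' Summarize codon scores per group
#'
#' Per-group n, mean, SEM, median and IQR of the codon `ln_ratio`. Every
#' input score must have status `"ok"`; drop undefined codons explicitly
#' before aggregating.
#'
#' @param scores Tibble with columns `ln_ratio` and `status` (from
#'   [score_codons()]).
#' @param group Name of the grouping column in `scores` (default `"group"`).
#' @return Tibble: `group`, `n`, `mean`, `sem` (NA when n < 2), `median`,
#'   `iqr`.
#' @export
aggregate_codon_scores <- function(scores, group = "group") {
  if (!nrow(scores)) abort("no scores supplied",
                           class = "metalsplice_value_error")
  if (!group %in% names(scores)) {
    abort(sprintf("grouping column '%s' not found", group),
          class = "metalsplice_value_error")
  }
  if ("status" %in% names(scores) && any(scores$status != "ok")) {
    abort("all scores must have status 'ok'; filter undefined codons first",
          class = "metalsplice_value_error")
  }
  scores %>%
    dplyr::group_by(group = .data[[group]]) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$ln_ratio),
      sem = sem(.data$ln_ratio),
      median = stats::median(.data$ln_ratio),
      iqr = stats::IQR(.data$ln_ratio),
      .groups = "drop")
}
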