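# Acceptor/donor architecture metrics. Position convention throughout:
# intron position -1 is the last intronic nucleotide (the G of the 3'ss AG);
# exon position +1 is the first exonic nucleotide.

base_at <- function(seq, pos) {
  # pos negative, -1 = last nt
  n <- nchar(seq)
  i <- n + pos + 1L
  ifelse(i >= 1L & i <= n, substring(seq, i, i), NA_character_)
}

#' Position-weight-matrix splice-site model
#'
#' Windows follow the common convention: donor = 3 exonic + 6 intronic nt
#' (9-mer), acceptor = 20 intronic + 3 exonic nt (23-mer). Scoring is log2
#' odds against a uniform background. Externally derived maximum-entropy
#' scores can be supplied instead via [read_site_score_table()].
#'
#' @param site `"donor"` or `"acceptor"`.
#' @param probs 4 x L probability matrix (rows A,C,G,T; columns sum to 1).
#'   `NULL` uses a shipped consensus-like default.
#' @return An object of class `"splice_site_model"`.
#' @export
splice_site_pwm <- function(site = c("donor", "acceptor"), probs = NULL) {
  site <- match.arg(site)
  len <- if (site == "donor") 9L else 23L
  if (is.null(probs)) {
    probs <- if (site == "donor") default_donor_probs()
    else default_acceptor_probs()
  }
  probs <- as.matrix(probs)
  if (!identical(rownames(probs), DNA_BASES) || ncol(probs) != len) {
    abort(sprintf("probs must be a 4 x %d matrix with rows A,C,G,T", len),
          class = "metalsplice_value_error")
  }
  if (any(abs(colSums(probs) - 1) > 1e-8) || any(probs < 0)) {
    abort("each position's probabilities must be non-negative and sum to 1",
          class = "metalsplice_value_error")
  }
  structure(list(kind = "pwm", site = site, length = len, probs = probs),
            class = "splice_site_model")
}

# Consensus-flavoured defaults so the pipeline runs with no external model.
# Donor window: exon -3..-1 | intron +1..+6 (MAG|GTRAGT flavour).
default_donor_probs <- function() {
  p <- function(a, c, g, t) c(A = a, C = c, G = g, T = t)
  m <- cbind(p(.33, .36, .18, .13), p(.60, .13, .14, .13),
             p(.09, .03, .80, .08),
             p(.004, .004, .988, .004), p(.004, .004, .004, .988),
             p(.60, .02, .35, .03), p(.70, .08, .12, .10),
             p(.07, .05, .82, .06), p(.16, .15, .19, .50))
  rownames(m) <- DNA_BASES
  m
}

# Acceptor window: intron -20..-1 | exon +1..+3 (PPT + yAG|G flavour).
default_acceptor_probs <- function() {
  ppt <- c(A = .09, C = .31, G = .10, T = .50)
  m <- matrix(rep(ppt, 17L), nrow = 4L)
  m <- cbind(m,
             c(A = .25, C = .35, G = .05, T = .35),   # -3 (y)
             c(A = .988, C = .004, G = .004, T = .004), # -2 (A)
             c(A = .004, C = .004, G = .988, T = .004), # -1 (G)
             c(A = .25, C = .15, G = .50, T = .10),   # +1
             c(A = .30, C = .20, G = .20, T = .30),   # +2
             c(A = .25, C = .25, G = .25, T = .25))   # +3
  rownames(m) <- DNA_BASES
  m
}

#' Read an externally supplied splice-site score table
#'
#' A TSV with columns `window`, `score` (e.g. maximum-entropy scores
#' computed elsewhere); [score_site()] then scores by lookup.
#'
#' @param path TSV path.
#' @param site `"donor"` or `"acceptor"`.
#' @return A `"splice_site_model"` of kind `"maxent_tables"`.
#' @export
read_site_score_table <- function(path, site = c("donor", "acceptor")) {
  site <- match.arg(site)
  len <- if (site == "donor") 9L else 23L
  df <- readr::read_tsv(path, col_types = readr::cols(
    window = "c", score = "d"), progress = FALSE)
  w <- normalize_seq(df$window, "window")
  if (any(nchar(w) != len)) {
    abort(sprintf("%s: windows must be %d-mers for a %s model",
                  path, len, site),
          class = "metalsplice_parse_error")
  }
  structure(list(kind = "maxent_tables", site = site, length = len,
                 scores = setNames(df$score, w)),
            class = "splice_site_model")
}

#' Score a splice-site window
#'
#' For a PWM model, the sum over positions of log2(p(base)/0.25); for a
#' lookup model, the stored score of the window.
#'
#' @param model A `"splice_site_model"`.
#' @param window Nucleotide string of the model's window length
#'   (vectorized).
#' @return Numeric score(s); higher = stronger site.
#' @export
score_site <- function(model, window) {
  if (!inherits(model, "splice_site_model")) {
    abort("model must be a splice_site_model",
          class = "metalsplice_value_error")
  }
  window <- normalize_seq(window, "window")
  if (any(nchar(window) != model$length)) {
    abort(sprintf("window length must be %d for a %s model",
                  model$length, model$site),
          class = "metalsplice_value_error")
  }
  if (model$kind == "pwm") {
    vapply(window, function(w) {
      b <- strsplit(w, "", fixed = TRUE)[[1L]]
      sum(log2(model$probs[cbind(match(b, DNA_BASES), seq_along(b))] / 0.25))
    }, numeric(1L), USE.NAMES = FALSE)
  } else {
    s <- unname(model$scores[window])
    if (anyNA(s)) {
      abort(sprintf("window '%s' absent from score table",
                    window[is.na(s)][1L]),
            class = "metalsplice_value_error")
    }
    s
  }
}

#' Classify the terminal NAG of an intron
#'
#' Reports the last three intronic nucleotides as CAG/TAG/AAG/GAG when the
#' intron ends in AG, `"other"` otherwise, plus the -3 base.
#'
#' @param intron Nucleotide string(s), length >= 3.
#' @return Tibble: `terminal_nag`, `minus3`.
#' @export
classify_terminal_nag <- function(intron) {
  intron <- normalize_seq(intron, "intron")
  if (any(nchar(intron) < 3L)) {
    abort("intron must be at least 3 nt", class = "metalsplice_value_error")
  }
  last3 <- substring(intron, nchar(intron) - 2L, nchar(intron))
  m3 <- substring(last3, 1L, 1L)
  nag <- ifelse(substring(last3, 2L, 3L) == "AG", last3, "other")
  tibble::tibble(terminal_nag = nag, minus3 = m3)
}

# Builtin 7-mer branchpoint weight model: CU-rich context around the branch
# adenine at window position 6 of 7 (yeast-consensus-flavoured TACTAAC is
# the unique argmax). Probabilities, scored as log2 odds vs uniform.
branchpoint_probs <- function() {
  p <- function(a, c, g, t) c(A = a, C = c, G = g, T = t)
  m <- cbind(p(.15, .30, .10, .45), p(.50, .20, .10, .20),
             p(.10, .50, .10, .30), p(.10, .15, .05, .70),
             p(.50, .15, .20, .15), p(.97, .01, .01, .01),
             p(.10, .50, .10, .30))
  rownames(m) <- DNA_BASES
  m
}

#' Call the best lariat branchpoint in an acceptor window
#'
#' Scans every adenine at positions `window[1]..window[2]` relative to the
#' 3'ss (builtin mode) with a 7-mer log-odds weight model whose branch
#' adenine sits at window position 6, or filters externally computed calls
#' (imported mode) to the window. Branchpoints outside -60..-13 are ignored
#' by default, matching the positioning of the vast majority of human
#' branchpoints. Score ties break toward the 3'-most adenine.
#'
#' @param intron Nucleotide string, length >= 20.
#' @param window Integer vector `c(min, max)` of allowed branch positions
#'   (negative; default `c(-60, -13)`).
#' @param mode `"builtin_pwm"` or `"imported"`.
#' @param imported_calls Tibble with columns `pos`, `score` (required for
#'   imported mode).
#' @return One-row tibble `pos`, `score`, `method`, or a zero-row tibble
#'   when no call lies in the window.
#' @export
call_branchpoint <- function(intron, window = c(-60L, -13L),
                             mode = c("builtin_pwm", "imported"),
                             imported_calls = NULL) {
  mode <- match.arg(mode)
  empty <- tibble::tibble(pos = integer(0), score = numeric(0),
                          method = character(0))
  if (mode == "imported") {
    if (is.null(imported_calls)) {
      abort("imported mode requires imported_calls",
            class = "metalsplice_value_error")
    }
    keep <- imported_calls$pos >= window[1L] & imported_calls$pos <= window[2L]
    calls <- imported_calls[keep, , drop = FALSE]
    if (!nrow(calls)) return(empty)
    best <- calls[calls$score == max(calls$score), , drop = FALSE]
    best <- best[which.max(best$pos), , drop = FALSE]
    return(tibble::tibble(pos = as.integer(best$pos), score = best$score,
                          method = "imported"))
  }
  intron <- normalize_seq(intron, "intron")
  n <- nchar(intron)
  if (n < 20L) abort("intron must be at least 20 nt",
                     class = "metalsplice_value_error")
  probs <- branchpoint_probs()
  cand <- max(window[1L], -(n - 5L)):min(window[2L], -2L)
  b <- base_at(intron, cand)
  cand <- cand[!is.na(b) & b == "A"]
  if (!length(cand)) return(empty)
  scores <- vapply(cand, function(p) {
    i <- n + p + 1L            # 1-based index of branch A
    w <- substring(intron, i - 5L, i + 1L)
    if (nchar(w) != 7L) return(-Inf)
    b <- strsplit(w, "", fixed = TRUE)[[1L]]
    sum(log2(probs[cbind(match(b, DNA_BASES), 1:7)] / 0.25))
  }, numeric(1L))
  ok <- is.finite(scores)
  cand <- cand[ok]; scores <- scores[ok]
  if (!length(cand)) return(empty)
  best <- which(scores == max(scores))
  pick <- best[which.max(cand[best])]
  tibble::tibble(pos = as.integer(cand[pick]), score = scores[pick],
                 method = "builtin_pwm")
}

#' Length of the AG-dinucleotide exclusion zone
#'
#' Number of nucleotides strictly between the nearest upstream AG and the
#' 3'ss AG. When the provided sequence contains no upstream AG the zone is
#' censored at the available scan length.
#'
#' @param intron Nucleotide string ending in AG.
#' @return One-row tibble: `agez_len`, `censored`.
#' @export
agez_length <- function(intron) {
  intron <- normalize_seq(intron, "intron")
  n <- nchar(intron)
  if (n < 2L || substring(intron, n - 1L, n) != "AG") {
    abort("AGEZ is defined only for introns ending in AG",
          class = "metalsplice_value_error")
  }
  starts <- gregexpr("(?=AG)", intron, perl = TRUE)[[1L]]
  starts <- starts[starts > 0L & starts < n - 1L]  # exclude the terminal AG
  if (!length(starts)) {
    return(tibble::tibble(agez_len = n - 2L, censored = TRUE))
  }
  i <- max(starts)                       # nearest upstream AG (5' base at i)
  tibble::tibble(agez_len = (n - 2L) - (i + 2L) + 1L, censored = FALSE)
}

# 1-based index range of the region strictly between the branch A
# (exclusive) and the 3'ss AG (exclusive): positions bp+1 .. -3.
ppt_region_bounds <- function(n, bp_pos) {
  if (is.null(bp_pos) || is.na(bp_pos)) bp_pos <- max(-30L, -n)
  from <- n + bp_pos + 2L
  to <- n - 2L                            # index of position -3 is n - 2
  c(max(1L, from), to)
}

# Maximum-sum contiguous subsegment (empty segment allowed => score >= 0).
max_subsegment_sum <- function(w) {
  best <- 0; cur <- 0
  for (x in w) {
    cur <- max(0, cur + x)
    best <- max(best, cur)
  }
  best
}

#' Polypyrimidine-tract metrics
#'
#' The uridine profile marks which of positions -4..-18 relative to the
#' 3'ss carry T. The PPT score is a transparent maximum-sum-subsegment
#' statistic over the region strictly between the branch adenine and the
#' 3'ss AG, with weights T = +1.0, C = +0.5, A = G = -2.0; the pyrimidine
#' fraction is computed over the same region. When no branchpoint is
#' supplied the region defaults to positions -30..-3.
#'
#' @param intron Nucleotide string.
#' @param bp_pos Branch adenine position (negative) or `NULL`.
#' @return List: `u_profile` (named 0/1/NA vector, positions -4..-18; NA
#'   where the intron is too short, with `partial = TRUE`), `ppt_score`,
#'   `pyr_fraction`, `region` (the region string), `partial`.
#' @export
ppt_metrics <- function(intron, bp_pos = NULL) {
  intron <- normalize_seq(intron, "intron")
  n <- nchar(intron)
  pos <- -4:-18
  bases <- base_at(intron, pos)
  u_profile <- setNames(ifelse(is.na(bases), NA_integer_,
                               as.integer(bases == "T")),
                        as.character(pos))
  bounds <- ppt_region_bounds(n, bp_pos)
  region <- if (bounds[1L] > bounds[2L]) ""
  else substring(intron, bounds[1L], bounds[2L])
  w <- c(A = -2, C = 0.5, G = -2, T = 1)
  rb <- if (nzchar(region)) strsplit(region, "", fixed = TRUE)[[1L]]
  else character(0)
  list(
    u_profile = u_profile,
    ppt_score = if (length(rb)) max_subsegment_sum(unname(w[rb])) else 0,
    pyr_fraction = if (length(rb)) mean(rb %in% c("C", "T")) else NA_real_,
    region = region,
    partial = anyNA(u_profile))
}

#' Count motifs between the branchpoint and the 3'ss AG
#'
#' Counts overlapping occurrences of each motif strictly between the
#' branch adenine and the 3'ss AG (the PPT region).
#'
#' @param intron Nucleotide string.
#' @param bp_pos Branch adenine position (negative).
#' @param motifs Character vector of k-mers (default `(U)4` and `(C)4`).
#' @return Tibble: `motif`, `count` (overlapping), `present`.
#' @export
motif_counts <- function(intron, bp_pos, motifs = c("TTTT", "CCCC")) {
  intron <- normalize_seq(intron, "intron")
  motifs_n <- normalize_seq(motifs, "motif")
  bounds <- ppt_region_bounds(nchar(intron), bp_pos)
  region <- if (bounds[1L] > bounds[2L]) ""
  else substring(intron, bounds[1L], bounds[2L])
  count <- vapply(motifs_n, function(m) {
    if (!nzchar(region) || nchar(region) < nchar(m)) return(0L)
    hits <- gregexpr(paste0("(?=", m, ")"), region, perl = TRUE)[[1L]]
    sum(hits > 0L)
  }, integer(1L))
  tibble::tibble(motif = motifs, count = unname(count),
                 present = unname(count) > 0L)
}

#' Classify intron type by its termini
#'
#' `GT..AG` (major spliceosome), `AT..AC` (U12-type flag), anything else
#' `other`.
#'
#' @param intron Nucleotide string(s), length >= 4.
#' @return Character vector: `"GT-AG"`, `"AT-AC"` or `"other"`.
#' @export
intron_type <- function(intron) {
  intron <- normalize_seq(intron, "intron")
  if (any(nchar(intron) < 4L)) {
    abort("intron must be at least 4 nt", class = "metalsplice_value_error")
  }
  first2 <- substring(intron, 1L, 2L)
  last2 <- substring(intron, nchar(intron) - 1L, nchar(intron))
  dplyr::case_when(first2 == "GT" & last2 == "AG" ~ "GT-AG",
                   first2 == "AT" & last2 == "AC" ~ "AT-AC",
                   TRUE ~ "other")
}

#' Acceptor architecture of an intron cohort
#'
#' Computes, per intron: terminal NAG class and -3 base, intron type,
#' branchpoint call, AGEZ length, PPT score, pyrimidine fraction, and
#' `(U)4`/`(C)4` motif counts between branchpoint and 3'ss.
#'
#' @param introns Tibble with `intron_id` and `seq`; extra columns (e.g.
#'   `group`) carried through.
#' @param bp_window Branchpoint window passed to [call_branchpoint()].
#' @return Tibble, one row per intron.
#' @export
acceptor_architecture <- function(introns, bp_window = c(-60L, -13L)) {
  if (!all(c("intron_id", "seq") %in% names(introns))) {
    abort("introns needs columns intron_id, seq",
          class = "metalsplice_value_error")
  }
  nag <- classify_terminal_nag(introns$seq)
  per <- purrr::map_dfr(introns$seq, function(s) {
    bp <- call_branchpoint(s, window = bp_window)
    bp_pos <- if (nrow(bp)) bp$pos else NA_integer_
    ag <- if (intron_type(s) != "AT-AC" &&
              substring(s, nchar(s) - 1L, nchar(s)) == "AG") agez_length(s)
    else tibble::tibble(agez_len = NA_integer_, censored = NA)
    pm <- ppt_metrics(s, if (is.na(bp_pos)) NULL else bp_pos)
    mc <- motif_counts(s, if (is.na(bp_pos)) NULL else bp_pos)
    tibble::tibble(
      bp_pos = bp_pos,
      bp_score = if (nrow(bp)) bp$score else NA_real_,
      bp_to_3ss_len = if (is.na(bp_pos)) NA_integer_ else -bp_pos,
      agez_len = ag$agez_len, agez_censored = ag$censored,
      ppt_score = pm$ppt_score, pyr_fraction = pm$pyr_fraction,
      u4_count = mc$count[mc$motif == "TTTT"],
      c4_count = mc$count[mc$motif == "CCCC"])
  })
  dplyr::bind_cols(introns[setdiff(names(introns), "seq")], nag,
                   tibble::tibble(intron_type = intron_type(introns$seq)),
                   per)
}

#' Long-format uridine profile for an intron cohort
#'
#' @param introns Tibble with `intron_id`, `seq`; extra columns carried.
#' @return Long tibble: one row per intron x position (-4..-18), with
#'   `is_u` in \{0,1,NA\}.
#' @export
ppt_u_profile <- function(introns) {
  purrr::map2_dfr(introns$intron_id, introns$seq, function(id, s) {
    pm <- ppt_metrics(s)
    tibble::tibble(intron_id = id,
                   pos = as.integer(names(pm$u_profile)),
                   is_u = as.integer(pm$u_profile))
  }) %>%
    dplyr::left_join(introns[setdiff(names(introns), "seq")],
                     by = "intron_id")
}

#' Allelic association of the -3 pyrimidine with the first exon positions
#'
#' For each of the first six exon positions and each base, builds the 2x2
#' table (-3 T/C by base present/absent), reporting the odds ratio for
#' -3T (Haldane 0.5 correction when a cell is empty), a 1-df chi-square
#' and, per position, the base most associated with -3T (maximum odds
#' ratio).
#'
#' @param records Tibble with columns `minus3` (values `"T"`/`"C"`) and
#'   `first6` (first six exon nucleotides).
#' @return Tibble, 24 rows: `position`, `base`, the four counts,
#'   `odds_ratio`, `chi_square`, `p_value`, `most_associated`.
#' @export
minus3_association <- function(records) {
  if (!all(c("minus3", "first6") %in% names(records))) {
    abort("records needs columns minus3, first6",
          class = "metalsplice_value_error")
  }
  keep <- records$minus3 %in% c("T", "C")
  records <- records[keep, , drop = FALSE]
  f6 <- normalize_seq(records$first6, "first6")
  if (any(nchar(f6) != 6L)) {
    abort("first6 must be 6-mers", class = "metalsplice_value_error")
  }
  is_t <- records$minus3 == "T"
  if (sum(is_t) < 2L || sum(!is_t) < 2L) {
    abort("need at least 2 records of each -3 class",
          class = "metalsplice_value_error")
  }
  grid <- tidyr::expand_grid(position = 1:6, base = DNA_BASES)
  out <- purrr::pmap_dfr(grid, function(position, base) {
    hit <- substring(f6, position, position) == base
    a <- sum(is_t & hit); b <- sum(is_t & !hit)
    c_ <- sum(!is_t & hit); d <- sum(!is_t & !hit)
    cells <- c(a, b, c_, d)
    if (any(cells == 0L)) cells <- cells + 0.5    # Haldane correction
    or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
    tab <- rbind(c(a, b), c(c_, d))
    chi <- if (any(colSums(tab) == 0L)) list(statistic = 0, p.value = 1)
    else suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(position = position, base = base,
                   n_t_present = a, n_t_absent = b,
                   n_c_present = c_, n_c_absent = d,
                   odds_ratio = or,
                   chi_square = unname(chi$statistic),
                   p_value = chi$p.value)
  })
  out %>%
    dplyr::group_by(.data$position) %>%
    dplyr::mutate(most_associated = .data$odds_ratio ==
                    max(.data$odds_ratio)) %>%
    dplyr::ungroup()
}
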