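# End-to-end orchestration: codon scoring -> exon profiling -> acceptor
# architecture -> inclusion -> disorder correlation, with a TSV/JSON report
# bundle. Identical config + seed gives identical outputs.

#' Default pipeline configuration
#'
#' All thresholds in one place: dataset mode and validation filter, the
#' 350 nt exon-length cap, the 90% PSI candidate threshold, the microexon
#' cutoff, the smoothing constant for codon frequencies and the
#' branchpoint window.
#'
#' @param ... Overrides for individual entries.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_per_group = c(zn = 60L, ca = 60L),
    dataset_mode = "extended",
    cmm_filter = FALSE,
    max_exon_len = 350L,
    psi_threshold = 90,
    microexon_min_len = 28L,
    smoothing_alpha = 0.5,
    bp_window = c(-60L, -13L),
    psi_tissues = c("neural", "muscle", "testis", "esc"),
    target_r = 0.5,
    delta = 0.3,
    out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config entries: %s",
                  paste(unknown, collapse = ", ")),
          class = "metalsplice_config_error")
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!cfg$dataset_mode %in% c("stringent", "extended")) {
    abort("dataset_mode must be 'stringent' or 'extended'",
          class = "metalsplice_config_error")
  }
  if (cfg$max_exon_len <= 0 || cfg$psi_threshold < 0 ||
      cfg$psi_threshold > 100 || cfg$smoothing_alpha < 0) {
    abort("config threshold out of documented range",
          class = "metalsplice_config_error")
  }
  if (length(cfg$bp_window) != 2L || cfg$bp_window[1L] > cfg$bp_window[2L]) {
    abort("bp_window must be c(min, max) with min <= max",
          class = "metalsplice_config_error")
  }
  invisible(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "metalsplice_pipeline_error")
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates (or accepts) a score table and exon cohort, then executes
#' every stage: coordinating-codon scoring with group aggregation and
#' ANOVA/Kruskal-Wallis, whole-exon profiling and group comparison,
#' acceptor architecture (terminal NAG contingency, branchpoints, AGEZ,
#' PPT metrics, motif contingency, -3 association), inclusion aggregation
#' and candidate selection, and the disorder-scale correlation. When
#' `config$out_dir` is set, TSV tables and a JSON summary are written
#' there.
#'
#' @param config List from [pipeline_config()].
#' @param inputs Optional list with precomputed `score_table` (list of
#'   `table`, `sets`) and `cohort` (list of `exons`, `residues`,
#'   `introns`); generated from the config seed when absent.
#' @return List of stage results (invisibly returned components also
#'   written to disk when `out_dir` is set): `codon_scores`,
#'   `codon_summary`, `codon_anova`, `exon_comparison`, `architecture`,
#'   `nag_chi2`, `acceptor_strength` (per-group acceptor-window PWM
#'   strength), `minus3`, `inclusion`, `candidates`, `disorder`,
#'   `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL) {
  validate_config(config)
  st <- run_stage("score_table", {
    if (!is.null(inputs$score_table)) inputs$score_table
    else gen_score_table(seed = config$seed)
  })
  cohort <- run_stage("cohort", {
    if (!is.null(inputs$cohort)) inputs$cohort
    else gen_exon_cohort(st$table, n_per_group = config$n_per_group,
                         delta = config$delta, seed = config$seed)
  })

  res <- run_stage("dataset_filters", {
    apply_dataset_filters(cohort$residues, mode = config$dataset_mode,
                          cmm_filter = config$cmm_filter)
  })
  codon_scores <- run_stage("codon_scoring", {
    score_codons(res, cohort$exons, st$table)
  })
  ok_scores <- dplyr::filter(codon_scores, .data$status == "ok")
  codon_summary <- run_stage("codon_aggregation", {
    aggregate_codon_scores(ok_scores)
  })
  codon_anova <- run_stage("codon_anova", {
    one_way_anova(ok_scores, ln_ratio, group)
  })

  exons_cmp <- run_stage("exon_filter", {
    filter_exons_for_comparison(cohort$exons, config$max_exon_len)
  })
  profiles <- run_stage("exon_profiles", {
    exon_profile(st$table, exons_cmp)
  })
  exon_comparison <- run_stage("exon_comparison", {
    compare_exon_groups(profiles)
  })

  arch <- run_stage("acceptor_architecture", {
    acceptor_architecture(cohort$introns, bp_window = config$bp_window)
  })
  nag_tab <- run_stage("nag_contingency", {
    t(table(arch$group, factor(arch$terminal_nag,
                               levels = c("CAG", "TAG", "AAG", "GAG"))))
  })
  nag_chi2 <- run_stage("nag_chi2", {
    keep <- rowSums(nag_tab) > 0
    chi2_contingency(t(nag_tab[keep, , drop = FALSE]))
  })
  site_strength <- run_stage("site_strength", {
    ac <- splice_site_pwm("acceptor")
    major <- cohort$introns[intron_type(cohort$introns$seq) == "GT-AG", ]
    win <- paste0(
      substring(major$seq, nchar(major$seq) - 19L, nchar(major$seq)),
      substring(major$first6, 1L, 3L))
    tibble::tibble(group = major$group,
                   score = score_site(ac, win)) %>%
      dplyr::group_by(.data$group) %>%
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                       sem = sem(.data$score), .groups = "drop")
  })
  minus3 <- run_stage("minus3_association", {
    gtag <- dplyr::filter(cohort$introns, !is.na(.data$minus3_true),
                          .data$minus3_true %in% c("C", "T"))
    minus3_association(tibble::tibble(minus3 = gtag$minus3_true,
                                      first6 = gtag$first6))
  })

  psi <- run_stage("psi", {
    gen_psi_table(unique(cohort$exons$exon_id),
                  tissues = config$psi_tissues, seed = config$seed)
  })
  psi <- dplyr::left_join(psi,
                          cohort$exons[c("exon_id", "group")],
                          by = "exon_id")
  lengths <- tibble::tibble(exon_id = cohort$exons$exon_id,
                            length = nchar(cohort$exons$seq))
  psi_kept <- run_stage("microexon_filter", {
    exclude_small_exons(psi, lengths, config$microexon_min_len)
  })
  inclusion <- run_stage("inclusion_means", {
    mean_inclusion(psi_kept, by = "group")
  })
  candidates <- run_stage("candidate_selection", {
    select_candidates(psi_kept, threshold = config$psi_threshold,
                      tissue_set = config$psi_tissues)
  })

  disorder <- run_stage("disorder_correlation", {
    prof <- codon_frequency_profile(st$sets, alpha = config$smoothing_alpha)
    aa <- aa_level_lnratio(prof)
    scale <- gen_disorder_scale(aa, target_r = config$target_r,
                                seed = config$seed)
    correlate_scale(aa, scale)
  })

  summary <- list(
    config = config[setdiff(names(config), "out_dir")],
    codon_groups = codon_summary,
    codon_anova = codon_anova,
    exon_groups = exon_comparison$summary,
    exon_anova = exon_comparison$anova,
    exon_kruskal = exon_comparison$kruskal,
    nag_chi2 = nag_chi2,
    acceptor_strength = site_strength,
    minus3_top = dplyr::filter(minus3, .data$most_associated),
    inclusion = inclusion,
    n_candidates = nrow(candidates),
    disorder = disorder)

  out <- list(codon_scores = codon_scores, codon_summary = codon_summary,
              codon_anova = codon_anova, exon_comparison = exon_comparison,
              architecture = arch, nag_chi2 = nag_chi2,
              acceptor_strength = site_strength, minus3 = minus3,
              inclusion = inclusion, candidates = candidates,
              disorder = disorder, summary = summary)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(codon_scores, file.path(config$out_dir,
                                             "codon_scores.tsv"))
    readr::write_tsv(codon_summary, file.path(config$out_dir,
                                              "codon_summary.tsv"))
    readr::write_tsv(arch, file.path(config$out_dir, "architecture.tsv"))
    readr::write_tsv(minus3, file.path(config$out_dir,
                                       "minus3_association.tsv"))
    readr::write_tsv(inclusion, file.path(config$out_dir, "inclusion.tsv"))
    readr::write_tsv(candidates, file.path(config$out_dir,
                                           "candidates.tsv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(out)
}
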