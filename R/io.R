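# Readers and writers for the cohort file formats: FASTA for sequences
# (record ids carry exon_id|gene|group), TSV for everything tabular.

need_biostrings <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("FASTA I/O requires the Biostrings package",
          class = "metalsplice_dependency_error")
  }
}

#' Write exon records to FASTA plus a flanking-intron TSV
#'
#' The FASTA id line is `exon_id|gene|group`; intron flanks (sense strand)
#' go to `<path>.flanks.tsv`.
#'
#' @param exons Exon tibble (`exon_id`, `gene`, `group`, `seq`,
#'   `upstream_intron`, `downstream_intron`).
#' @param path FASTA output path.
#' @return `path`, invisibly.
#' @export
write_exon_fasta <- function(exons, path) {
  need_biostrings()
  ss <- Biostrings::DNAStringSet(exons$seq)
  names(ss) <- paste(exons$exon_id, exons$gene, exons$group, sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  readr::write_tsv(exons[c("exon_id", "upstream_intron",
                           "downstream_intron")],
                   paste0(path, ".flanks.tsv"))
  invisible(path)
}

#' Read exon records from FASTA (with optional flank TSV)
#'
#' @param path FASTA path written by [write_exon_fasta()]; the
#'   `<path>.flanks.tsv` sidecar is read when present.
#' @return Exon tibble.
#' @export
read_exon_fasta <- function(path) {
  need_biostrings()
  ss <- Biostrings::readDNAStringSet(path)
  meta <- stringr::str_split_fixed(names(ss), stringr::fixed("|"), 3L)
  out <- tibble::tibble(exon_id = meta[, 1L], gene = meta[, 2L],
                        group = meta[, 3L], seq = unname(as.character(ss)))
  sidecar <- paste0(path, ".flanks.tsv")
  if (file.exists(sidecar)) {
    fl <- readr::read_tsv(sidecar, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    out <- dplyr::left_join(out, fl, by = "exon_id")
  }
  out
}

#' Write / read introns as FASTA
#'
#' @param introns Tibble with `intron_id`, `seq` (and optionally `group`).
#' @param path FASTA path.
#' @return `path` / an intron tibble.
#' @export
write_intron_fasta <- function(introns, path) {
  need_biostrings()
  ss <- Biostrings::DNAStringSet(introns$seq)
  grp <- if ("group" %in% names(introns)) introns$group else "NA"
  names(ss) <- paste(introns$intron_id, grp, sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' @rdname write_intron_fasta
#' @export
read_intron_fasta <- function(path) {
  need_biostrings()
  ss <- Biostrings::readDNAStringSet(path)
  meta <- stringr::str_split_fixed(names(ss), stringr::fixed("|"), 2L)
  tibble::tibble(intron_id = meta[, 1L], group = meta[, 2L],
                 seq = unname(as.character(ss)))
}

#' Read imported branchpoint calls from TSV
#'
#' Columns: `intron_id`, `pos` (negative, relative to the 3'ss), `score`,
#' optional `method`.
#'
#' @param path TSV path.
#' @return Tibble of calls.
#' @export
read_branchpoint_calls <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    intron_id = "c", pos = "i", score = "d", .default = "c"),
    progress = FALSE)
  if (!all(c("intron_id", "pos", "score") %in% names(df))) {
    abort(sprintf("%s: need columns intron_id, pos, score", path),
          class = "metalsplice_parse_error")
  }
  df
}

#' Read an inclusion (PSI/EST) table from TSV
#'
#' Long format: `exon_id`, `tissue`, `value`, optional `category` and
#' `source`. Wide tables (one column per tissue) are reshaped when
#' `wide = TRUE`.
#'
#' @param path TSV path.
#' @param wide Reshape a wide exon-by-tissue table.
#' @return Inclusion tibble.
#' @export
read_inclusion_table <- function(path, wide = FALSE) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (wide) {
    df <- tidyr::pivot_longer(df, -dplyr::all_of("exon_id"),
                              names_to = "tissue", values_to = "value")
  }
  if (!all(c("exon_id", "tissue", "value") %in% names(df))) {
    abort(sprintf("%s: need columns exon_id, tissue, value", path),
          class = "metalsplice_parse_error")
  }
  check_psi_values(df$value)
  df
}

#' Materialize a full synthetic demo cohort on disk
#'
#' Writes every file format the readers consume: the hexamer score table
#' and high-confidence sets, exon FASTA with flank sidecar, residue
#' annotations, intron FASTA, a PSI table and a synthetic disorder scale.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all generators.
#' @param n_per_group Exon counts per group (passed to
#'   [gen_exon_cohort()]).
#' @return Named list of the written file paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L,
                           n_per_group = c(zn = 40L, ca = 40L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- gen_score_table(seed = seed)
  cohort <- gen_exon_cohort(st$table, n_per_group = n_per_group,
                            seed = seed)
  psi <- gen_psi_table(unique(cohort$exons$exon_id), seed = seed)
  prof <- codon_frequency_profile(st$sets)
  aa <- aa_level_lnratio(prof)
  scale <- gen_disorder_scale(aa, target_r = 0.5, seed = seed)
  paths <- list(
    score_table = file.path(dir, "score_table.tsv"),
    hexamer_sets = file.path(dir, "hexamer_sets.tsv"),
    exons = file.path(dir, "exons.fasta"),
    residues = file.path(dir, "residues.tsv"),
    introns = file.path(dir, "introns.fasta"),
    psi = file.path(dir, "psi.tsv"),
    disorder_scale = file.path(dir, "disorder_scale.tsv"))
  readr::write_tsv(st$table, paths$score_table)
  readr::write_tsv(
    tibble::tibble(hexamer = c(st$sets$ese_set, st$sets$ess_set),
                   set = rep(c("ese", "ess"),
                             c(length(st$sets$ese_set),
                               length(st$sets$ess_set)))),
    paths$hexamer_sets)
  write_exon_fasta(cohort$exons, paths$exons)
  readr::write_tsv(cohort$residues, paths$residues)
  write_intron_fasta(cohort$introns, paths$introns)
  readr::write_tsv(psi, paths$psi)
  readr::write_tsv(scale, paths$disorder_scale)
  invisible(paths)
}
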