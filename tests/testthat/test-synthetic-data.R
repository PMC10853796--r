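test_that("score-table generation is seeded, sized and feasibility-checked", {
  st1 <- gen_score_table(seed = 7)
  st2 <- gen_score_table(seed = 7)
  expect_identical(st1$table, st2$table)
  expect_equal(length(st1$sets$ese_set), 1182L)
  expect_equal(length(st1$sets$ess_set), 1090L)
  expect_equal(nrow(st1$table), 4096L)
  cls_counts <- table(st1$table$class)
  expect_equal(as.vector(cls_counts[c("E", "S", "N")]),
               c(1182L, 1090L, 1824L))
  # enhancers score higher on the enhancer axis, silencers the reverse
  e <- st1$table[st1$table$class == "E", ]
  s <- st1$table[st1$table$class == "S", ]
  expect_gt(mean(e$ese_score - e$ess_score), 0)
  expect_lt(mean(s$ese_score - s$ess_score), 0)
  expect_error(gen_score_table(n_e = 2000, n_s = 2000, n_n = 100),
               "infeasible")
  st3 <- gen_score_table(seed = 8)
  expect_false(identical(st1$table$class, st3$table$class))
})

test_that("exon cohorts are reproducible and plant the codon pools", {
  st <- gen_score_table(seed = 7)
  c1 <- gen_exon_cohort(st$table, n_per_group = c(zn = 30, ca = 30),
                        seed = 4)
  c2 <- gen_exon_cohort(st$table, n_per_group = c(zn = 30, ca = 30),
                        seed = 4)
  expect_identical(c1$exons, c2$exons)
  expect_identical(c1$residues, c2$residues)

  # coordinating codons come from the right pools
  zn_res <- c1$residues[c1$residues$metal == "Zn", ]
  ca_res <- c1$residues[c1$residues$metal == "Ca", ]
  zn_codons <- substr(
    c1$exons$seq[match(zn_res$exon_id, c1$exons$exon_id)],
    zn_res$codon_start_in_exon + 1, zn_res$codon_start_in_exon + 3)
  expect_true(all(zn_codons %in% c("TGC", "TGT", "CAC", "CAT")))
  expect_true(all(zn_res$residue %in% c("C", "H")))
  expect_true(all(ca_res$residue %in% c("D", "E")))

  # realized coordinating fraction close to the requested 0.2
  frac <- nrow(c1$residues) / (sum(nchar(c1$exons$seq)) / 3)
  expect_lt(abs(frac - 0.2), 0.03)

  # whole-codon exons within the length range
  lens <- nchar(c1$exons$seq)
  expect_true(all(lens %% 3 == 0))
  expect_true(all(lens >= 75 & lens <= 249))

  # near_junction flags consistent with codon placement
  r <- c1$residues
  len_of <- nchar(c1$exons$seq)[match(r$exon_id, c1$exons$exon_id)]
  expect_equal(r$near_junction,
               r$codon_start_in_exon < 3 |
                 r$codon_start_in_exon + 3 > len_of - 3)
})

test_that("an unachievable planted difference raises a diagnostic error", {
  st <- gen_score_table(seed = 7)
  expect_error(gen_exon_cohort(st$table, n_per_group = c(zn = 5, ca = 5),
                               delta = 50, seed = 1),
               "unachievable")
})

test_that("a null cohort (delta = 0) shows no systematic group difference", {
  st <- gen_score_table(seed = 7)
  diffs <- vapply(1:12, function(s) {
    co <- gen_exon_cohort(st$table, n_per_group = c(zn = 60, ca = 60),
                          delta = 0, seed = s)
    p <- exon_profile(st$table, co$exons)
    m <- tapply(p$mean_ln_ratio, p$group, mean)
    se <- tapply(p$mean_ln_ratio, p$group, function(x)
      sd(x) / sqrt(length(x)))
    (m["ca"] - m["zn"]) / sqrt(sum(se^2))
  }, 1)
  # standardized differences behave like z-scores under the null
  expect_lt(mean(abs(diffs) > 2), 0.35)
  expect_lt(abs(mean(diffs)), 1.5)
})

test_that("intron generation is seeded and honours its parameter knobs", {
  p <- intron_group_defaults("Zn")
  i1 <- gen_intron(25, p, seed = 5)
  expect_identical(i1, gen_intron(25, p, seed = 5))
  expect_true(all(nchar(i1$seq) == p$length))

  # deterministic -3 identity
  p3 <- p; p3$minus3_prob <- c(T = 1); p3$u12_frac <- 0
  i3 <- gen_intron(20, p3, seed = 6)
  expect_true(all(substr(i3$seq, nchar(i3$seq) - 2, nchar(i3$seq)) ==
                    "TAG"))

  # planted uridine content recovered from the -4..-18 profile
  p9 <- p; p9$ppt_u_content <- 0.9
  i9 <- gen_intron(400, p9, seed = 7)
  up <- ppt_u_profile(dplyr::mutate(i9, group = "zn"))
  expect_lt(abs(mean(up$is_u, na.rm = TRUE) - 0.9), 0.05)

  # type fractions follow u12_frac
  pc <- intron_group_defaults("Ca"); pc$u12_frac <- 0.5
  ic <- gen_intron(300, pc, seed = 8)
  expect_lt(abs(mean(intron_type(ic$seq) == "AT-AC") - 0.5), 0.1)
})

test_that("generated records satisfy the module type invariants", {
  st <- gen_score_table(seed = 7)
  co <- gen_exon_cohort(st$table, n_per_group = c(zn = 15, ca = 15),
                        seed = 9)
  expect_true(all(co$residues$residue_pos >= 1))
  expect_true(all(co$residues$cmm_status %in%
                    c("plausible", "problematic", "not_validated")))
  arch <- acceptor_architecture(co$introns)
  gtag <- arch[arch$intron_type == "GT-AG", ]
  expect_true(all(gtag$bp_pos == co$introns$bp_pos_true[
    match(gtag$intron_id, co$introns$intron_id)]))
  psi <- gen_psi_table(co$exons$exon_id, seed = 9)
  expect_true(all(psi$value >= 0 & psi$value <= 100))
  expect_error(gen_psi_table("e", alpha = -1), "Beta parameters")
})

test_that("fixture files round-trip losslessly through the readers", {
  dir <- withr::local_tempdir()
  paths <- write_fixtures(dir, seed = 2, n_per_group = c(zn = 8, ca = 8))
  tab <- read_score_table(paths$score_table)
  expect_equal(nrow(tab), 4096L)
  sets <- read_hexamer_sets(paths$hexamer_sets)
  expect_equal(length(sets$ese_set), 1182L)
  exons <- read_exon_fasta(paths$exons)
  expect_equal(nrow(exons), 16L)
  expect_true(all(c("upstream_intron", "downstream_intron") %in%
                    names(exons)))
  st <- gen_score_table(seed = 2)
  co <- gen_exon_cohort(st$table, n_per_group = c(zn = 8, ca = 8),
                        seed = 2)
  expect_equal(dplyr::arrange(exons, exon_id)$seq,
               dplyr::arrange(co$exons, exon_id)$seq)
  introns <- read_intron_fasta(paths$introns)
  expect_equal(sort(introns$seq), sort(co$introns$seq))
  psi <- read_inclusion_table(paths$psi)
  expect_equal(nrow(psi), 16L * 4L)
})
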