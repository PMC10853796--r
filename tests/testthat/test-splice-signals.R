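test_that("pwm scoring is log2 odds against a uniform background", {
  uni <- matrix(0.25, 4, 23, dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- splice_site_pwm("acceptor", uni)
  expect_equal(score_site(m, random_seq(23, 1)), 0)

  # -3 C vs T closed form: differ only at one position
  probs <- uni
  probs[, 21] <- c(A = 0.0, C = 0.8, G = 0.0, T = 0.2)
  m2 <- splice_site_pwm("acceptor", probs)
  base <- strsplit(random_seq(23, 2), "")[[1]]
  wc <- base; wc[21] <- "C"; wt <- base; wt[21] <- "T"
  expect_equal(score_site(m2, paste(wc, collapse = "")) -
                 score_site(m2, paste(wt, collapse = "")),
               log2(0.8 / 0.2), tolerance = 1e-12)

  expect_error(score_site(m, "ACGT"), "length")
})

test_that("the consensus window maximizes a toy pwm score exhaustively", {
  probs <- cbind(c(A = .7, C = .1, G = .1, T = .1),
                 c(A = .1, C = .6, G = .2, T = .1),
                 c(A = .05, C = .05, G = .8, T = .1),
                 c(A = .1, C = .1, G = .1, T = .7))
  # wrap the 4-position toy in a pwm-like closure using the same math
  score4 <- function(w) {
    b <- strsplit(w, "")[[1]]
    sum(log2(probs[cbind(match(b, c("A", "C", "G", "T")), 1:4)] / 0.25))
  }
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1, paste,
                collapse = "")
  expect_equal(all4[which.max(vapply(all4, score4, 1))], "ACGT")
  # and the per-position sum equals an independent per-position oracle
  m <- splice_site_pwm("donor")
  w <- random_seq(9, 3)
  b <- strsplit(w, "")[[1]]
  pr <- metalsplice:::default_donor_probs()
  want <- sum(vapply(1:9, function(i)
    log2(pr[match(b[i], rownames(pr)), i] / 0.25), 1))
  expect_equal(score_site(m, w), want, tolerance = 1e-12)
})

test_that("terminal NAG classification reads the last three nucleotides", {
  r <- classify_terminal_nag(c("GTTTTTCAG", "GTTTTTTAG", "GTTTTTAAC"))
  expect_equal(r$terminal_nag, c("CAG", "TAG", "other"))
  expect_equal(r$minus3, c("C", "T", "A"))
})

test_that("branchpoint calls recover planted motifs and obey the window", {
  # planted TACTAAC with branch A at -25, A-free window elsewhere
  tail_part <- paste0("TACTAAC", strrep("TC", 10), "CAG")  # branch at -25
  intron <- paste0("GT", strrep("C", 40), tail_part)
  call <- call_branchpoint(intron)
  expect_equal(call$pos, -25L)
  expect_equal(call$method, "builtin_pwm")

  # only adenine outside the window: no call
  intron2 <- paste0("GT", strrep("C", 30), "TACTAAC",
                    strrep("C", 68), "CTG")
  # branch A sits ~ -70; window scan must come back empty
  expect_equal(nrow(call_branchpoint(intron2)), 0L)

  # tie-break toward the 3'-most position (imported calls)
  calls <- tibble::tibble(pos = c(-30L, -20L), score = c(5, 5))
  got <- call_branchpoint(strrep("C", 50), mode = "imported",
                          imported_calls = calls)
  expect_equal(got$pos, -20L)
  keep <- call_branchpoint(strrep("C", 50), mode = "imported",
                           imported_calls = tibble::tibble(pos = -70L,
                                                           score = 9))
  expect_equal(nrow(keep), 0L)
  expect_error(call_branchpoint(strrep("C", 50), mode = "imported"),
               "imported_calls")
})

test_that("planted branchpoints across the full window are recovered", {
  p <- intron_group_defaults("Zn")
  p$bp_range <- c(-55L, -14L)
  p$length <- 140L
  ii <- gen_intron(150, p, seed = 21)
  calls <- vapply(ii$seq, function(s) call_branchpoint(s)$pos, 1L)
  expect_true(all(calls == ii$bp_pos_true))
  expect_true(all(calls >= -60 & calls <= -13))
})

test_that("AGEZ length counts nucleotides strictly between AG dinucleotides", {
  r <- agez_length("AGTTTTTTTTTTCAG")
  expect_equal(r$agez_len, 11L)
  expect_false(r$censored)
  r2 <- agez_length("TTTTTTTTTTTTTAG")
  expect_true(r2$censored)
  expect_equal(r2$agez_len, 13L)
  expect_equal(agez_length("AGAG")$agez_len, 0L)
  expect_error(agez_length("GTTTTAC"), "ending in AG")
  # the returned zone never contains AG (rescan property)
  set.seed(6)
  for (i in 1:50) {
    s <- paste0(random_seq(sample(20:60, 1)), "AG")
    r <- agez_length(s)
    zone <- substr(s, nchar(s) - 2L - r$agez_len + 1L, nchar(s) - 2L)
    expect_false(grepl("AG", zone, fixed = TRUE))
  }
})

test_that("PPT scoring equals the exhaustive subsegment oracle", {
  # hand examples via introns whose region is exactly the given string
  mk <- function(region) paste0("GT", strrep("G", 40), region, "AG")
  r1 <- "TTTTCTTTT"
  pm1 <- ppt_metrics(mk(r1), bp_pos = -(nchar(r1) + 3L))
  expect_equal(pm1$ppt_score, 8.5)
  r2 <- "TTTTATTTT"
  pm2 <- ppt_metrics(mk(r2), bp_pos = -(nchar(r2) + 3L))
  expect_equal(pm2$ppt_score, 6.0)
  r3 <- "GAGAGAGAG"
  pm3 <- ppt_metrics(mk(r3), bp_pos = -(nchar(r3) + 3L))
  expect_equal(pm3$ppt_score, 0)

  set.seed(11)
  for (i in 1:100) {
    region <- random_seq(sample(5:30, 1))
    pm <- ppt_metrics(mk(region), bp_pos = -(nchar(region) + 3L))
    expect_equal(pm$ppt_score, oracle_max_segment(ppt_weights(region)))
  }
})

test_that("PPT score is non-negative and monotone under purine-to-T swaps", {
  set.seed(12)
  for (i in 1:40) {
    region <- random_seq(20)
    mk <- function(r) paste0("GT", strrep("G", 40), r, "AG")
    s0 <- ppt_metrics(mk(region), bp_pos = -23L)$ppt_score
    expect_gte(s0, 0)
    pur <- which(strsplit(region, "")[[1]] %in% c("A", "G"))
    if (length(pur)) {
      i0 <- sample(pur, 1)
      region2 <- region
      substr(region2, i0, i0) <- "T"
      expect_gte(ppt_metrics(mk(region2), bp_pos = -23L)$ppt_score, s0)
    }
  }
})

test_that("uridine profile marks T at positions -4..-18", {
  s <- paste0("GT", strrep("C", 50), strrep("T", 15), "CAG")
  pm <- ppt_metrics(s)
  expect_equal(unname(pm$u_profile[as.character(-4:-18)]),
               rep(1L, 15))
  s2 <- paste0("GT", strrep("C", 70), "AG")
  expect_true(all(ppt_metrics(s2)$u_profile == 0L))
})

test_that("motif counting is overlapping and matches a brute-force scan", {
  mk <- function(region) paste0("GT", strrep("G", 40), region, "AG")
  expect_equal(motif_counts(mk("TTTT"), -7L, "TTTT")$count, 1L)
  expect_equal(motif_counts(mk("TTTTT"), -8L, "TTTT")$count, 2L)
  set.seed(13)
  for (i in 1:30) {
    region <- random_seq(30)
    got <- motif_counts(mk(region), -33L, c("TTTT", "CCCC"))
    brute <- vapply(c("TTTT", "CCCC"), function(m) {
      sum(vapply(1:(nchar(region) - 3), function(j)
        substr(region, j, j + 3) == m, NA))
    }, 1L)
    expect_equal(got$count, unname(brute))
  }
})

test_that("intron type classifies GT-AG, AT-AC and everything else", {
  expect_equal(intron_type(c("GTAAGTTTAG", "ATATCCTTAC", "ATATCCTTAA")),
               c("GT-AG", "AT-AC", "other"))
})

test_that("minus3 association reproduces hand 2x2 arithmetic", {
  rec <- tibble::tibble(
    minus3 = rep(c("T", "C"), each = 100),
    first6 = c(rep("GAAAAA", 80), rep("CAAAAA", 20),
               rep("GAAAAA", 40), rep("CAAAAA", 60)))
  as <- minus3_association(rec)
  g1 <- as[as$position == 1 & as$base == "G", ]
  expect_equal(g1$odds_ratio, 6.0)
  expect_equal(g1$chi_square, 200 * (80 * 60 - 20 * 40)^2 /
                 (100 * 100 * 120 * 80), tolerance = 1e-10)

  # identical distributions: OR 1, chi2 0
  same <- tibble::tibble(minus3 = rep(c("T", "C"), each = 50),
                         first6 = rep(c("GATTAC", "CATTAG"), 50))
  as_same <- minus3_association(same)
  expect_true(all(abs(as_same$chi_square) < 1e-10))
  expect_true(all(abs(as_same$odds_ratio - 1) < 1e-10))

  # label swap inverts the odds ratio
  swapped <- dplyr::mutate(rec, minus3 = ifelse(minus3 == "T", "C", "T"))
  as_sw <- minus3_association(swapped)
  expect_equal(as_sw$odds_ratio, 1 / as$odds_ratio, tolerance = 1e-10)

  expect_error(minus3_association(rec[rec$minus3 == "T", ]),
               "each -3 class")
})

test_that("the planted -3T haplotype is recovered as most associated", {
  ii <- gen_intron(2500, intron_group_defaults("Zn"), seed = 17)
  rec <- dplyr::filter(ii, minus3_true %in% c("C", "T"))
  as <- minus3_association(tibble::tibble(minus3 = rec$minus3_true,
                                          first6 = rec$first6))
  top <- dplyr::arrange(dplyr::filter(as, most_associated), position)
  expect_equal(top$base, c("G", "A", "A", "T", "T", "A"))
})

test_that("acceptor architecture assembles all per-intron metrics", {
  ii <- gen_intron(40, intron_group_defaults("Ca"), seed = 19)
  ii$group <- "ca"
  arch <- acceptor_architecture(ii)
  expect_equal(nrow(arch), 40L)
  gtag <- arch[arch$intron_type == "GT-AG", ]
  expect_true(all(gtag$terminal_nag %in% c("CAG", "TAG", "AAG", "GAG")))
  expect_true(all(gtag$bp_pos >= -60 & gtag$bp_pos <= -13))
  expect_true(all(gtag$ppt_score >= 0))
  expect_true(all(gtag$agez_len >= 0, na.rm = TRUE))
})
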