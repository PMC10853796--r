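test_that("score tables parse from TSV and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hexamer\tese_score\tess_score\tclass",
               "AAAAAA\t2.0\t1.0\tE",
               "CCCCCC\t1.0\t2.0\tS",
               "GGGGGG\t1.0\t1.0\tN"), path)
  tab <- read_score_table(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$class, c("E", "S", "N"))

  writeLines(c("hexamer\tese_score\tess_score",
               "AAAAAA\t2\t1", "AAAAXA\t2\t1"), path)
  expect_error(read_score_table(path), "line 3.*AAAAXA")

  writeLines(c("hexamer\tese_score\tess_score",
               "AAAAAA\t2\t1", "AAAAAA\t2\t1"), path)
  expect_error(read_score_table(path), "line 3.*duplicate|duplicate")

  writeLines(c("hexamer\tese_score", "AAAAAA\t2"), path)
  expect_error(read_score_table(path), "missing required column")
})

test_that("a complete 4096-row table round-trips without duplicates", {
  hx <- metalsplice:::all_hexamers()
  expect_equal(length(hx), 4096L)
  expect_equal(anyDuplicated(hx), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- constant_table()
  readr::write_tsv(tab, path)
  back <- read_score_table(path)
  expect_equal(nrow(back), 4096L)
  expect_equal(back$hexamer, tab$hexamer)
})

test_that("sign-based default classification applies when class is absent", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hexamer\tese_score\tess_score",
               "AAAAAA\t2.0\t1.0",
               "CCCCCC\t1.0\t2.0",
               "GGGGGG\t1.5\t1.5"), path)
  expect_equal(read_score_table(path)$class, c("E", "S", "N"))
})

test_that("codon windows follow the four-start geometry and clip at edges", {
  expect_equal(codon_windows("AAATGCAAA", 3),
               c("AAATGC", "AATGCA", "ATGCAA", "TGCAAA"))
  expect_equal(codon_windows("ACGTACGTA", 0), "ACGTAC")
  expect_equal(codon_windows("ACGTAC", 3), "ACGTAC")
  expect_error(codon_windows("ACGTAC", 4), "not fully inside")
  # oracle: brute-force all in-bounds starts that contain the codon
  set.seed(42)
  for (i in 1:50) {
    s <- random_seq(sample(6:30, 1))
    cs <- sample(0:(nchar(s) - 3), 1)
    starts <- Filter(function(st) st <= cs && st + 6 >= cs + 3 &&
                       st >= 0 && st + 6 <= nchar(s),
                     0:(nchar(s) - 3))
    expect_equal(codon_windows(s, cs),
                 vapply(starts, function(st) substr(s, st + 1, st + 6), ""))
  }
})

test_that("codon tokens slice hexamers into 4 in-frame triplets", {
  expect_equal(codon_tokens("GAAGAA"), c("GAA", "AAG", "AGA", "GAA"))
  expect_equal(codon_tokens("AAAAAA"), rep("AAA", 4))
  expect_error(codon_tokens("AAAA"), "6-mers")
})

test_that("codon scoring averages non-neutral windows and flags statuses", {
  tab <- constant_table(2, 1, "E")
  sc <- score_codon(tab, "ACGTACGTACGT", 4)
  expect_equal(sc$mean_ese, 2)
  expect_equal(sc$mean_ess, 1)
  expect_equal(sc$ln_ratio, log(2))
  expect_equal(sc$n_windows_used, 4L)
  expect_equal(sc$status, "ok")

  # hand example: window ese {1,2,3,4}, ess all 1, all E
  s <- "AAATGCAAA"
  wins <- codon_windows(s, 3)
  tab2 <- constant_table(9, 9, "E")
  tab2$ese_score[match(wins, tab2$hexamer)] <- 1:4
  tab2$ess_score[match(wins, tab2$hexamer)] <- 1
  sc2 <- score_codon(tab2, s, 3)
  expect_equal(sc2$mean_ese, 2.5)
  expect_equal(sc2$ln_ratio, log(2.5), tolerance = 1e-12)

  # boundary codon without full context
  sc3 <- score_codon(tab, "ACGTACGTACGT", 0)
  expect_equal(sc3$status, "undefined_no_context")
  sc4 <- score_codon(tab, "ACGTACGTACGT", 0, require_full_context = FALSE)
  expect_equal(sc4$status, "ok")
  expect_equal(sc4$n_windows_used, 1L)

  # all-neutral context
  ntab <- constant_table(1, 1, "N")
  sc5 <- score_codon(ntab, "ACGTACGTACGT", 4)
  expect_equal(sc5$status, "undefined_all_neutral")
  expect_true(is.na(sc5$ln_ratio))
})

test_that("codon scoring matches the brute-force window oracle", {
  tab <- random_table(seed = 99)
  lkup <- metalsplice:::table_lookup(tab)
  set.seed(7)
  n_match <- 0L
  for (i in 1:300) {
    s <- random_seq(sample(9:40, 1))
    cs <- sample(0:(nchar(s) - 3), 1)
    got <- score_codon(tab, s, cs, require_full_context = FALSE)
    want <- oracle_score_codon(tab, s, cs)
    if (want$n == 0) {
      expect_equal(got$status, "undefined_all_neutral")
    } else {
      expect_equal(got$mean_ese, want$mean_ese, tolerance = 1e-12)
      expect_equal(got$mean_ess, want$mean_ess, tolerance = 1e-12)
      expect_equal(got$n_windows_used, want$n)
    }
    n_match <- n_match + 1L
  }
  expect_equal(n_match, 300L)
})

test_that("constant tables give identical scores for all full-context codons", {
  tab <- constant_table(3, 2, "E")
  s <- random_seq(60, seed = 5)
  scores <- vapply(seq(3, 51, by = 3),
                   function(cs) score_codon(tab, s, cs)$ln_ratio, 1)
  expect_true(all(abs(scores - log(3 / 2)) < 1e-12))
})

test_that("codon frequency profile smooths, sums to one and conserves tokens", {
  sets <- hexamer_sets("AAAAAA", "CCCCCC")
  prof <- codon_frequency_profile(sets, alpha = 0.5)
  aaa <- prof[prof$codon == "AAA", ]
  expect_equal(aaa$ese_f, 4.5 / 36)
  expect_equal(aaa$ess_f, 0.5 / 36)
  expect_equal(aaa$ln_f_ratio, log(9), tolerance = 1e-12)
  expect_equal(sum(prof$ese_f), 1, tolerance = 1e-12)
  expect_equal(sum(prof$ess_f), 1, tolerance = 1e-12)
  expect_error(codon_frequency_profile(sets, alpha = 0),
               "alpha > 0")

  # token conservation on generated sets of the reference sizes
  st <- gen_score_table(seed = 3)
  prof2 <- codon_frequency_profile(st$sets)
  expect_equal(sum(prof2$ese_count), 4L * 1182L)
  expect_equal(sum(prof2$ess_count), 4L * 1090L)
  expect_equal(sum(prof2$ese_f), 1, tolerance = 1e-12)
})

test_that("identical sets give zero log ratios; swapping sets negates them", {
  st <- gen_score_table(n_e = 40, n_s = 40, n_n = 0, seed = 2)
  same <- hexamer_sets(st$sets$ese_set, paste0(st$sets$ess_set))
  # identical content on both sides: build via two disjoint labels is not
  # possible, so compare a set against itself through the count path
  prof_same <- codon_frequency_profile(
    structure(list(ese_set = st$sets$ese_set, ess_set = st$sets$ese_set),
              class = "hexamer_sets"))
  expect_true(all(abs(prof_same$ln_f_ratio) < 1e-12))

  fwd <- codon_frequency_profile(st$sets)
  rev <- codon_frequency_profile(
    structure(list(ese_set = st$sets$ess_set, ess_set = st$sets$ese_set),
              class = "hexamer_sets"))
  expect_equal(fwd$ln_f_ratio, -rev$ln_f_ratio, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fwd$ln_f_ratio, rev$ln_f_ratio)))
  expect_s3_class(same, "hexamer_sets")
})

test_that("group aggregation reports n, mean, SEM, median, IQR", {
  scores <- tibble::tibble(ln_ratio = c(0.1, 0.3, 0.5), status = "ok",
                           group = "g1")
  agg <- aggregate_codon_scores(scores)
  expect_equal(agg$mean, 0.3)
  expect_equal(agg$median, 0.3)
  expect_equal(agg$sem, 0.2 / sqrt(3), tolerance = 1e-6)

  single <- tibble::tibble(ln_ratio = 0.7, status = "ok", group = "solo")
  agg1 <- aggregate_codon_scores(single)
  expect_equal(agg1$mean, 0.7)
  expect_true(is.na(agg1$sem))

  two <- dplyr::bind_rows(scores,
                          dplyr::mutate(scores, group = "g2"))
  agg2 <- aggregate_codon_scores(two)
  expect_equal(agg2$mean[1], agg2$mean[2])
  expect_equal(agg2$sem[1], agg2$sem[2])

  expect_error(aggregate_codon_scores(scores[0, ]), "no scores")
  bad <- dplyr::mutate(scores, status = "undefined_no_context")
  expect_error(aggregate_codon_scores(bad), "status 'ok'")
})
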