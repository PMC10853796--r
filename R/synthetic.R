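# Synthetic-data generators. Every generator is deterministic given its
# seed (the RNG state is saved and restored), and plants structure that the
# analysis stages are expected to recover: group score differences, PPT
# uridine content, branchpoint placement, -3 allele / exon-base
# association, inclusion-level distributions.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a root seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

#' Generate a synthetic hexamer score table and high-confidence sets
#'
#' Draws `n_e` enhancer, `n_s` silencer and `n_n` neutral hexamers (without
#' replacement from the 4096) with positive scores such that enhancers have
#' `ese_score > ess_score` in expectation and silencers the reverse. Set
#' sizes default to the reference resource's 1182 enhancers and 1090
#' silencers; by default the remaining hexamers are neutral, so the table
#' is complete.
#'
#' Class membership follows a noisy compositional latent (purine-leaning
#' hexamers tend to be enhancers, T-rich ones silencers, `comp_noise`
#' standard deviations of Gaussian noise on top), mirroring the
#' composition bias of experimentally derived enhancer/silencer resources;
#' this is what lets codon usage carry a splicing signal in generated
#' exons.
#'
#' @param n_e,n_s,n_n Class counts; `n_e + n_s + n_n` must not exceed 4096.
#' @param comp_noise Noise SD on the compositional latent.
#' @param seed Integer seed.
#' @return List: `table` (score-table tibble), `sets` (`"hexamer_sets"` of
#'   the enhancer and silencer hexamers).
#' @export
gen_score_table <- function(n_e = 1182L, n_s = 1090L,
                            n_n = 4096L - n_e - n_s, comp_noise = 1.5,
                            seed = 1L) {
  n_e <- as.integer(n_e); n_s <- as.integer(n_s); n_n <- as.integer(n_n)
  if (min(n_e, n_s, n_n) < 0L || n_e + n_s + n_n > 4096L) {
    abort("infeasible class counts: need n_e + n_s + n_n <= 4096",
          class = "metalsplice_value_error")
  }
  with_seed(derive_seed(seed, "score_table"), {
    hx <- sample(all_hexamers(), n_e + n_s + n_n)
    w <- c(A = 1, G = 0.5, C = -0.5, T = -1)
    comp <- vapply(strsplit(hx, "", fixed = TRUE),
                   function(b) sum(w[b]), numeric(1L))
    z <- comp + rnorm(length(hx), sd = comp_noise)
    cls <- rep("N", length(hx))
    ord <- order(z, decreasing = TRUE)
    cls[ord[seq_len(n_e)]] <- "E"
    cls[rev(ord)[seq_len(n_s)]] <- "S"
    ese <- numeric(length(hx)); ess <- numeric(length(hx))
    ese[cls == "E"] <- runif(n_e, 1.5, 3.0)
    ess[cls == "E"] <- runif(n_e, 0.5, 1.5)
    ese[cls == "S"] <- runif(n_s, 0.5, 1.5)
    ess[cls == "S"] <- runif(n_s, 1.5, 3.0)
    ese[cls == "N"] <- runif(n_n, 0.8, 1.2)
    ess[cls == "N"] <- runif(n_n, 0.8, 1.2)
    tab <- score_table(hx, ese, ess, class = cls)
    list(table = tab,
         sets = hexamer_sets(hx[cls == "E"], hx[cls == "S"]))
  })
}

# ---- expected exon mean under i.i.d. codon composition --------------------

# Decomposition of all 4096 hexamers into the codon pieces that generate
# them when codons are concatenated, for each of the 3 frame offsets.
hex_decomposition <- function() {
  h <- all_hexamers()
  list(h = h,
       f3 = substring(h, 1, 3), l3 = substring(h, 4, 6),
       s2 = substring(h, 1, 2), m3a = substring(h, 3, 5),
       p1 = substring(h, 6, 6),
       s1 = substring(h, 1, 1), m3b = substring(h, 2, 4),
       p2 = substring(h, 5, 6))
}

marginal <- function(q, piece) {
  # distribution of a codon prefix/suffix under codon distribution q
  tapply(q, piece, sum)
}

# Exact expected per-hexamer ln ratio (neutral excluded, ratio of
# expectations) for sequences of i.i.d. codons drawn from q, marginalised
# over the three frame offsets a hexamer can occupy.
expected_exon_mean <- function(q, lnr, dec) {
  s2d <- marginal(q, substring(names(q), 2, 3))
  p1d <- marginal(q, substring(names(q), 1, 1))
  s1d <- marginal(q, substring(names(q), 3, 3))
  p2d <- marginal(q, substring(names(q), 1, 2))
  P0 <- q[dec$f3] * q[dec$l3]
  P1 <- s2d[dec$s2] * q[dec$m3a] * p1d[dec$p1]
  P2 <- s1d[dec$s1] * q[dec$m3b] * p2d[dec$p2]
  P <- (P0 + P1 + P2) / 3
  v <- lnr[dec$h]
  use <- !is.na(v)
  sum(P[use] * v[use]) / sum(P[use])
}

# Per-codon enhancer-leaning score: mean non-neutral hexamer ln ratio over
# all hexamers containing the codon as an in-frame token.
codon_tilt_scores <- function(lnr) {
  h <- names(lnr)
  tok <- codon_tokens(h)                       # 4 per hexamer, in order
  val <- rep(lnr, each = 4L)
  m <- tapply(val, tok, function(x) mean(x, na.rm = TRUE))
  full <- setNames(rep(0, 64L), all_codons())
  m[is.nan(m)] <- 0
  full[names(m)] <- m
  full - mean(full)
}

# Solve the exponential tilt w so the codon mixture
# f * pool + (1 - f) * softmax(w * s) hits the target expected mean.
calibrate_tilt <- function(target, pool, coord_fraction, lnr, dec,
                           interval = c(-8, 8)) {
  codons <- all_codons()
  gc <- genetic_code()
  sense <- gc[codons] != "*"
  s <- codon_tilt_scores(lnr)
  pool_q <- setNames(rep(0, 64L), codons)
  pool_q[pool] <- 1 / length(pool)
  mix_mean <- function(w) {
    bg <- ifelse(sense, exp(w * s), 0)
    bg <- bg / sum(bg)
    q <- coord_fraction * pool_q + (1 - coord_fraction) * bg
    expected_exon_mean(q, lnr, dec)
  }
  g <- function(w) mix_mean(w) - target
  lo <- g(interval[1L]); hi <- g(interval[2L])
  if (is.na(lo) || is.na(hi) || sign(lo) == sign(hi)) {
    abort(sprintf(paste(
      "target exon mean %.3f is unachievable with this score table",
      "(achievable range %.3f .. %.3f); reduce delta or regenerate the",
      "table"), target, min(lo, hi) + target, max(lo, hi) + target),
      class = "metalsplice_value_error")
  }
  w <- uniroot(g, interval, tol = 1e-6)$root
  bg <- ifelse(sense, exp(w * s), 0)
  bg / sum(bg)
}

#' Generate a synthetic exon cohort with planted group structure
#'
#' Builds whole-codon exons for metal-binding groups. Coordinating codons
#' are drawn from the Zn pool (Cys/His codons TGC, TGT, CAC, CAT) or the
#' Ca pool (Asp/Glu codons GAC, GAT, GAA, GAG) at `coord_fraction` of
#' codon slots; background codons are drawn from a per-group exponentially
#' tilted sense-codon distribution calibrated so the groups' expected
#' whole-exon mean ln(ESE/ESS) values differ by `delta` (Ca above Zn).
#' Residue annotations carry validation status and homology-extension
#' flags at the requested rates (assigned as exact counts). Flanking
#' introns come from [gen_intron()] with the per-group defaults.
#'
#' @param table Score-table tibble (e.g. from [gen_score_table()]).
#' @param n_per_group Named integer vector of exon counts per group.
#' @param metal_of_group Named character vector mapping each group to
#'   `"Zn"` or `"Ca"`.
#' @param len_range Exon length range in nt; lengths are drawn as whole
#'   codons within it.
#' @param coord_fraction Fraction of codon slots that are coordinating.
#' @param delta Planted difference in expected exon mean ln-ratio between
#'   the Ca and Zn metal classes.
#' @param extended_rate Fraction of residue annotations flagged
#'   homology-extended.
#' @param not_validated_rate Fraction flagged `not_validated` (assigned
#'   among non-extended records).
#' @param seed Integer seed.
#' @return List: `exons` (tibble: `exon_id`, `gene`, `group`, `seq`,
#'   `upstream_intron`, `downstream_intron`), `residues` (annotation
#'   tibble), `introns` (the upstream-intron generator output with planted
#'   truth columns).
#' @export
gen_exon_cohort <- function(table,
                            n_per_group = c(zn = 200L, ca = 200L),
                            metal_of_group = c(zn = "Zn", ca = "Ca"),
                            len_range = c(75L, 249L),
                            coord_fraction = 0.2,
                            delta = 0.3,
                            extended_rate = 0.15,
                            not_validated_rate = 0.1,
                            seed = 1L) {
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% names(metal_of_group))) {
    abort("n_per_group names must appear in metal_of_group",
          class = "metalsplice_value_error")
  }
  if (!all(metal_of_group %in% c("Zn", "Ca"))) {
    abort("metal_of_group values must be 'Zn' or 'Ca'",
          class = "metalsplice_value_error")
  }
  pools <- list(Zn = c("TGC", "TGT", "CAC", "CAT"),
                Ca = c("GAC", "GAT", "GAA", "GAG"))
  lk <- table_lookup(table)
  dec <- hex_decomposition()
  # centre = midpoint of the two metals' untilted means; targets +- delta/2
  centre <- mean(vapply(c("Zn", "Ca"), function(m) {
    q0 <- calibrate_target_free(pools[[m]], coord_fraction, lk$lnr, dec)
    q0
  }, numeric(1L)))
  targets <- c(Zn = centre - delta / 2, Ca = centre + delta / 2)
  bg <- lapply(c(Zn = "Zn", Ca = "Ca"), function(m)
    calibrate_tilt(targets[[m]], pools[[m]], coord_fraction, lk$lnr, dec))
  with_seed(derive_seed(seed, "exon_cohort"), {
    codons <- all_codons()
    exon_rows <- list(); res_rows <- list(); intron_rows <- list()
    for (grp in names(n_per_group)) {
      metal <- metal_of_group[[grp]]
      n <- n_per_group[[grp]]
      n_codons <- sample(seq(ceiling(len_range[1L] / 3),
                             floor(len_range[2L] / 3)), n, replace = TRUE)
      up <- gen_intron(n, group_params = intron_group_defaults(metal),
                       seed = derive_seed(seed, paste0("up_", grp)))
      for (i in seq_len(n)) {
        k <- n_codons[i]
        coord <- runif(k) < coord_fraction
        if (!any(coord)) coord[sample.int(k, 1L)] <- TRUE
        cd <- character(k)
        cd[coord] <- sample(pools[[metal]], sum(coord), replace = TRUE)
        cd[!coord] <- sample(codons, sum(!coord), replace = TRUE,
                             prob = bg[[metal]])
        seq <- paste(cd, collapse = "")
        id <- sprintf("%s_exon_%03d", grp, i)
        gene <- sprintf("%s_gene_%03d", grp, i)
        dn <- paste0("GTAAGT",
                     paste(sample(DNA_BASES, 24L, TRUE), collapse = ""))
        exon_rows[[length(exon_rows) + 1L]] <- tibble::tibble(
          exon_id = id, gene = gene, group = grp, seq = seq,
          upstream_intron = up$seq[i], downstream_intron = dn)
        slots <- which(coord)
        cs <- 3L * (slots - 1L)
        res_rows[[length(res_rows) + 1L]] <- tibble::tibble(
          protein_id = gene, exon_id = id, group = grp,
          residue_pos = slots,
          residue = unname(genetic_code()[cd[slots]]),
          metal = metal, codon_start_in_exon = cs,
          near_junction = cs < 3L | (cs + 3L) > (3L * k - 3L))
      }
      upg <- up
      upg$group <- grp
      upg$intron_id <- sprintf("%s_intron_%03d", grp, seq_len(n))
      intron_rows[[length(intron_rows) + 1L]] <- upg
    }
    exons <- dplyr::bind_rows(exon_rows)
    residues <- dplyr::bind_rows(res_rows)
    # validation / homology flags as exact counts at the requested rates
    nr <- nrow(residues)
    n_ext <- round(extended_rate * nr)
    n_nv <- round(not_validated_rate * nr)
    ext_idx <- sample.int(nr, n_ext)
    residues$homology_extended <- seq_len(nr) %in% ext_idx
    core_idx <- setdiff(seq_len(nr), ext_idx)
    if (n_nv > length(core_idx)) {
      abort("not_validated_rate too high for the non-extended subset",
            class = "metalsplice_value_error")
    }
    nv_idx <- sample(core_idx, n_nv)
    residues$cmm_status <- "plausible"
    residues$cmm_status[sample(core_idx, min(length(core_idx),
                                             round(0.1 * nr)))] <-
      "problematic"
    residues$cmm_status[nv_idx] <- "not_validated"
    list(exons = exons, residues = residues,
         introns = dplyr::bind_rows(intron_rows))
  })
}

# Untilted (w = 0) expected mean for a metal pool mixture.
calibrate_target_free <- function(pool, coord_fraction, lnr, dec) {
  codons <- all_codons()
  gc <- genetic_code()
  sense <- gc[codons] != "*"
  bg <- ifelse(sense, 1, 0); bg <- bg / sum(bg)
  pool_q <- setNames(rep(0, 64L), codons)
  pool_q[pool] <- 1 / length(pool)
  q <- coord_fraction * pool_q + (1 - coord_fraction) * bg
  expected_exon_mean(q, lnr, dec)
}

#' Per-metal default intron parameters
#'
#' Zn-preceding introns are uridine-richer with more TAG acceptors and a
#' near-zero U12 fraction; Ca-preceding introns are cytosine-richer with a
#' CAG excess and the larger U12-type fraction, following the direction and
#' magnitude of the genome-scale contrasts this emulates.
#'
#' @param metal `"Zn"` or `"Ca"`.
#' @return Parameter list for [gen_intron()].
#' @export
intron_group_defaults <- function(metal = c("Zn", "Ca")) {
  metal <- match.arg(metal)
  if (metal == "Zn") {
    list(length = 120L, ppt_u_content = 0.55, bp_range = c(-50L, -20L),
         minus3_prob = c(C = 0.50, T = 0.40, A = 0.05, G = 0.05),
         u12_frac = 0.002, assoc_strength = 0.55)
  } else {
    list(length = 120L, ppt_u_content = 0.40, bp_range = c(-50L, -20L),
         minus3_prob = c(C = 0.70, T = 0.20, A = 0.05, G = 0.05),
         u12_frac = 0.035, assoc_strength = 0.55)
  }
}

#' Generate synthetic introns with planted acceptor architecture
#'
#' Each intron carries: canonical GT (or, at `u12_frac`, AT..AC) termini; a
#' branch adenine planted at a position drawn uniformly from `bp_range`
#' inside a consensus heptamer (TACTAAC, branch at the penultimate
#' adenine); a polypyrimidine tract between the branchpoint and the 3'ss
#' drawn with `P(T) = ppt_u_content` and the remainder mostly C; a terminal
#' NAG drawn from `minus3_prob`; and no competing adenine anywhere in the
#' -60..-13 window, so the planted branchpoint is recovered exactly on
#' noise-free draws. The accompanying first six exon bases are drawn with
#' the -3T-associated haplotype (+1G +2A +3A +4T +5T +6A) enriched at
#' `assoc_strength` when the acceptor is TAG, uniform otherwise.
#'
#' @param n Number of introns.
#' @param group_params List as returned by [intron_group_defaults()].
#' @param seed Integer seed.
#' @return Tibble: `intron_id`, `seq`, `bp_pos_true`, `minus3_true`,
#'   `first6`, `type_true`.
#' @export
gen_intron <- function(n, group_params = intron_group_defaults("Zn"),
                       seed = 1L) {
  p <- group_params
  L <- p$length
  if (L < -p$bp_range[1L] + 10L) {
    abort("intron length too short for the branchpoint range",
          class = "metalsplice_value_error")
  }
  planted_hap <- c("G", "A", "A", "T", "T", "A")
  with_seed(derive_seed(seed, "introns"), {
    rows <- lapply(seq_len(n), function(i) {
      bp <- sample(seq(p$bp_range[1L], p$bp_range[2L]), 1L)
      is_u12 <- runif(1) < p$u12_frac
      minus3 <- sample(names(p$minus3_prob), 1L, prob = p$minus3_prob)
      s <- sample(DNA_BASES, L, replace = TRUE)
      s[1:2] <- if (is_u12) c("A", "T") else c("G", "T")
      # PPT: between branch motif and the terminal NAG
      ppt_idx <- seq(L + bp + 2L, L - 3L)
      rem <- c(C = 0.95, G = 0.05)
      s[ppt_idx] <- ifelse(runif(length(ppt_idx)) < p$ppt_u_content, "T",
                           sample(names(rem), length(ppt_idx), TRUE, rem))
      # branch motif: branch A at window position 6 of 7
      mi <- (L + bp + 1L) + (-5L:1L)
      s[mi] <- c("T", "A", "C", "T", "A", "A", "C")
      # sanitize the scan window upstream of the motif: no competing A
      win_lo <- max(1L, L - 59L)
      win_hi <- L + bp - 5L
      if (win_hi >= win_lo) {
        win <- win_lo:win_hi
        s[win][s[win] == "A"] <- "C"
      }
      s[(L - 2L):L] <- if (is_u12) c(minus3, "A", "C")
      else c(minus3, "A", "G")
      first6 <- if (!is_u12 && minus3 == "T") {
        vapply(planted_hap, function(b) {
          if (runif(1) < p$assoc_strength) b
          else sample(setdiff(DNA_BASES, b), 1L)
        }, character(1L), USE.NAMES = FALSE)
      } else sample(DNA_BASES, 6L, replace = TRUE)
      tibble::tibble(
        intron_id = sprintf("intron_%04d", i),
        seq = paste(s, collapse = ""),
        bp_pos_true = bp,
        minus3_true = if (is_u12) NA_character_ else minus3,
        first6 = paste(first6, collapse = ""),
        type_true = if (is_u12) "AT-AC" else "GT-AG")
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate residue annotations with exact flag counts
#'
#' A minimal annotation table for exercising the dataset filters:
#' exactly `n_extended` records are homology-extended and exactly
#' `n_not_validated` records (drawn among the non-extended ones, mirroring
#' the tiered curation design) have `cmm_status = "not_validated"`.
#'
#' @param n Total records.
#' @param n_extended Homology-extended count.
#' @param n_not_validated `not_validated` count (among non-extended).
#' @param seed Integer seed.
#' @return Annotation tibble: `protein_id`, `residue_pos`, `residue`,
#'   `metal`, `cmm_status`, `homology_extended`.
#' @export
gen_residue_flags <- function(n, n_extended, n_not_validated, seed = 1L) {
  if (n_extended + n_not_validated > n) {
    abort("flag counts exceed n", class = "metalsplice_value_error")
  }
  with_seed(derive_seed(seed, "residue_flags"), {
    ext <- sample.int(n, n_extended)
    nv <- sample(setdiff(seq_len(n), ext), n_not_validated)
    status <- rep("plausible", n)
    status[nv] <- "not_validated"
    tibble::tibble(
      protein_id = sprintf("prot_%04d", 1L + (seq_len(n) - 1L) %/% 10L),
      residue_pos = seq_len(n),
      residue = sample(c("C", "H", "D", "E"), n, replace = TRUE),
      metal = "Zn",
      cmm_status = status,
      homology_extended = seq_len(n) %in% ext)
  })
}

#' Generate a synthetic PSI table
#'
#' PSI per exon x tissue is `100 * Beta(alpha, beta)`; the defaults
#' (alpha = 50, beta = 1, mean about 98) emulate the close-to-constitutive
#' inclusion of metal-coordinating exons.
#'
#' @param exon_ids Character vector of exon ids.
#' @param tissues Tissues sampled per exon.
#' @param alpha,beta Beta distribution parameters (> 0).
#' @param seed Integer seed.
#' @return Inclusion tibble: `exon_id`, `source`, `tissue`, `value`,
#'   `category`.
#' @export
gen_psi_table <- function(exon_ids,
                          tissues = c("neural", "muscle", "testis", "esc"),
                          alpha = 50, beta = 1, seed = 1L) {
  if (alpha <= 0 || beta <= 0) {
    abort("Beta parameters must be > 0", class = "metalsplice_value_error")
  }
  with_seed(derive_seed(seed, "psi"), {
    grid <- tidyr::expand_grid(exon_id = exon_ids, tissue = tissues)
    grid$value <- 100 * rbeta(nrow(grid), alpha, beta)
    grid$source <- "psi_table"
    grid$category <- "PSI"
    grid[c("exon_id", "source", "tissue", "value", "category")]
  })
}

#' Generate a disorder scale correlated with given amino-acid values
#'
#' Draws a synthetic 20-residue propensity scale jointly with the supplied
#' values at population correlation `target_r` (Gaussian construction:
#' `y = r * z(x) + sqrt(1 - r^2) * noise`).
#'
#' @param aa_values Tibble (`aa`, `value`), e.g. from [aa_level_lnratio()].
#' @param target_r Target correlation in \[-1, 1\].
#' @param seed Integer seed.
#' @return A disorder-scale tibble named `"synthetic"`.
#' @export
gen_disorder_scale <- function(aa_values, target_r, seed = 1L) {
  if (abs(target_r) > 1) abort("|target_r| must be <= 1",
                               class = "metalsplice_value_error")
  with_seed(derive_seed(seed, "disorder"), {
    x <- aa_values$value
    z <- (x - mean(x)) / stats::sd(x)
    y <- target_r * z + sqrt(1 - target_r^2) * rnorm(length(z))
    disorder_scale(setNames(y, aa_values$aa), name = "synthetic")
  })
}

#' Synthetic minigene validation outcomes matching printed summary counts
#'
#' No per-exon outcome table is published for the screening summary this
#' emulates; this synthetic stand-in plants exactly `n_skip_all` exons
#' skipping in every transcriptome, `n_skip_any - n_skip_all` skipping in
#' one to three, and the remainder skipping nowhere.
#'
#' @param n_tested Number of exons tested (default 38).
#' @param n_skip_any Exons skipping in at least one transcriptome
#'   (default 18).
#' @param n_skip_all Exons skipping in all transcriptomes (default 6).
#' @param transcriptomes Assay context labels.
#' @param seed Integer seed.
#' @return List: `outcomes` (tibble `exon_id`, `transcriptome`, `skipped`),
#'   `n_tested`.
#' @export
gen_validation_outcomes <- function(n_tested = 38L, n_skip_any = 18L,
                                    n_skip_all = 6L,
                                    transcriptomes = c("hek293", "sh_sy5y",
                                                       "brain",
                                                       "skeletal_muscle"),
                                    seed = 1L) {
  if (n_skip_all > n_skip_any || n_skip_any > n_tested) {
    abort("need n_skip_all <= n_skip_any <= n_tested",
          class = "metalsplice_value_error")
  }
  k <- length(transcriptomes)
  with_seed(derive_seed(seed, "validation"), {
    ids <- sprintf("tested_exon_%02d", seq_len(n_tested))
    rows <- lapply(seq_len(n_tested), function(i) {
      skipped <- rep(FALSE, k)
      if (i <= n_skip_all) skipped <- rep(TRUE, k)
      else if (i <= n_skip_any) {
        m <- sample.int(k - 1L, 1L)
        skipped[sample.int(k, m)] <- TRUE
      }
      tibble::tibble(exon_id = ids[i], transcriptome = transcriptomes,
                     skipped = skipped)
    })
    list(outcomes = dplyr::bind_rows(rows), n_tested = n_tested)
  })
}
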