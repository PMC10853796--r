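# Shared fixtures, built in code.

# Complete table with constant scores and a single class.
constant_table <- function(ese = 2, ess = 1, class = "E") {
  hx <- metalsplice:::all_hexamers()
  score_table(hx, rep(ese, length(hx)), rep(ess, length(hx)),
              class = rep(class, length(hx)))
}

# Complete table with per-hexamer random positive scores; some neutral.
random_table <- function(seed = 1, p_neutral = 0.3) {
  set.seed(seed)
  hx <- metalsplice:::all_hexamers()
  n <- length(hx)
  cls <- ifelse(runif(n) < p_neutral, "N",
                ifelse(runif(n) < 0.5, "E", "S"))
  score_table(hx, runif(n, 0.5, 3), runif(n, 0.5, 3), class = cls)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force oracle for codon scoring: enumerate every hexamer start that
# keeps the whole codon inside the window and the window inside the
# sequence, then average non-neutral scores.
oracle_score_codon <- function(table, seq, codon_start) {
  n <- nchar(seq)
  wins <- character(0)
  for (st in 0:(n - 6)) {
    if (st <= codon_start && st + 6 >= codon_start + 3) {
      wins <- c(wins, substr(seq, st + 1, st + 6))
    }
  }
  rows <- table[match(wins, table$hexamer), ]
  use <- rows$class != "N"
  if (!any(use)) return(list(mean_ese = NA, mean_ess = NA, n = 0))
  list(mean_ese = mean(rows$ese_score[use]),
       mean_ess = mean(rows$ess_score[use]), n = sum(use))
}

# Exhaustive maximum-sum-subsegment oracle (all O(n^2) segments + empty).
oracle_max_segment <- function(w) {
  best <- 0
  n <- length(w)
  if (n == 0) return(0)
  for (i in seq_len(n)) for (j in i:n) best <- max(best, sum(w[i:j]))
  best
}

ppt_weights <- function(region) {
  w <- c(A = -2, C = 0.5, G = -2, T = 1)
  unname(w[strsplit(region, "", fixed = TRUE)[[1]]])
}

# Closed-form one-way ANOVA F.
oracle_anova_f <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

groups_df <- function(groups) {
  tibble::tibble(
    value = unlist(groups),
    group = rep(names(groups), lengths(groups)))
}
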