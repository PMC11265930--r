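# Independent oracles, deliberately implemented by different routes than
# the package: edit distance by exhaustive enumeration of monotone
# alignments, longest common subsequence by its own DP, Mann-Whitney
# exact p by enumeration of rank assignments, chi-squared by the
# textbook formula.

# Every edit script between two sequences corresponds to a monotone
# matching of positions (matched pairs are substituted, everything else
# inserted/deleted), so the minimum over all matchings is the edit
# distance. Exponential, fine for lengths <= 5.
oracle_edit_distance <- function(s1, s2, sc, indel = 1) {
  a <- as_latch_states(s1, rownames(sc))
  b <- as_latch_states(s2, rownames(sc))
  n1 <- length(a)
  n2 <- length(b)
  best <- (n1 + n2) * indel
  for (k in seq_len(min(n1, n2))) {
    II <- utils::combn(n1, k, simplify = FALSE)
    JJ <- utils::combn(n2, k, simplify = FALSE)
    for (I in II) {
      for (J in JJ) {
        cost <- (n1 + n2 - 2 * k) * indel +
          sum(vapply(seq_len(k),
                     function(m) sc[a[I[m]], b[J[m]]], numeric(1)))
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# longest common subsequence length, classic DP
lcs_length <- function(s1, s2) {
  a <- as_latch_states(s1)
  b <- as_latch_states(s2)
  n1 <- length(a)
  n2 <- length(b)
  L <- matrix(0L, n1 + 1L, n2 + 1L)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L else
        max(L[i, j + 1L], L[i + 1L, j])
    }
  }
  L[n1 + 1L, n2 + 1L]
}

# exact two-sided Mann-Whitney p by enumerating which of the pooled
# ranks the first sample occupies (tie-free data only); follows the
# doubled-tail convention
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- rank(c(x, y))
  w_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- vapply(utils::combn(n1 + n2, n1, simplify = FALSE),
                  function(I) sum(I) - n1 * (n1 + 1) / 2, numeric(1))
  p_low <- mean(all_w <= w_obs)
  p_high <- mean(all_w >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

oracle_chisq <- function(counts) {
  e <- sum(counts) / length(counts)
  sum((counts - e)^2 / e)
}

# random latch sequence of length n under a fixed RNG state
random_seq <- function(n, alphabet = latch_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random substitution-cost matrix in TRATE style: derive it from the
# transition rates of a random pool of sequences
random_trate_sc <- function() {
  pool <- replicate(5, random_seq(sample(3:8, 1)))
  trate_costs(estimate_transition_rates(pool))
}

uniform_sc <- function(cost = 2) {
  ab <- latch_alphabet()
  sc <- matrix(cost, 4, 4, dimnames = list(ab, ab))
  diag(sc) <- 0
  sc
}
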