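# Categorical sequence metrics over the four-latch alphabet:
# longitudinal entropy, transition counts, the complexity index,
# transition-rate substitution costs and optimal-matching distances.

#' The four-latch alphabet
#'
#' States of the multi-solution box: horizontal side-pull bolt (\code{H}),
#' rod removal (\code{R}), vertical pull-down bolt (\code{V}) and rotating
#' swivel (\code{S}).
#'
#' @return Character vector \code{c("H", "R", "V", "S")}.
#' @export
latch_alphabet <- function() c("H", "R", "V", "S")

#' Coerce a latch sequence to a state vector
#'
#' Accepts either a single string (e.g. \code{"HRVS"}) or a character
#' vector of single-letter states, validates every state against the
#' alphabet, and returns the state vector.
#'
#' @param x single string or character vector of states.
#' @param alphabet permitted states; defaults to [latch_alphabet()].
#' @return Character vector of states (possibly length 0).
#' @export
as_latch_states <- function(x, alphabet = latch_alphabet()) {
  if (is.null(x)) return(character(0))
  x <- as.character(x)
  if (length(x) == 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(x), alphabet)
  if (length(bad) > 0L) {
    stop("sequence contains states outside the alphabet {",
         paste(alphabet, collapse = ","), "}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Longitudinal entropy of a latch sequence
#'
#' Shannon entropy (natural log) of the within-sequence distribution of
#' states, ignoring order. Zero when a single state is used; at most
#' \code{log(length(alphabet))} when all states occur equally often.
#'
#' @inheritParams as_latch_states
#' @return Entropy in nats.
#' @examples
#' longitudinal_entropy("HHHH")  # 0
#' longitudinal_entropy("HRVS")  # log(4)
#' @export
longitudinal_entropy <- function(x, alphabet = latch_alphabet()) {
  s <- as_latch_states(x, alphabet)
  if (length(s) == 0L) stop("sequence must have length >= 1", call. = FALSE)
  p <- table(factor(s, levels = alphabet)) / length(s)
  p <- p[p > 0]
  -sum(p * log(p)) + 0  # + 0 normalises IEEE negative zero
}

#' Number of transitions in a latch sequence
#'
#' Count of adjacent positions at which the state changes; between 0 and
#' \code{n - 1} for a sequence of length \code{n}.
#'
#' @inheritParams as_latch_states
#' @return Integer transition count.
#' @export
transition_count <- function(x, alphabet = latch_alphabet()) {
  s <- as_latch_states(x, alphabet)
  if (length(s) == 0L) stop("sequence must have length >= 1", call. = FALSE)
  if (length(s) == 1L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Complexity index of a latch sequence
#'
#' Geometric mean of the normalised transition count and the normalised
#' longitudinal entropy:
#' \deqn{C = \sqrt{\frac{q}{q_{max}} \cdot \frac{h}{h_{max}}}}
#' with \eqn{q_{max} = n - 1} and \eqn{h_{max} = \log|A|} over the full
#' alphabet \eqn{A}. \eqn{C = 0} iff a single state is used; \eqn{C = 1}
#' iff all states occur equally often and every adjacent pair differs.
#' A length-1 sequence has no scope for switching and scores 0.
#'
#' @inheritParams as_latch_states
#' @return A list of class \code{"complexity_result"} with elements
#'   \code{h}, \code{h_max}, \code{q}, \code{q_max}, \code{C}.
#' @examples
#' complexity_index("HHHHHHHH")$C      # 0
#' complexity_index("HRVSHRVSHRVS")$C  # 1
#' @export
complexity_index <- function(x, alphabet = latch_alphabet()) {
  s <- as_latch_states(x, alphabet)
  n <- length(s)
  if (n == 0L) stop("sequence must have length >= 1", call. = FALSE)
  h <- longitudinal_entropy(s, alphabet)
  h_max <- log(length(alphabet))
  q <- transition_count(s, alphabet)
  q_max <- n - 1L
  C <- if (q_max == 0L) 0 else sqrt((q / q_max) * (h / h_max)) + 0
  structure(list(h = h, h_max = h_max, q = q, q_max = q_max, C = C),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("complexity C = %.4f (h = %.4f / %.4f nats, q = %d / %d)\n",
              x$C, x$h, x$h_max, x$q, x$q_max))
  invisible(x)
}

#' Per-sequence complexity table
#'
#' Applies [complexity_index()] to each row of a sequence table and binds
#' the components as columns.
#'
#' @param sequences data frame with a \code{sequence} column of strings
#'   over the alphabet (other columns are carried through).
#' @param alphabet permitted states.
#' @return The input with columns \code{h}, \code{q}, \code{C} appended.
#' @export
sequence_complexity <- function(sequences, alphabet = latch_alphabet()) {
  stopifnot(is.data.frame(sequences), "sequence" %in% names(sequences))
  res <- lapply(sequences$sequence, complexity_index, alphabet = alphabet)
  sequences$h <- vapply(res, `[[`, numeric(1), "h")
  sequences$q <- vapply(res, function(r) as.integer(r$q), integer(1))
  sequences$C <- vapply(res, `[[`, numeric(1), "C")
  sequences
}

#' Pooled transition-rate matrix
#'
#' Tallies adjacent state pairs over a collection of sequences and
#' converts row-wise to transition probabilities \eqn{P[i,j] =
#' \Pr(s_{t+1} = j \mid s_t = i)}. A state never observed as a source
#' gets a uniform outgoing row (a documented convention so the derived
#' substitution costs stay defined for the full alphabet).
#'
#' @param seqs list or character vector of sequences (strings or state
#'   vectors), or a data frame with a \code{sequence} column.
#' @param alphabet permitted states.
#' @return A list of class \code{"transition_matrix"} with integer
#'   \code{counts} and row-stochastic \code{P}, both
#'   \code{|A| x |A|} with dimnames the alphabet.
#' @export
estimate_transition_rates <- function(seqs, alphabet = latch_alphabet()) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  if (is.character(seqs)) seqs <- as.list(seqs)
  k <- length(alphabet)
  counts <- matrix(0L, k, k, dimnames = list(alphabet, alphabet))
  any_pair <- FALSE
  for (s in seqs) {
    v <- as_latch_states(s, alphabet)
    if (length(v) < 2L) next
    any_pair <- TRUE
    from <- match(v[-length(v)], alphabet)
    to <- match(v[-1L], alphabet)
    for (t in seq_along(from)) {
      counts[from[t], to[t]] <- counts[from[t], to[t]] + 1L
    }
  }
  if (!any_pair) {
    stop("no sequence of length >= 2: transition rates undefined",
         call. = FALSE)
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 1 / k
  structure(list(counts = counts, P = P, alphabet = alphabet),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition probabilities (rows = from):\n")
  print(round(x$P, 3))
  invisible(x)
}

#' Transition-rate substitution costs
#'
#' The classic TRATE construction: for distinct states \eqn{i, j} the
#' substitution cost is \eqn{c - p(i \to j) - p(j \to i)} (clipped below
#' at 0); the diagonal is 0. States that frequently follow one another
#' are cheap to substitute. The rates used here are the observed ones
#' (zero for a state never seen as a source), so a pair of states that
#' never transition in either direction costs the full constant; the
#' uniform-row convention of [estimate_transition_rates()] applies only
#' to the probabilistic \code{P}.
#'
#' @param tm a \code{"transition_matrix"} from
#'   [estimate_transition_rates()].
#' @param c_val positive constant, default 2.
#' @return Symmetric cost matrix with zero diagonal, entries in
#'   \code{[0, c_val]}.
#' @export
trate_costs <- function(tm, c_val = 2) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (!is.numeric(c_val) || length(c_val) != 1L || c_val <= 0) {
    stop("c_val must be a positive scalar", call. = FALSE)
  }
  rs <- rowSums(tm$counts)
  p_obs <- tm$counts / ifelse(rs > 0, rs, 1)
  sc <- c_val - p_obs - t(p_obs)
  sc[sc < 0] <- 0
  diag(sc) <- 0
  sc
}

#' Optimal-matching distance between two latch sequences
#'
#' Minimum total cost of insertions, deletions (each \code{indel}) and
#' substitutions (matrix \code{sc}) transforming one sequence into the
#' other, by the standard dynamic programme. Symmetric whenever \code{sc}
#' is symmetric; zero between identical sequences.
#'
#' @param s1,s2 sequences (strings or state vectors); either may be
#'   empty.
#' @param sc substitution cost matrix with dimnames naming the states.
#' @param indel insertion/deletion cost, default 1.
#' @return Non-negative distance.
#' @examples
#' sc <- matrix(2, 4, 4, dimnames = list(latch_alphabet(), latch_alphabet()))
#' diag(sc) <- 0
#' om_distance("HRV", "HV", sc)  # 1
#' @export
om_distance <- function(s1, s2, sc, indel = 1) {
  ab <- rownames(sc)
  if (is.null(ab) || !identical(ab, colnames(sc))) {
    stop("sc must have identical row and column names (the alphabet)",
         call. = FALSE)
  }
  a <- match(as_latch_states(s1, ab), ab)
  b <- match(as_latch_states(s2, ab), ab)
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0L && n2 == 0L) return(0)
  D <- matrix(0, n1 + 1L, n2 + 1L)
  D[, 1L] <- (0:n1) * indel
  D[1L, ] <- (0:n2) * indel
  for (i in seq_len(n1)) {
    sci <- sc[a[i], ]
    for (j in seq_len(n2)) {
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + indel,
                               D[i + 1L, j] + indel,
                               D[i, j] + sci[b[j]])
    }
  }
  D[n1 + 1L, n2 + 1L]
}

#' Length-normalise an optimal-matching distance
#'
#' Divides a raw distance by a function of the two sequence lengths so
#' distances are comparable across sequences of different lengths.
#' \code{"longest"} (the default) divides by \code{max(n1, n2)};
#' \code{"sum"} divides by \code{n1 + n2}; \code{"none"} returns the raw
#' distance.
#'
#' @param d raw distance (non-negative).
#' @param n1,n2 sequence lengths (>= 1).
#' @param method normalisation rule.
#' @return Normalised distance.
#' @export
normalize_distance <- function(d, n1, n2,
                               method = c("longest", "sum", "none")) {
  method <- match.arg(method)
  stopifnot(all(d >= 0), all(n1 >= 1), all(n2 >= 1))
  switch(method,
         longest = d / pmax(n1, n2),
         sum = d / (n1 + n2),
         none = d)
}

#' Pairwise optimal-matching distance matrix
#'
#' Computes the full symmetric matrix of (optionally length-normalised)
#' optimal-matching distances between every pair of sequences in a
#' sequence table, preserving the identifying metadata.
#'
#' @param sequences data frame with columns \code{individual_id},
#'   \code{trial_index}, \code{condition}, \code{sequence}.
#' @param sc substitution cost matrix.
#' @param indel insertion/deletion cost.
#' @param normalize logical; normalise by sequence length?
#' @param method normalisation rule, see [normalize_distance()].
#' @return List of class \code{"om_distances"} with \code{d} (raw),
#'   \code{d_norm} (normalised, equal to \code{d} when
#'   \code{normalize = FALSE}) and \code{labels} (the metadata columns).
#' @export
pairwise_distances <- function(sequences, sc, indel = 1, normalize = TRUE,
                               method = c("longest", "sum", "none")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(sequences),
            all(c("individual_id", "sequence") %in% names(sequences)))
  m <- nrow(sequences)
  if (m < 2L) stop("need at least two sequences", call. = FALSE)
  states <- lapply(sequences$sequence, as_latch_states, rownames(sc))
  lens <- lengths(states)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d[i, j] <- d[j, i] <- om_distance(states[[i]], states[[j]], sc, indel)
    }
  }
  d_norm <- d
  if (normalize && method != "none") {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d_norm[i, j] <- d_norm[j, i] <-
          normalize_distance(d[i, j], lens[i], lens[j], method)
      }
    }
  }
  keep <- intersect(c("individual_id", "trial_index", "condition"),
                    names(sequences))
  structure(list(d = d, d_norm = d_norm,
                 labels = sequences[, keep, drop = FALSE],
                 lengths = lens),
            class = "om_distances")
}

#' @export
print.om_distances <- function(x, ...) {
  cat(sprintf("optimal-matching distances: %d sequences, %d pairs\n",
              nrow(x$d), choose(nrow(x$d), 2)))
  invisible(x)
}

#' Partition pairwise dissimilarities into intra- and inter-individual sets
#'
#' Splits the off-diagonal (normalised) distances into comparisons within
#' an individual's own trials and comparisons between different
#' individuals. Each unordered pair appears exactly once, so the two sets
#' together cover all \code{choose(m, 2)} pairs.
#'
#' @param dm an \code{"om_distances"} object.
#' @param condition optional condition label; when given, only sequences
#'   with that condition label enter the partition.
#' @return List with numeric vectors \code{intra} and \code{inter}.
#' @export
partition_dissimilarities <- function(dm, condition = NULL) {
  stopifnot(inherits(dm, "om_distances"))
  keep <- seq_len(nrow(dm$d_norm))
  if (!is.null(condition)) {
    if (!"condition" %in% names(dm$labels)) {
      stop("distance matrix carries no condition labels", call. = FALSE)
    }
    keep <- which(dm$labels$condition == condition)
  }
  ids <- dm$labels$individual_id[keep]
  d <- dm$d_norm[keep, keep, drop = FALSE]
  m <- length(keep)
  intra <- numeric(0)
  inter <- numeric(0)
  if (m >= 2L) {
    ut <- which(upper.tri(d), arr.ind = TRUE)
    same <- ids[ut[, 1L]] == ids[ut[, 2L]]
    intra <- d[ut[same, , drop = FALSE]]
    inter <- d[ut[!same, , drop = FALSE]]
  }
  single <- names(which(table(ids) < 2))
  if (length(single) > 0L) {
    message("individual(s) with a single trial contribute no ",
            "intra-individual pairs: ", paste(single, collapse = ", "))
  }
  list(intra = as.numeric(intra), inter = as.numeric(inter))
}
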