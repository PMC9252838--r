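# Independent oracles and in-code fixtures shared across tests.
# Everything here deliberately avoids the package's fast paths
# (cumulative-sum interval queries, beam search) so the tests compare
# two genuinely different routes to the same quantity.

# random symmetric contact-probability matrix with zero diagonal
random_prob_matrix <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# --- partition-index / best-split oracle (direct summation) -----------

oracle_pi <- function(P, segment, cuts) {
  a <- segment[1]; b <- segment[2]
  bounds <- c(a - 1, sort(cuts), b)
  segs <- lapply(seq_len(length(bounds) - 1),
                 function(i) (bounds[i] + 1):bounds[i + 1])
  I <- vapply(segs, function(s) sum(P[s, s, drop = FALSE]) / 2, 0)
  X <- 0
  m <- length(segs)
  for (k in seq_len(m - 1)) for (l in (k + 1):m)
    X <- X + sum(P[segs[[k]], segs[[l]], drop = FALSE])
  G <- prod(I)^(2 / m)
  if (G + X^2 == 0) return(0)
  (G - X^2) / (G + X^2)
}

# exhaustive scan of all admissible 1- and 2-cut splits; same tie-break
# contract (fewest cuts, then leftmost) but via plain enumeration
oracle_best_split <- function(P, segment, min_pu_size, max_cuts = 2,
                              pi_gain_threshold = 0.05) {
  a <- segment[1]; b <- segment[2]
  len <- b - a + 1
  cands <- list()
  if (len >= 2 * min_pu_size)
    for (c1 in (a + min_pu_size - 1):(b - min_pu_size))
      cands[[length(cands) + 1]] <- c1
  if (max_cuts >= 2 && len >= 3 * min_pu_size)
    for (c1 in (a + min_pu_size - 1):(b - 2 * min_pu_size))
      for (c2 in (c1 + min_pu_size):(b - min_pu_size))
        cands[[length(cands) + 1]] <- c(c1, c2)
  if (length(cands) == 0) return(NULL)
  pis <- vapply(cands, function(cc) oracle_pi(P, segment, cc), 0)
  best <- NULL; best_pi <- -Inf
  for (k in seq_along(cands)) {
    if (pis[k] > best_pi + 1e-12) {
      best <- cands[[k]]; best_pi <- pis[k]
    }
    # ties: candidates are generated fewest-cuts-first and in
    # lexicographic order, so the incumbent already wins ties
  }
  if (best_pi <= pi_gain_threshold) return(NULL)
  list(cut_positions = best, partition_index = best_pi)
}

# --- ambiguity-index oracle ------------------------------------------

oracle_a_index <- function(q) {
  best <- 0
  for (A in 0:5) if (sum(q >= A) >= A) best <- A
  best
}

# all quality multisets of sizes 0..max_n (values 1..5)
all_quality_multisets <- function(max_n) {
  out <- list(integer(0))
  for (n in seq_len(max_n)) {
    combs <- utils::combn(5 + n - 1, n)   # stars and bars -> multisets
    for (j in seq_len(ncol(combs)))
      out[[length(out) + 1]] <- combs[, j] - seq_len(n) + 1L
  }
  out
}

# --- set-partition enumeration (for merge_search) ---------------------

all_set_partitions <- function(n) {
  if (n == 0) return(list(list()))
  parts <- list(list(1L))
  for (el in seq_len(n)[-1]) {
    nxt <- list()
    for (p in parts) {
      for (b in seq_along(p)) {
        q <- p; q[[b]] <- c(q[[b]], el)
        nxt[[length(nxt) + 1]] <- q
      }
      nxt[[length(nxt) + 1]] <- c(p, list(el))
    }
    parts <- nxt
  }
  parts
}

partition_key <- function(blocks) {
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(vapply(blocks, min, 1L))]
  paste(vapply(blocks, paste, "", collapse = ","), collapse = "|")
}

# --- decoy-mean oracle: exact expectation over all label permutations --

# For a uniformly random permutation of the unit's labels, each contact
# pair sees a uniformly random ordered pair of distinct positions, so
# the exact permutation-average energy is
#   -n_pairs * mean_{u != v} lo[l_u, l_v].
oracle_permutation_mean <- function(labels, n_pairs, log_odds) {
  n <- length(labels)
  tot <- 0
  for (u in seq_len(n)) for (v in seq_len(n)) if (u != v)
    tot <- tot + log_odds[labels[u], labels[v]]
  -n_pairs * tot / (n * (n - 1))
}

# --- small in-code fixtures -------------------------------------------

two_globule_fixture <- function(seed = 1)
  make_globule_chain(c(30, 30), linker_lengths = 5, seed = seed)

# minimal PDB text fixture exercising the cleaning rules
write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   5      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   5      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA  GLY A   6      12.345   2.500  -4.000  1.00  0.00           C",
    "ATOM      4  CA ASER A   7       9.000   1.000  -3.000  0.40  0.00           C",
    "ATOM      5  CA BSER A   7       9.100   1.100  -3.100  0.60  0.00           C",
    "ATOM      6  CA  LYS A   7A      8.000   0.000  -2.000  1.00  0.00           C",
    "ATOM      7  CA  VAL A   8       7.000  -1.000  -1.000  1.00  0.00           C",
    "ATOM      8  CA  MSE A   9       6.000  -2.000   0.000  1.00  0.00           C",
    "HETATM    9  O   HOH A  90       0.000   0.000   0.000  1.00  0.00           O",
    "TER", "END"), path)
  path
}

# classic-format DSSP fixture (fixed columns: resno 6-10, chain 12,
# aa 14, ss 17)
write_mini_dssp <- function(path, resnos, chains, ss) {
  hdr <- c("==== Secondary Structure Definition by the program DSSP ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  rows <- sprintf("%5d%5d %s %s  %s", seq_along(resnos), resnos, chains,
                  "A", ss)
  # enforce exact columns: rebuild with fixed widths
  rows <- vapply(seq_along(resnos), function(i) {
    line <- sprintf("%5d%5d%1s%1s%1s%1s%2s%1s",
                    i, resnos[i], " ", chains[i], " ", "A", "  ", ss[i])
    line
  }, "")
  writeLines(c(hdr, rows), path)
  path
}
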