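# Protein peeling: recursive splitting of the chain into Protein Units
# (PUs) -- contiguous fragments with many internal and few external
# contacts -- by maximizing a partition index on the contact map.

#' Partition index of a candidate cut set
#'
#' Scores a split of a contiguous segment into 2 or 3 sub-segments.
#' With intra masses I_1..I_m and total inter mass X between distinct
#' sub-segments, the geometric-mean term G = (prod I_k)^(2/m) is balanced
#' against X^2:
#'
#'   PI = (G - X^2) / (G + X^2)
#'
#' PI lies in `[-1, 1]`; it equals 1 exactly when X = 0 with all I_k > 0
#' (perfectly separated compact sub-segments) and 0 when all masses
#' vanish.  The form is bounded and scale-free; it is isolated behind
#' this function so an alternative criterion can be swapped in.
#'
#' @param cm A `contact_map`.
#' @param segment `c(start, end)` interval (1-based, inclusive).
#' @param cuts 1 or 2 cut positions; a cut at `k` separates residues `k`
#'   and `k+1`.
#' @param min_pu_size Minimum sub-segment length (error if violated).
#' @return Scalar in `[-1, 1]`.
#' @export
partition_index <- function(cm, segment, cuts, min_pu_size = 1L) {
  a <- segment[1L]; b <- segment[2L]
  cuts <- sort(as.integer(cuts))
  if (any(cuts < a | cuts >= b))
    stop("partition_index: cuts must lie strictly inside the segment")
  bounds <- c(a - 1L, cuts, b)
  lens <- diff(bounds)
  if (any(lens < min_pu_size))
    stop("partition_index: sub-segment shorter than min_pu_size")
  m <- length(lens)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  I <- vapply(seq_len(m),
              function(k) .intra_interval(cm, starts[k], ends[k]),
              numeric(1L))
  X <- 0
  for (k in seq_len(m - 1L))
    for (l in (k + 1L):m)
      X <- X + .rect_mass(cm, starts[k], ends[k], starts[l], ends[l])
  G <- prod(I)^(2 / m)
  if (G + X^2 == 0) return(0)
  (G - X^2) / (G + X^2)
}

#' Best admissible split of a segment
#'
#' Exhaustively scans every admissible single-cut position and (when
#' `max_cuts = 2` and the segment is long enough) every admissible
#' two-cut pair, and returns the cut set with maximal partition index.
#' Ties are broken deterministically: fewest cuts first, then leftmost
#' first cut, then leftmost second cut.  Returns `NULL` when no
#' admissible cut exists or the best PI does not exceed
#' `pi_gain_threshold`.
#'
#' @param cm A `contact_map`.
#' @param segment `c(start, end)`.
#' @param min_pu_size Minimum sub-segment length (default 15).
#' @param max_cuts 1 or 2 simultaneous cuts (default 2).
#' @param pi_gain_threshold Minimum PI a split must exceed (default 0.05).
#' @return A list `split_result(cut_positions, partition_index)` or
#'   `NULL`.
#' @export
best_split <- function(cm, segment, min_pu_size = 15L, max_cuts = 2L,
                       pi_gain_threshold = 0.05) {
  a <- segment[1L]; b <- segment[2L]
  len <- b - a + 1L
  best <- NULL
  consider <- function(cuts, pi) {
    if (is.null(best) ||
        pi > best$partition_index + 1e-12 ||
        (abs(pi - best$partition_index) <= 1e-12 &&
         (length(cuts) < length(best$cut_positions) ||
          (length(cuts) == length(best$cut_positions) &&
           .lex_lt(cuts, best$cut_positions)))))
      best <<- list(cut_positions = cuts, partition_index = pi)
  }
  if (len >= 2L * min_pu_size) {
    for (c1 in (a + min_pu_size - 1L):(b - min_pu_size))
      consider(c1, partition_index(cm, segment, c1, min_pu_size))
  }
  if (max_cuts >= 2L && len >= 3L * min_pu_size) {
    for (c1 in (a + min_pu_size - 1L):(b - 2L * min_pu_size))
      for (c2 in (c1 + min_pu_size):(b - min_pu_size))
        consider(c(c1, c2),
                 partition_index(cm, segment, c(c1, c2), min_pu_size))
  }
  if (is.null(best) || best$partition_index <= pi_gain_threshold)
    return(NULL)
  best
}

# strict lexicographic order on equal-length integer vectors
.lex_lt <- function(x, y) {
  d <- x - y
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1L]] < 0L
}

#' Peel a chain into Protein Units
#'
#' Iterative hierarchical splitting: starting from the whole chain, at
#' every iteration the current frontier PU whose best split attains the
#' globally highest partition index is split, and the new frontier is
#' recorded as the next peeling level.  Peeling stops when no frontier
#' PU admits a split or the frontier reaches `max_pus` units.  Low
#' levels hold few long PUs; higher levels hold more and shorter ones.
#'
#' @param cm A `contact_map`.
#' @inheritParams best_split
#' @param max_pus Stop once the frontier holds this many PUs.
#' @return An object of class `peeling_tree`: list with `levels` (list of
#'   interval matrices, level 0 = whole chain), `terminal_pus` (matrix
#'   with columns start, end) and the parameters used.
#' @export
peel <- function(cm, min_pu_size = 15L, max_pus = 16L, max_cuts = 2L,
                 pi_gain_threshold = 0.05) {
  n <- n_residues_map(cm)
  if (n < min_pu_size)
    min_pu_size <- max(1L, n)  # degenerate tiny chains stay unsplit
  frontier <- list(c(1L, n))
  levels <- list(.frontier_mat(frontier))
  repeat {
    if (length(frontier) >= max_pus) break
    splits <- lapply(frontier, function(seg)
      best_split(cm, seg, min_pu_size = min_pu_size, max_cuts = max_cuts,
                 pi_gain_threshold = pi_gain_threshold))
    pis <- vapply(splits, function(s) if (is.null(s)) -Inf else
      s$partition_index, numeric(1L))
    if (all(!is.finite(pis))) break
    k <- which.max(pis)   # deterministic: first max (leftmost PU)
    seg <- frontier[[k]]
    cuts <- splits[[k]]$cut_positions
    bounds <- c(seg[1L] - 1L, cuts, seg[2L])
    pieces <- lapply(seq_len(length(bounds) - 1L),
                     function(i) c(bounds[i] + 1L, bounds[i + 1L]))
    frontier <- append(frontier[-k], pieces, after = k - 1L)
    levels <- c(levels, list(.frontier_mat(frontier)))
  }
  base::structure(
    list(levels = levels,
         terminal_pus = levels[[length(levels)]],
         min_pu_size = min_pu_size, max_pus = max_pus,
         max_cuts = max_cuts, pi_gain_threshold = pi_gain_threshold,
         criterion = "normalized-product-vs-crosstalk"),
    class = "peeling_tree")
}

.frontier_mat <- function(frontier) {
  m <- do.call(rbind, frontier)
  colnames(m) <- c("start", "end")
  m[order(m[, 1L]), , drop = FALSE]
}

#' @export
print.peeling_tree <- function(x, ...) {
  cat("peeling_tree:", length(x$levels) - 1L, "split(s),",
      nrow(x$terminal_pus), "terminal PU(s)\n")
  for (l in seq_along(x$levels)) {
    m <- x$levels[[l]]
    cat("  level", l - 1L, ": ",
        paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Compaction index of a Protein Unit
#'
#' Fraction of a unit's non-local contact mass (pairs with `|i-j| >= 3`)
#' that is internal:
#'
#'   CI = intra / (intra + inter-to-rest)
#'
#' CI near 1 marks a structurally independent unit; defined as 0 when
#' the unit has no non-local contacts at all.
#'
#' @param cm A `contact_map` (the full-chain map; the non-local view is
#'   taken internally).
#' @param pu `c(start, end)` interval.
#' @return Scalar in `[0, 1]`.
#' @export
compaction_index <- function(cm, pu) {
  n <- n_residues_map(cm)
  nl <- nonlocal_map(cm, 3L)
  inside <- pu[1L]:pu[2L]
  rest <- setdiff(seq_len(n), inside)
  intra <- contact_mass(nl, inside)
  inter <- if (length(rest)) contact_mass(nl, inside, rest) else 0
  if (intra + inter == 0) return(0)
  intra / (intra + inter)
}

#' Per-level PU table
#'
#' @param tree A `peeling_tree`.
#' @param cm The `contact_map` used to build it.
#' @param structure Optional `protein_structure` for original numbering.
#' @return data.frame: level, pu_index, start, end, original range, CI.
#' @export
pu_table <- function(tree, cm, structure = NULL) {
  rows <- list()
  for (l in seq_along(tree$levels)) {
    m <- tree$levels[[l]]
    for (i in seq_len(nrow(m))) {
      s <- m[i, 1L]; e <- m[i, 2L]
      orig <- if (is.null(structure)) c(s, e) else
        c(structure$residues$original_number[s],
          structure$residues$original_number[e])
      rows[[length(rows) + 1L]] <- data.frame(
        level = l - 1L, pu_index = i, start = s, end = e,
        orig_start = orig[1L], orig_end = orig[2L],
        compaction_index = compaction_index(cm, c(s, e)))
    }
  }
  do.call(rbind, rows)
}
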