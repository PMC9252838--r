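# Contact-probability map: the single data structure every downstream
# stage (peeling, assembly, quality, compaction) consumes.

#' Compute a logistic contact-probability map
#'
#' For every residue pair the C-alpha distance d_ij is transformed to a
#' contact probability p_ij = 1 / (1 + exp((d_ij - d0) / delta)).  The
#' smooth logistic transform avoids a hard distance cut-off: pairs near
#' d0 contribute ~0.5 rather than toggling between 0 and 1.
#'
#' @param structure A `protein_structure` with at least 2 residues.
#' @param d0 Logistic midpoint in Angstrom (default 8.0, the conventional
#'   C-alpha contact midpoint).
#' @param delta Logistic steepness in Angstrom (default 1.5).
#' @param min_sequence_separation Pairs with `|i-j|` below this are zeroed
#'   (default 0 = keep all off-diagonal pairs).
#' @return An object of class `contact_map`: list with `probs` (N x N
#'   symmetric matrix, zero diagonal), the parameters, and a cached
#'   cumulative-sum matrix used for O(1) interval mass queries.
#' @export
compute_contact_map <- function(structure, d0 = 8.0, delta = 1.5,
                                min_sequence_separation = 0L) {
  n <- n_residues(structure)
  if (n < 2L) stop("compute_contact_map: need at least 2 residues")
  stopifnot(d0 > 0, delta > 0, min_sequence_separation >= 0)
  xyz <- ca_coords(structure)
  d <- as.matrix(stats::dist(xyz))
  p <- 1 / (1 + exp((d - d0) / delta))
  diag(p) <- 0
  if (min_sequence_separation > 0L) {
    sep <- abs(row(p) - col(p))
    p[sep < min_sequence_separation] <- 0
  }
  new_contact_map(p, d0 = d0, delta = delta,
                  min_sequence_separation = min_sequence_separation)
}

#' Construct a contact_map from an explicit probability matrix
#'
#' Validates symmetry, range and the zero diagonal, and precomputes the
#' cumulative-sum table for fast interval queries.
#'
#' @param probs Symmetric N x N matrix in `[0,1]`, zero diagonal.
#' @param d0,delta,min_sequence_separation Metadata echoed in output
#'   (`NA` for analytic toy maps).
#' @return A `contact_map`.
#' @export
new_contact_map <- function(probs, d0 = NA_real_, delta = NA_real_,
                            min_sequence_separation = 0L) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  stopifnot(ncol(probs) == n)
  if (max(abs(probs - t(probs))) > 1e-9)
    stop("new_contact_map: probability matrix must be symmetric")
  if (any(probs < 0 | probs > 1)) stop("new_contact_map: entries outside [0,1]")
  if (any(diag(probs) != 0)) stop("new_contact_map: diagonal must be zero")
  dimnames(probs) <- NULL
  base::structure(
    list(probs = probs,
         d0 = d0, delta = delta,
         min_sequence_separation = as.integer(min_sequence_separation),
         cum = .cum2d(probs)),
    class = "contact_map")
}

# 2-D cumulative sums with a zero first row/col so rectangle sums are O(1)
.cum2d <- function(m) {
  cs <- apply(m, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  rbind(0, cbind(0, cs))
}

# sum of probs[a..b, c..d] via the cumulative table (1-based inclusive)
.rect_mass <- function(cm, a, b, c, d) {
  if (a > b || c > d) return(0)
  cu <- cm$cum
  cu[b + 1L, d + 1L] - cu[a, d + 1L] - cu[b + 1L, c] + cu[a, c]
}

# intra-pair mass (i<j, both in a..b) of a contiguous interval
.intra_interval <- function(cm, a, b) .rect_mass(cm, a, b, a, b) / 2

#' Number of residues covered by a contact map
#' @param cm A `contact_map`.
#' @return Integer.
#' @export
n_residues_map <- function(cm) nrow(cm$probs)

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", nrow(x$probs), "residues; d0 =", x$d0,
      "A, delta =", x$delta, "A, min separation =",
      x$min_sequence_separation, "\n")
  invisible(x)
}

#' Contact mass within or between residue sets
#'
#' The shared kernel behind the partition index, separation, compactness
#' and compaction index.  If `setA` and `setB` are identical the intra
#' mass (sum of p_ij over unordered pairs inside the set) is returned; if
#' they are disjoint, the inter mass (sum over all cross pairs).
#'
#' @param cm A `contact_map`.
#' @param setA,setB Integer vectors of residue indices in `1..N`.
#' @return Non-negative scalar.
#' @export
contact_mass <- function(cm, setA, setB = setA) {
  n <- n_residues_map(cm)
  setA <- sort(unique(as.integer(setA)))
  setB <- sort(unique(as.integer(setB)))
  if (length(setA) == 0L || length(setB) == 0L) return(0)
  if (any(setA < 1L | setA > n) || any(setB < 1L | setB > n))
    stop("contact_mass: indices outside 1..N")
  if (identical(setA, setB))
    return(sum(cm$probs[setA, setA, drop = FALSE]) / 2)
  if (length(intersect(setA, setB)) > 0L)
    stop("contact_mass: sets overlap but are not identical")
  sum(cm$probs[setA, setB, drop = FALSE])
}

#' Non-local view of a contact map
#'
#' Zeroes all pairs closer than `min_sep` in sequence (default 3); used
#' by the compaction index, partition quality and the pseudo-energy,
#' which all focus on non-local contacts.
#'
#' @param cm A `contact_map`.
#' @param min_sep Minimum `|i-j|` retained.
#' @return A `contact_map`.
#' @export
nonlocal_map <- function(cm, min_sep = 3L) {
  p <- cm$probs
  sep <- abs(row(p) - col(p))
  p[sep < min_sep] <- 0
  new_contact_map(p, d0 = cm$d0, delta = cm$delta,
                  min_sequence_separation = max(cm$min_sequence_separation,
                                                as.integer(min_sep)))
}

#' Write a contact map to text files
#'
#' Emits a whitespace-delimited dense matrix and/or a sparse TSV of the
#' upper triangle (`i`, `j`, `p` with `i < j`, 1-based).
#'
#' @param cm A `contact_map`.
#' @param dense_path,sparse_path Output paths (`NULL` to skip either).
#' @param digits Significant digits in the sparse file.
#' @return Character vector of written paths, invisibly.
#' @export
write_contact_map <- function(cm, dense_path = NULL, sparse_path = NULL,
                              digits = 6) {
  written <- character(0)
  if (!is.null(dense_path)) {
    write.table(signif(cm$probs, digits), dense_path,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    written <- c(written, dense_path)
  }
  if (!is.null(sparse_path)) {
    idx <- which(upper.tri(cm$probs) & cm$probs > 0, arr.ind = TRUE)
    sp <- data.frame(i = idx[, 1L], j = idx[, 2L],
                     p = signif(cm$probs[idx], digits))
    sp <- sp[order(sp$i, sp$j), ]
    write.table(sp, sparse_path, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, sparse_path)
  }
  invisible(written)
}
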