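# Knowledge-based pseudo-energy, sequence-shuffled decoy Z-score and the
# Chebyshev-mapped Autonomous Unit Likelihood (AUL).

#' Load a residue-pair contact propensity table
#'
#' Reads a whitespace-delimited symmetric 20x20 log-odds table (residue
#' order as in [aa_alphabet()]).  The table bundled with the package
#' (`contact_logodds_synthetic.txt`) is a synthetic hydrophobicity-derived
#' contact log-odds surface: it rewards burial of hydrophobic pairs and is
#' shipped in place of a trained statistical potential, which is why the
#' absolute pseudo-energies it yields are only meaningful relative to the
#' decoy distribution (i.e. through the Z-score).
#'
#' @param path Table file; default: the bundled synthetic table.
#' @return Object of class `propensity_table`: list with `log_odds`
#'   (named 20x20 matrix) and `source_label`.
#' @export
load_propensity_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "contact_logodds_synthetic.txt",
                        package = "peeldom", mustWork = TRUE)
  tab <- as.matrix(utils::read.table(path, comment.char = "#",
                                     header = TRUE, row.names = 1L,
                                     check.names = FALSE))
  aas <- aa_alphabet()
  if (!identical(rownames(tab), aas) || !identical(colnames(tab), aas))
    stop("load_propensity_table: expected a 20x20 table over ",
         paste(aas, collapse = ""))
  if (max(abs(tab - t(tab))) > 1e-9)
    stop("load_propensity_table: table must be symmetric")
  if (any(!is.finite(tab)))
    stop("load_propensity_table: non-finite entries")
  base::structure(list(log_odds = tab, source_label = basename(path)),
                  class = "propensity_table")
}

# qualifying contact pairs inside a unit: |i-j| >= min_sep, d <= cutoff
.energy_pairs <- function(structure, unit, min_sep = 3L, cutoff = 8.0) {
  unit <- sort(unique(as.integer(unit)))
  if (length(unit) < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  xyz <- ca_coords(structure)[unit, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(unit, unit, "-"))
  ok <- upper.tri(d) & d <= cutoff & sep >= min_sep
  idx <- which(ok, arr.ind = TRUE)
  cbind(i = unit[idx[, 1L]], j = unit[idx[, 2L]])
}

#' Pseudo-energy of a substructure
#'
#' E = - sum of log-odds over all residue pairs within the unit that are
#' in contact (C-alpha distance <= `cutoff`, sequence separation
#' >= `min_sep`).  Favorable contact propensities therefore drive E
#' negative, mimicking a free-energy-like score.
#'
#' @param structure A `protein_structure`.
#' @param unit Residue index set (need not be contiguous).
#' @param table A `propensity_table`.
#' @param min_sep Minimum `|i-j|` for a pair to count (default 3).
#' @param cutoff C-alpha distance cutoff in Angstrom (default 8).
#' @return Scalar energy (dimensionless).
#' @export
pseudo_energy <- function(structure, unit, table = load_propensity_table(),
                          min_sep = 3L, cutoff = 8.0) {
  pr <- .energy_pairs(structure, unit, min_sep, cutoff)
  if (nrow(pr) == 0L) return(0)
  aa <- structure$residues$amino_acid
  -sum(table$log_odds[cbind(aa[pr[, "i"]], aa[pr[, "j"]])])
}

#' Decoy pseudo-energy distribution by sequence shuffling
#'
#' Generates `n_decoys` decoys by uniformly permuting the amino-acid
#' labels of the unit's residues while keeping every coordinate fixed,
#' recomputes the pseudo-energy of each decoy, and returns the sample
#' mean and standard deviation.  Fully determined by `seed`.  A
#' homopolymeric unit (all labels identical) yields sigma = 0 and is
#' flagged degenerate.
#'
#' @inheritParams pseudo_energy
#' @param n_decoys Number of shuffled decoys (default 2000).
#' @param seed Integer RNG seed.
#' @return List: `mu`, `sigma`, `energies`, `degenerate`.
#' @export
decoy_distribution <- function(structure, unit,
                               table = load_propensity_table(),
                               n_decoys = 2000L, seed = 1L,
                               min_sep = 3L, cutoff = 8.0) {
  unit <- sort(unique(as.integer(unit)))
  stopifnot(n_decoys >= 2L, length(unit) >= 2L)
  pr <- .energy_pairs(structure, unit, min_sep, cutoff)
  aa <- structure$residues$amino_acid
  labels <- aa[unit]
  pos_i <- match(pr[, "i"], unit)
  pos_j <- match(pr[, "j"], unit)
  energies <- withr_seed(seed, {
    vapply(seq_len(n_decoys), function(k) {
      perm <- labels[sample.int(length(labels))]
      if (nrow(pr) == 0L) 0 else
        -sum(table$log_odds[cbind(perm[pos_i], perm[pos_j])])
    }, numeric(1L))
  })
  mu <- mean(energies)
  sigma <- stats::sd(energies)
  list(mu = mu, sigma = sigma, energies = energies,
       degenerate = length(unique(labels)) == 1L || sigma == 0)
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Z-score of a pseudo-energy against its decoy distribution
#'
#' Z = (E - mu) / sigma: the distance, in decoy standard deviations,
#' between the native-sequence energy and the shuffled-sequence mean.
#' Strongly negative Z marks a substructure whose native sequence fits
#' its own fold far better than random sequences do.
#'
#' @param E Pseudo-energy of the unit.
#' @param mu,sigma Decoy mean and standard deviation (`sigma > 0`).
#' @return Scalar Z.
#' @export
z_score <- function(E, mu, sigma) {
  if (sigma < 0) stop("z_score: sigma must be >= 0")
  if (sigma == 0)
    stop("z_score: degenerate decoy distribution (sigma = 0); ",
         "AUL is not computable for this unit")
  (E - mu) / sigma
}

#' Autonomous Unit Likelihood from a Z-score
#'
#' One-sided Chebyshev bound on the probability that a randomly
#' relabelled unit would score as well as the native one:
#'
#'   AUL = 100 * (1 - 1/Z^2)  for Z <= -1, else 0.
#'
#' Z = -2 gives 75%, Z = -4 gives 93.75% (reported 94%), and any
#' Z > -1 (e.g. -0.8) gives 0%.  The higher the AUL, the more likely the
#' unit is a native-like, potentially autonomously folding fragment.
#'
#' @param Z Finite Z-score.
#' @param digits Rounding of the reported percentage (default 0 =
#'   nearest integer percent).
#' @return Percentage in `[0, 100]`.
#' @export
aul_from_zscore <- function(Z, digits = 0) {
  if (!is.finite(Z)) stop("aul_from_zscore: Z must be finite")
  aul <- if (Z <= -1) 100 * (1 - 1 / Z^2) else 0
  round(aul, digits)
}

#' Full native-likeness assessment of one substructure
#'
#' Computes E, the decoy distribution, Z and AUL in one call.  For a
#' degenerate decoy distribution (sigma = 0) Z and AUL are `NA` and the
#' `degenerate` flag is set, so "no signal" is never conflated with
#' "not native-like".
#'
#' @inheritParams decoy_distribution
#' @return Object of class `energy_assessment`: list with
#'   `pseudo_energy`, `decoy_mean`, `decoy_sd`, `z_score`, `aul_percent`,
#'   `n_decoys`, `seed`, `degenerate`.
#' @export
assess_unit <- function(structure, unit, table = load_propensity_table(),
                        n_decoys = 2000L, seed = 1L,
                        min_sep = 3L, cutoff = 8.0) {
  E <- pseudo_energy(structure, unit, table, min_sep, cutoff)
  dd <- decoy_distribution(structure, unit, table, n_decoys, seed,
                           min_sep, cutoff)
  if (dd$degenerate || dd$sigma == 0) {
    z <- NA_real_; aul <- NA_real_
  } else {
    z <- z_score(E, dd$mu, dd$sigma)
    aul <- aul_from_zscore(z)
  }
  base::structure(
    list(pseudo_energy = E, decoy_mean = dd$mu, decoy_sd = dd$sigma,
         z_score = z, aul_percent = aul, n_decoys = as.integer(n_decoys),
         seed = as.integer(seed), degenerate = dd$degenerate),
    class = "energy_assessment")
}

#' @export
print.energy_assessment <- function(x, ...) {
  cat(sprintf("energy_assessment: E = %.3f, mu = %.3f, sigma = %.3f\n",
              x$pseudo_energy, x$decoy_mean, x$decoy_sd))
  if (x$degenerate) cat("  degenerate decoy distribution; Z/AUL: n/a\n")
  else cat(sprintf("  Z = %.2f, AUL = %s%%\n", x$z_score,
                   format(x$aul_percent)))
  invisible(x)
}
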