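#' @importFrom stats sd runif rnorm
#' @importFrom utils head tail write.table
NULL

# 20 standard amino acids, 3-letter -> 1-letter
.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Amino-acid alphabet used throughout the package
#'
#' One-letter codes of the 20 standard amino acids, in the fixed order
#' used by the bundled contact propensity table.
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Resolve alternate-location C-alpha records for one residue
#'
#' Picks the record with the highest occupancy; ties are broken by the
#' alphabetically first alternate-location identifier.  Records with no
#' alt-loc id sort before any lettered one.
#'
#' @param records data.frame with at least columns `o` (occupancy) and
#'   `alt` (alt-loc id, `NA` when absent), all rows belonging to a single
#'   residue.
#' @return A single-row data.frame.
#' @export
resolve_altloc <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("resolve_altloc: no records supplied")
  occ <- records$o
  occ[is.na(occ)] <- 1
  alt <- as.character(records$alt)
  alt[is.na(alt)] <- ""  # blank alt-loc sorts first
  ord <- order(-occ, alt)
  records[ord[1L], , drop = FALSE]
}

#' Read and clean a single protein chain from a PDB file
#'
#' Parses a PDB file, keeps one chain of one model, and applies the
#' cleaning rules used for all downstream computation: heteroatom records
#' are dropped, residues with non-standard names are dropped, residues
#' bearing insertion codes are dropped, alternate locations are resolved
#' to the highest-occupancy record, residues lacking a C-alpha atom are
#' dropped with a warning, and the survivors are renumbered 1..N in file
#' order.  The original author numbering is retained per residue.
#'
#' Only C-alpha atoms are stored: every downstream quantity (contact
#' probabilities, peeling, compactness, pseudo-energy) is C-alpha based.
#'
#' @param path Path to a `.pdb`/`.ent` file.
#' @param chain Chain identifier (default `"A"`).
#' @param model_index 1-based model number for multi-model files
#'   (default: first model).
#' @return An object of class `protein_structure`: a list with
#'   `chain_id`, `source_label` and a data.frame `residues` with columns
#'   `internal_index`, `original_number`, `insertion_code`, `amino_acid`
#'   (1-letter), `x`, `y`, `z`.
#' @export
load_structure <- function(path, chain = "A", model_index = 1L) {
  if (!file.exists(path)) stop("load_structure: file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("load_structure: cannot parse '", path,
                             "' as PDB: ", conditionMessage(e)))
  atoms <- pdb$atom
  chains <- sort(unique(atoms$chain[atoms$type == "ATOM"]))
  if (length(chains) == 0L) chains <- sort(unique(atoms$chain))
  if (!chain %in% atoms$chain)
    stop("load_structure: chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))

  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || is.na(nmod)) nmod <- 1L
  model_index <- as.integer(model_index)
  if (model_index < 1L || model_index > nmod)
    stop("load_structure: model_index ", model_index,
         " out of range (file has ", nmod, " model(s))")
  # substitute the requested model's coordinates
  xyz <- pdb$xyz[model_index, ]
  atoms$x <- xyz[seq(1L, length(xyz), by = 3L)]
  atoms$y <- xyz[seq(2L, length(xyz), by = 3L)]
  atoms$z <- xyz[seq(3L, length(xyz), by = 3L)]

  keep <- atoms$type == "ATOM" &
    atoms$chain == chain &
    atoms$elety == "CA" &
    atoms$resid %in% names(.aa3) &
    is.na(atoms$insert)
  ca <- atoms[keep, , drop = FALSE]

  # residues that had a non-CA record but lost their CA (or never had one)
  res_all <- unique(atoms[atoms$type == "ATOM" & atoms$chain == chain &
                            atoms$resid %in% names(.aa3) &
                            is.na(atoms$insert),
                          c("resno", "resid")])
  if (nrow(res_all) > length(unique(ca$resno)))
    warning("load_structure: ",
            nrow(res_all) - length(unique(ca$resno)),
            " residue(s) without a C-alpha atom dropped")

  if (nrow(ca) == 0L)
    stop("load_structure: no standard residues with C-alpha remain in chain '",
         chain, "' after cleaning")

  # resolve alternate locations per residue, preserving file order
  first_row <- !duplicated(ca$resno)
  order_key <- ca$resno[first_row]
  picked <- lapply(split(seq_len(nrow(ca)), factor(ca$resno, levels = order_key)),
                   function(idx) resolve_altloc(ca[idx, , drop = FALSE]))
  ca <- do.call(rbind, picked)

  residues <- data.frame(
    internal_index  = seq_len(nrow(ca)),
    original_number = ca$resno,
    insertion_code  = "",
    amino_acid      = unname(.aa3[ca$resid]),
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE)
  rownames(residues) <- NULL

  structure(list(chain_id = chain,
                 source_label = basename(path),
                 residues = residues),
            class = "protein_structure")
}

#' Construct a protein_structure from raw components
#'
#' Used by the fixture generator and tests; applies the same invariants
#' as [load_structure()].
#'
#' @param coords N x 3 numeric matrix of C-alpha coordinates (Angstrom).
#' @param sequence Character vector of 1-letter codes (length N) or a
#'   single string.
#' @param chain_id Chain identifier.
#' @param original_numbers Author numbering (default `1..N`).
#' @param source_label Free-text origin label.
#' @return A `protein_structure`.
#' @export
new_structure <- function(coords, sequence, chain_id = "A",
                          original_numbers = NULL,
                          source_label = "in-memory") {
  coords <- as.matrix(coords)
  if (length(sequence) == 1L && nchar(sequence[1L]) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3L, length(sequence) == n)
  if (!all(sequence %in% aa_alphabet()))
    stop("new_structure: non-standard amino acid code(s): ",
         paste(setdiff(sequence, aa_alphabet()), collapse = ", "))
  if (is.null(original_numbers)) original_numbers <- seq_len(n)
  structure(list(chain_id = chain_id,
                 source_label = source_label,
                 residues = data.frame(
                   internal_index = seq_len(n),
                   original_number = as.integer(original_numbers),
                   insertion_code = "",
                   amino_acid = as.character(sequence),
                   x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                   stringsAsFactors = FALSE)),
            class = "protein_structure")
}

#' Number of residues in a structure
#' @param structure A `protein_structure`.
#' @return Integer length.
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' C-alpha coordinate matrix
#' @param structure A `protein_structure`.
#' @return N x 3 numeric matrix.
#' @export
ca_coords <- function(structure)
  as.matrix(structure$residues[, c("x", "y", "z")])

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", x$source_label,
      " chain", x$chain_id, " (", n_residues(x), "residues )\n")
  invisible(x)
}

#' Write a cleaned structure as a C-alpha-only PDB file
#'
#' Residues are written with their internal (1..N) numbering so that a
#' reload reproduces the object exactly.
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  r <- structure$residues
  aa1to3 <- names(.aa3)
  names(aa1to3) <- unname(.aa3)
  xyz <- as.vector(t(as.matrix(r[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = r$internal_index,
                   resid = aa1to3[r$amino_acid],
                   chain = structure$chain_id,
                   elety = rep("CA", nrow(r)),
                   o = rep(1, nrow(r)), b = rep(0, nrow(r)))
  invisible(path)
}
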