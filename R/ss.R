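# Secondary-structure annotation: reporting layer only; never feeds the
# contact map, peeling or assembly stages.

#' Reduce an 8-state secondary-structure string to 3 states
#'
#' Applies the standard DSSP state reduction: H, G, I -> H (helix);
#' E, B -> E (strand); S, T, C (and blank) -> C (coil).
#'
#' @param states8 A string over `{H,G,I,E,B,S,T,C}`; blanks are treated
#'   as C.
#' @return A string of the same length over `{H,E,C}`.
#' @export
reduce_states <- function(states8) {
  if (length(states8) != 1L || !is.character(states8))
    stop("reduce_states: expected a single string")
  if (nchar(states8) == 0L) return("")
  ch <- strsplit(states8, "")[[1L]]
  ch[ch == " "] <- "C"
  map <- c(H = "H", G = "H", I = "H",
           E = "E", B = "E",
           S = "C", T = "C", C = "C")
  bad <- which(!ch %in% names(map))
  if (length(bad))
    stop("reduce_states: unknown state '", ch[bad[1L]],
         "' at position ", bad[1L])
  paste(map[ch], collapse = "")
}

#' Parse a classic-format DSSP output file
#'
#' Reads the per-residue table of a DSSP text file and aligns the 8-state
#' codes to a cleaned structure by original residue number.  Residues of
#' the structure absent from the DSSP file (or with a blank code) are
#' coded C.
#'
#' @param path DSSP output file.
#' @param chain Chain identifier to extract.
#' @param structure A `protein_structure` to align against.
#' @return A list of class `secondary_structure` with fields `states8`,
#'   `states3` and `method = "dssp"`.
#' @export
parse_dssp <- function(path, chain, structure) {
  if (!file.exists(path)) stop("parse_dssp: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L)
    stop("parse_dssp: malformed DSSP file (missing '  #  RESIDUE' header): ",
         path)
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nchar(body) >= 17L]
  # classic fixed columns: resnum 6-10, insertion 11, chain 12, aa 14, ss 17
  aa <- substr(body, 14L, 14L)
  body <- body[aa != "!"]                  # chain breaks
  if (length(body) == 0L) stop("parse_dssp: no residue records in ", path)
  ch  <- substr(body, 12L, 12L)
  if (!chain %in% ch)
    stop("parse_dssp: chain '", chain, "' not present in DSSP file (has: ",
         paste(sort(unique(ch)), collapse = ", "), ")")
  body <- body[ch == chain]
  resno <- suppressWarnings(as.integer(substr(body, 6L, 10L)))
  ss <- substr(body, 17L, 17L)
  ss[ss == " "] <- "C"
  ok <- !is.na(resno)
  lut <- ss[ok]
  names(lut) <- resno[ok]

  orig <- as.character(structure$residues$original_number)
  s8 <- unname(lut[orig])
  s8[is.na(s8)] <- "C"
  s8 <- paste(s8, collapse = "")
  base::structure(list(states8 = s8, states3 = reduce_states(s8),
                 method = "dssp"),
            class = "secondary_structure")
}

#' Approximate secondary structure from C-alpha geometry
#'
#' Coarse fallback used when no DSSP file is supplied, so that C-alpha-only
#' inputs still get a first-level annotation.  Residue windows whose
#' i to i+3 C-alpha distance lies in \[4.5, 6.0\] Angstrom for at least 4
#' consecutive window starts are labelled H (the run's residues i..i+3);
#' locally extended stretches (i to i+2 distance >= 6.4 Angstrom for >= 3
#' consecutive starts) are labelled E; everything else is C.  H takes
#' precedence over E.  The result is deliberately crude and is flagged
#' `method = "ca-geometric-approximate"` in the output.
#'
#' @param structure A `protein_structure` of length >= 5 (shorter inputs
#'   yield an all-C string with a warning).
#' @return A `secondary_structure` with `states8` copied from `states3`.
#' @export
assign_ss_from_ca <- function(structure) {
  n <- n_residues(structure)
  mk <- function(s3) base::structure(list(states8 = s3, states3 = s3,
                                    method = "ca-geometric-approximate"),
                               class = "secondary_structure")
  if (n < 5L) {
    warning("assign_ss_from_ca: structure shorter than 5 residues; all-C")
    return(mk(paste(rep("C", n), collapse = "")))
  }
  xyz <- ca_coords(structure)
  d_k <- function(k) {
    i <- seq_len(n - k)
    sqrt(rowSums((xyz[i + k, , drop = FALSE] - xyz[i, , drop = FALSE])^2))
  }
  lab <- rep("C", n)
  # strand: runs of >= 3 extended i->i+2 windows
  e_ok <- d_k(2L) >= 6.4
  for (r in .runs(e_ok, 3L)) lab[r[1L]:(r[2L] + 2L)] <- "E"
  # helix: runs of >= 4 helical i->i+3 windows (precedence over E)
  d3 <- d_k(3L)
  h_ok <- d3 >= 4.5 & d3 <= 6.0
  for (r in .runs(h_ok, 4L)) lab[r[1L]:(r[2L] + 3L)] <- "H"
  mk(paste(lab, collapse = ""))
}

# maximal runs of TRUE of length >= minlen; list of c(start, end)
.runs <- function(flags, minlen) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minlen
  mapply(function(s, e) c(s, e), starts[keep], ends[keep], SIMPLIFY = FALSE)
}
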