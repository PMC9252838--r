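# Synthetic C-alpha-only structures with known ground truth: compact
# globules (confined self-avoiding walks) joined by near-straight
# extended linkers.  Every stage of the pipeline is testable on these
# without any download.

#' Generate a synthetic globule-linker chain
#'
#' Builds a C-alpha trace of `length(globule_sizes)` compact globules
#' joined by extended linkers.  Each globule is a self-avoiding random
#' walk with 3.8 Angstrom steps confined to a sphere of
#' `globule_radius`; a persistent drift along the chain axis steers each
#' walk towards its exit side so consecutive globule centres end up
#' roughly `2*radius + (L+1)*step` apart and the globules do not touch.
#' Linkers are near-straight jittered 3.8 Angstrom-step paths bridging
#' consecutive globules.  Residue identities are drawn uniformly from
#' the 20 standard types.  Deterministic given `seed`.
#'
#' @param globule_sizes Integer vector of residues per globule (each
#'   >= 5).
#' @param linker_lengths Residues per linker (one fewer than globules).
#' @param globule_radius Confinement radius in Angstrom (default 10).
#' @param step_length C-alpha step in Angstrom (default 3.8).
#' @param seed Integer RNG seed.
#' @return List: `structure` (a `protein_structure`), `boundaries`
#'   (ground-truth inter-segment boundary positions: residue index k for
#'   a boundary between k and k+1), `segments` (data.frame with kind,
#'   start, end), `linker_midpoints` (cut position at each linker's
#'   midpoint), `spec` (echo of the parameters).
#' @export
make_globule_chain <- function(globule_sizes, linker_lengths = integer(0),
                               globule_radius = 10, step_length = 3.8,
                               seed = 1L) {
  g <- as.integer(globule_sizes)
  l <- as.integer(linker_lengths)
  stopifnot(length(g) >= 1L, length(l) == length(g) - 1L,
            globule_radius > 0, step_length > 0)
  if (any(g < 5L)) stop("make_globule_chain: every globule size must be >= 5")
  # crude sphere-packing feasibility bound (min pair distance 3.5 A)
  cap <- floor(0.35 * (2 * globule_radius / 3.5)^3)
  if (any(g > cap))
    stop("make_globule_chain: ", max(g), " residues cannot be confined in a ",
         globule_radius, " A sphere; increase globule_radius (capacity ~",
         cap, ")")

  withr_seed(seed, {
    # clash-checked single step from the current chain end
    step_from <- function(pts, dir, jitter) {
      for (try in 1:400) {
        # widen the jitter cone as attempts fail so the step can route
        # around blocking residues
        cand <- pts[nrow(pts), ] +
          step_length * .unit(dir, jitter * (1 + try / 25))
        if (nrow(pts) < 2L) return(cand)
        d2 <- rowSums(sweep(pts[-nrow(pts), , drop = FALSE], 2L, cand)^2)
        if (min(d2) >= 3.5^2) return(cand)
      }
      stop("peeldom_trapped_chain")
    }
    build_once <- function() {
      pts <- matrix(numeric(0), ncol = 3L)
      kinds <- character(0)
      centre <- c(0, 0, 0)
      for (gi in seq_along(g)) {
        if (gi == 1L && length(g) > 1L) {
          # build the first globule backwards from its exit point on the
          # east pole, drifting west, then reverse: the linker then
          # leaves from a clean surface point with the globule's mass
          # behind it (the same geometry later globules get at their
          # entry pole)
          exit_pt <- centre + c(0.85 * globule_radius, 0, 0)
          walk <- .confined_saw(n = g[1L], start = exit_pt, centre = centre,
                                radius = globule_radius, step = step_length,
                                drift = c(-1, 0, 0), existing = pts)
          walk <- walk[rev(seq_len(nrow(walk))), , drop = FALSE]
        } else {
          start_pt <- if (nrow(pts) == 0L) centre else
            step_from(pts, centre - pts[nrow(pts), ], jitter = 0.1)
          walk <- .confined_saw(n = g[gi], start = start_pt, centre = centre,
                                radius = globule_radius, step = step_length,
                                drift = c(1, 0, 0), existing = pts)
        }
        pts <- rbind(pts, walk)
        kinds <- c(kinds, rep("globule", g[gi]))
        if (gi < length(g)) {
          nl <- l[gi]
          for (k in seq_len(nl)) {
            pts <- rbind(pts, step_from(pts, c(1, 0, 0), jitter = 0.08))
            kinds <- c(kinds, "linker")
          }
          # next globule centre: beyond the linker end, along the axis
          entry <- pts[nrow(pts), ] + step_length * c(1, 0, 0)
          centre <- entry + c(0.7 * globule_radius, 0, 0)
        }
      }
      list(pts = pts, kinds = kinds)
    }
    # a dead-ended chain (walk end buried among its own residues) is
    # rebuilt from scratch; the RNG stream advances, so the result is
    # still fully determined by the seed
    built <- NULL
    for (attempt in 1:40) {
      built <- tryCatch(build_once(), error = function(e) {
        if (grepl("peeldom_trapped_chain", conditionMessage(e))) NULL
        else stop(e)
      })
      if (!is.null(built)) break
    }
    if (is.null(built))
      stop("make_globule_chain: cannot build a clash-free chain; ",
           "increase globule_radius")
    pts <- built$pts
    kinds <- built$kinds
    n <- nrow(pts)
    seqc <- sample(aa_alphabet(), n, replace = TRUE)
    st <- new_structure(pts, seqc,
                        source_label = sprintf("synthetic-globule-chain-seed%d",
                                               seed))
    seg_end <- cumsum(rle(kinds)$lengths)
    seg_start <- c(1L, head(seg_end, -1L) + 1L)
    segments <- data.frame(kind = rle(kinds)$values,
                           start = seg_start, end = seg_end)
    linkers <- segments[segments$kind == "linker", , drop = FALSE]
    list(structure = st,
         boundaries = head(seg_end, -1L),
         segments = segments,
         linker_midpoints = if (nrow(linkers))
           as.integer(floor((linkers$start + linkers$end) / 2)) else integer(0),
         spec = list(globule_sizes = g, linker_lengths = l,
                     globule_radius = globule_radius,
                     step_length = step_length, seed = seed))
  })
}

# unit vector of v, optionally jittered by isotropic noise
.unit <- function(v, jitter = 0) {
  if (jitter > 0) v <- v + rnorm(3L, sd = jitter * sqrt(sum(v^2)))
  nv <- sqrt(sum(v^2))
  if (nv == 0) v <- c(1, 0, 0) else v / nv
}

# self-avoiding walk of n points confined to a sphere, with drift
.confined_saw <- function(n, start, centre, radius, step, drift, existing,
                          min_clash = 3.5, max_tries = 400L,
                          max_restarts = 50L) {
  for (restart in seq_len(max_restarts)) {
    pts <- matrix(start, nrow = 1L)
    ok <- TRUE
    while (nrow(pts) < n) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        dir <- .unit(.unit(drift) * 0.9 + rnorm(3L))
        cand <- pts[nrow(pts), ] + step * dir
        # pull back inside the sphere
        if (sqrt(sum((cand - centre)^2)) > radius) next
        prev <- rbind(existing, pts)
        if (nrow(prev) > 1L) {
          d2 <- rowSums(sweep(prev[-nrow(prev), , drop = FALSE], 2L,
                              cand)^2)
          if (any(d2 < min_clash^2)) next
        }
        pts <- rbind(pts, cand)
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  stop("make_globule_chain: confinement infeasible after ", max_restarts,
       " restarts; increase globule_radius")
}

#' Ideal alpha-helix C-alpha trace
#'
#' Canonical helix geometry: 1.5 Angstrom rise and 100 degree rotation
#' per residue on a 2.3 Angstrom-radius cylinder, giving ~3.8 Angstrom
#' consecutive C-alpha distances and ~5.1 Angstrom i to i+3 distances.
#'
#' @param n Number of residues (>= 4).
#' @param sequence Optional 1-letter sequence (default: poly-A).
#' @return A `protein_structure`.
#' @export
make_ideal_helix <- function(n, sequence = NULL) {
  stopifnot(n >= 4L)
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  coords <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  if (is.null(sequence)) sequence <- rep("A", n)
  new_structure(coords, sequence, source_label = "synthetic-ideal-helix")
}

#' Analytic block-diagonal toy contact map
#'
#' Contact map whose probabilities are `intra_p` inside each block and
#' `inter_p` between blocks (diagonal 0); used to test peeling and
#' assembly against hand-computable masses.
#'
#' @param block_sizes Integer vector of block lengths.
#' @param intra_p,inter_p Probabilities with
#'   `0 <= inter_p <= intra_p <= 1`.
#' @return A `contact_map`.
#' @export
make_block_map <- function(block_sizes, intra_p, inter_p = 0) {
  stopifnot(inter_p >= 0, intra_p <= 1, inter_p <= intra_p)
  n <- sum(block_sizes)
  blk <- rep(seq_along(block_sizes), block_sizes)
  same <- outer(blk, blk, "==")
  p <- ifelse(same, intra_p, inter_p)
  diag(p) <- 0
  new_contact_map(p)
}

#' Write a fixture as a PDB file plus ground-truth JSON sidecar
#'
#' @param fixture Output of [make_globule_chain()].
#' @param pdb_path Destination PDB path.
#' @param json_path Destination JSON path (default: `pdb_path` with
#'   `.json` extension).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, pdb_path,
                          json_path = sub("\\.pdb$", ".json", pdb_path)) {
  write_structure_pdb(fixture$structure, pdb_path)
  jsonlite::write_json(
    list(boundaries = fixture$boundaries,
         segments = fixture$segments,
         linker_midpoints = fixture$linker_midpoints,
         spec = fixture$spec),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(pdb_path, json_path))
}
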