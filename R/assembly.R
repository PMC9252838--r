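# Domain assembly: agglomerative merging of terminal Protein Units into
# domains, enumeration of alternative partitions, quality scoring,
# ambiguity index, junction statistics and domain frequencies.

#' Separation between two residue sets
#'
#' S = inter mass / sqrt(intra(A) * intra(B)).  High S means the two
#' units share many contacts relative to their internal cohesion and are
#' good candidates to be merged into one domain.  If either intra mass
#' is 0, S falls back to the raw inter mass (0 when that is 0 too).
#'
#' @param cm A `contact_map`.
#' @param unitA,unitB Disjoint non-empty residue index sets.
#' @return Non-negative scalar, symmetric in its arguments.
#' @export
separation <- function(cm, unitA, unitB) {
  ia <- contact_mass(cm, unitA)
  ib <- contact_mass(cm, unitB)
  x <- contact_mass(cm, unitA, unitB)   # errors on overlapping sets
  if (ia == 0 || ib == 0) return(x)
  x / sqrt(ia * ib)
}

#' Compactness (contact density) of a residue set
#'
#' C = intra mass / number of residues.
#'
#' @param cm A `contact_map`.
#' @param unit Non-empty residue index set.
#' @return Non-negative scalar.
#' @export
compactness <- function(cm, unit) {
  unit <- unique(as.integer(unit))
  contact_mass(cm, unit) / length(unit)
}

# ---- internal partition-state helpers --------------------------------

# a state is a list of integer vectors (sorted PU indices per domain),
# ordered by smallest member; key = canonical string
.state_key <- function(blocks) paste(vapply(blocks, paste, "", collapse = ","),
                                     collapse = "|")

.canon_blocks <- function(blocks) {
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  blocks[order(vapply(blocks, min, integer(1L)))]
}

.block_residues <- function(block, pus)
  sort(unlist(lapply(block, function(i) pus[i, 1L]:pus[i, 2L])))

#' Quality of a domain partition
#'
#' Discrete 1-5 score from a step function over two ratios computed on
#' the contact map: the separation fraction
#' rho = (total inter-domain mass) / (total non-local mass of the chain)
#' and the compactness ratio
#' kappa = min_d C_d / C_chain.
#' Small rho (domains rarely talk to each other) and kappa near 1 (the
#' least compact domain is nearly as dense as the whole chain) mark a
#' clean decomposition:
#'
#'   5: rho <= 0.03 and kappa >= 0.9;  4: rho <= 0.06 and kappa >= 0.8;
#'   3: rho <= 0.10 and kappa >= 0.7;  2: rho <= 0.15 and kappa >= 0.6;
#'   1: otherwise.
#'
#' A single-domain partition has rho = 0 and kappa = 1 by construction,
#' hence quality 5.  Partitions of quality >= 2 are "acceptable".
#'
#' @param cm A `contact_map`.
#' @param domain_sets List of disjoint residue index sets covering 1..N.
#' @return List with `quality`, `is_acceptable`, `separation_fraction`,
#'   `min_compactness_ratio`.
#' @export
partition_quality <- function(cm, domain_sets) {
  n <- n_residues_map(cm)
  all_res <- sort(unlist(domain_sets))
  if (!identical(all_res, seq_len(n)))
    stop("partition_quality: domains must disjointly cover 1..N")
  if (length(domain_sets) == 1L) {
    rho <- 0; kappa <- 1
  } else {
    inter <- 0
    for (i in seq_len(length(domain_sets) - 1L))
      for (j in (i + 1L):length(domain_sets))
        inter <- inter + contact_mass(cm, domain_sets[[i]], domain_sets[[j]])
    nl_total <- contact_mass(nonlocal_map(cm, 3L), seq_len(n))
    rho <- if (nl_total > 0) inter / nl_total else 0
    c_chain <- compactness(cm, seq_len(n))
    c_min <- min(vapply(domain_sets, function(d) compactness(cm, d),
                        numeric(1L)))
    kappa <- if (c_chain > 0) c_min / c_chain else 1
  }
  q <- if (rho <= 0.03 && kappa >= 0.9) 5L else
    if (rho <= 0.06 && kappa >= 0.8) 4L else
      if (rho <= 0.10 && kappa >= 0.7) 3L else
        if (rho <= 0.15 && kappa >= 0.6) 2L else 1L
  list(quality = q, is_acceptable = q >= 2L,
       separation_fraction = rho, min_compactness_ratio = kappa)
}

#' Agglomerative beam search over PU merges
#'
#' Starting from one domain per terminal PU, repeatedly merges domain
#' pairs.  Candidate merges are ranked by separation S (descending),
#' ties by the compactness of the merged domain (descending), then by
#' the smallest involved PU index; the top `beam_width` states survive
#' to the next depth.  Every state visited at any depth is recorded, so
#' the search returns the whole ladder from |PUs| domains down to 1.
#' Merged domains may be sequence-discontinuous (unions of non-adjacent
#' PUs).  Duplicate partitions are removed, each survivor is scored by
#' [partition_quality()], and only acceptable partitions are returned,
#' sorted by number of domains (ascending) then quality (descending).
#'
#' @param cm A `contact_map`.
#' @param terminal_pus Matrix with columns start, end (one row per PU).
#' @param beam_width States kept per depth (default 3; `Inf` =
#'   exhaustive agglomerative enumeration).
#' @param keep_all Return every visited partition regardless of
#'   acceptability (default FALSE: acceptable partitions only).
#' @return List of partition objects: `domains` (list of residue sets),
#'   `pu_members` (list of PU index vectors), `n_domains`, `quality`,
#'   `is_acceptable`, `separation_fraction`, `min_compactness_ratio`,
#'   `mean_compactness`.
#' @export
merge_search <- function(cm, terminal_pus, beam_width = 3,
                         keep_all = FALSE) {
  pus <- terminal_pus
  m <- nrow(pus)
  stopifnot(m >= 1L)
  start <- .canon_blocks(as.list(seq_len(m)))
  visited <- list()
  visited[[.state_key(start)]] <- start
  beam <- list(start)
  for (depth in seq_len(m - 1L)) {
    succ <- list(); succ_rank <- list()
    for (state in beam) {
      nb <- length(state)
      for (i in seq_len(nb - 1L)) {
        for (j in (i + 1L):nb) {
          ra <- .block_residues(state[[i]], pus)
          rb <- .block_residues(state[[j]], pus)
          s_ij <- separation(cm, ra, rb)
          c_ij <- compactness(cm, c(ra, rb))
          merged <- .canon_blocks(c(state[-c(i, j)],
                                    list(c(state[[i]], state[[j]]))))
          key <- .state_key(merged)
          rank <- c(-s_ij, -c_ij, min(state[[i]], state[[j]]))
          # keep the best-ranked route to each distinct successor state
          if (is.null(succ[[key]]) || .rank_lt(rank, succ_rank[[key]])) {
            succ[[key]] <- merged
            succ_rank[[key]] <- rank
          }
        }
      }
    }
    if (length(succ) == 0L) break
    ord <- order(vapply(succ_rank, function(r) r[1L], numeric(1L)),
                 vapply(succ_rank, function(r) r[2L], numeric(1L)),
                 vapply(succ_rank, function(r) r[3L], numeric(1L)))
    keep <- head(ord, if (is.finite(beam_width)) beam_width else length(ord))
    beam <- unname(succ[keep])
    for (st in beam) visited[[.state_key(st)]] <- st
  }

  # score all recorded states; dedupe is inherent (keyed by state)
  parts <- lapply(unname(visited), function(blocks) {
    dsets <- lapply(blocks, .block_residues, pus = pus)
    pq <- partition_quality(cm, dsets)
    list(domains = dsets,
         pu_members = blocks,
         n_domains = length(dsets),
         quality = pq$quality,
         is_acceptable = pq$is_acceptable,
         separation_fraction = pq$separation_fraction,
         min_compactness_ratio = pq$min_compactness_ratio,
         mean_compactness = mean(vapply(dsets, function(d)
           compactness(cm, d), numeric(1L))))
  })
  if (!keep_all) parts <- Filter(function(p) p$is_acceptable, parts)
  ord <- order(vapply(parts, `[[`, 0L, "n_domains"),
               -vapply(parts, `[[`, 0L, "quality"))
  parts[ord]
}

.rank_lt <- function(x, y) {
  d <- x - y
  nz <- which(abs(d) > 1e-12)
  length(nz) > 0L && d[nz[1L]] < 0
}

#' Select the optimal partition
#'
#' Among acceptable partitions: (i) the largest number of domains, then
#' (ii) the highest mean domain compactness, then the highest quality,
#' then the first in deterministic order.  If no acceptable partition is
#' supplied the single-domain partition is returned with a warning.
#'
#' @param partitions List of partitions as produced by [merge_search()].
#' @return One partition (element of the input list).
#' @export
select_optimal <- function(partitions) {
  acc <- Filter(function(p) isTRUE(p$is_acceptable), partitions)
  if (length(acc) == 0L) {
    warning("select_optimal: no acceptable partition; ",
            "falling back to the single-domain partition")
    one <- Filter(function(p) p$n_domains == 1L, partitions)
    if (length(one)) return(one[[1L]])
    stop("select_optimal: empty partition list")
  }
  nd <- vapply(acc, `[[`, 0L, "n_domains")
  acc <- acc[nd == max(nd)]
  mc <- vapply(acc, `[[`, 0, "mean_compactness")
  acc <- acc[abs(mc - max(mc)) <= 1e-12]
  q <- vapply(acc, `[[`, 0L, "quality")
  acc[[which.max(q)]]
}

#' Ambiguity index of a set of partition qualities
#'
#' The largest A >= 0 such that at least A of the partitions have
#' quality >= A (an h-index over the 1-5 qualities).  A high A-index
#' means many good alternative decompositions exist, i.e. the protein's
#' domain organization is ambiguous; a low value is neither good nor
#' bad on its own.
#'
#' @param qualities Integer vector with values in 1..5 (may be empty).
#' @return Integer in 0..5.
#' @export
a_index <- function(qualities) {
  if (length(qualities) == 0L) return(0L)
  qualities <- as.integer(qualities)
  if (any(is.na(qualities)) || any(qualities < 1L | qualities > 5L))
    stop("a_index: qualities must lie in 1..5")
  a <- 0L
  for (cand in seq_len(5L)) if (sum(qualities >= cand) >= cand) a <- cand
  a
}

#' Junction statistics across alternative partitions
#'
#' A junction of partition p is an inter-residue boundary k (between
#' residues k and k+1, chain termini excluded) where either residues k
#' and k+1 fall in different domains, or k is an internal extremity of a
#' PU used to build p's domains.  For every junction observed anywhere:
#' `count` = number of partitions containing it; `frequency` =
#' count / N_d; `weight` = sum over containing partitions of
#' (quality/5) / N_d, so weight <= frequency with equality iff every
#' containing partition has quality 5.
#'
#' @param partitions List of partitions from [merge_search()].
#' @param terminal_pus The PU interval matrix the partitions were built
#'   from.
#' @param include_pu_extremities Also count PU extremities interior to a
#'   domain (default TRUE).
#' @return data.frame: position, count, frequency, weight, sorted by
#'   position.
#' @export
junction_stats <- function(partitions, terminal_pus,
                           include_pu_extremities = TRUE) {
  nd <- length(partitions)
  stopifnot(nd >= 1L)
  n <- max(terminal_pus[, 2L])
  tally <- new.env(parent = emptyenv())
  for (p in partitions) {
    jx <- integer(0)
    # inter-domain boundaries
    dom_of <- integer(n)
    for (di in seq_along(p$domains)) dom_of[p$domains[[di]]] <- di
    jx <- which(dom_of[-n] != dom_of[-1L])
    if (include_pu_extremities) {
      for (b in p$pu_members) for (i in b) {
        s <- terminal_pus[i, 1L]; e <- terminal_pus[i, 2L]
        if (s > 1L) jx <- c(jx, s - 1L)
        if (e < n) jx <- c(jx, e)
      }
    }
    for (k in unique(jx)) {
      key <- as.character(k)
      prev <- if (is.null(tally[[key]])) c(0, 0) else tally[[key]]
      tally[[key]] <- prev + c(1, p$quality / 5)
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0L)
    return(data.frame(position = integer(0), count = integer(0),
                      frequency = numeric(0), weight = numeric(0)))
  out <- data.frame(
    position = as.integer(keys),
    count = vapply(keys, function(k) as.integer(tally[[k]][1L]), 0L),
    frequency = vapply(keys, function(k) tally[[k]][1L] / nd, 0),
    weight = vapply(keys, function(k) tally[[k]][2L] / nd, 0))
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out
}

#' Domain occurrence counts across partitions
#'
#' Counts identical domain residue-sets across all partitions; domains
#' recurring in many alternative decompositions are robust structural
#' regions.
#'
#' @param partitions List of partitions from [merge_search()].
#' @return data.frame: domain (compact range string), n_residues, count;
#'   sorted by descending count.
#' @export
domain_frequency <- function(partitions) {
  stopifnot(length(partitions) >= 1L)
  keys <- character(0); sizes <- integer(0)
  tab <- new.env(parent = emptyenv())
  for (p in partitions) for (d in p$domains) {
    key <- ranges_label(d)
    if (is.null(tab[[key]])) {
      tab[[key]] <- 0L
      keys <- c(keys, key); sizes <- c(sizes, length(d))
    }
    tab[[key]] <- tab[[key]] + 1L
  }
  cnt <- vapply(keys, function(k) tab[[k]], 0L)
  out <- data.frame(domain = keys, n_residues = sizes, count = cnt)
  out <- out[order(-out$count, out$domain), ]
  rownames(out) <- NULL
  out
}

#' Compact label for a residue set
#'
#' Renders a (possibly discontinuous) residue set as comma-separated
#' inclusive ranges, e.g. `"1-30,45-60"`.
#'
#' @param residue_set Integer vector of residue indices.
#' @return A single string.
#' @export
ranges_label <- function(residue_set) {
  r <- sort(unique(as.integer(residue_set)))
  if (length(r) == 0L) return("")
  brk <- c(0L, which(diff(r) != 1L), length(r))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    s <- r[brk[i] + 1L]; e <- r[brk[i + 1L]]
    if (s == e) as.character(s) else paste0(s, "-", e)
  }, ""), collapse = ",")
}
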