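# Pipeline orchestration and result serialization: the batch equivalent
# of an interactive decomposition report.

#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline with its default; any subset
#' can be overridden.  All constants are echoed into the result bundle
#' so outputs are self-describing.
#'
#' @param input_path Path to a PDB file (or `NULL` when a structure is
#'   passed to [run_pipeline()] directly).
#' @param chain Chain identifier (default "A").
#' @param dssp_path Optional DSSP output file for secondary structure.
#' @param d0,delta,min_sequence_separation Contact-map logistic
#'   parameters.
#' @param min_pu_size,max_pus,max_cuts,pi_gain_threshold Peeling
#'   parameters.
#' @param beam_width Assembly beam width.
#' @param n_decoys Decoys per energy assessment (default 2000).
#' @param seed Integer seed controlling all randomness.
#' @param model_index PDB model used for multi-model files.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(input_path = NULL, chain = "A", dssp_path = NULL,
                       d0 = 8.0, delta = 1.5, min_sequence_separation = 0L,
                       min_pu_size = 15L, max_pus = 16L, max_cuts = 2L,
                       pi_gain_threshold = 0.05, beam_width = 3,
                       n_decoys = 2000L, seed = 1L, model_index = 1L) {
  cfg <- list(input_path = input_path, chain = chain, dssp_path = dssp_path,
              d0 = d0, delta = delta,
              min_sequence_separation = as.integer(min_sequence_separation),
              min_pu_size = as.integer(min_pu_size),
              max_pus = as.integer(max_pus), max_cuts = as.integer(max_cuts),
              pi_gain_threshold = pi_gain_threshold, beam_width = beam_width,
              n_decoys = as.integer(n_decoys), seed = as.integer(seed),
              model_index = as.integer(model_index))
  num <- c("d0", "delta", "min_pu_size", "max_pus", "max_cuts",
           "n_decoys", "seed")
  for (f in num) if (cfg[[f]] <= 0)
    stop("run_config: '", f, "' must be positive")
  base::structure(cfg, class = "run_config")
}

#' Run the full hierarchical decomposition pipeline
#'
#' load/clean -> secondary-structure annotation -> contact map ->
#' peeling into Protein Units -> domain assembly (alternative
#' partitions, quality, optimal, A-index, junctions, domain
#' frequencies) -> pseudo-energy assessment of every terminal PU and
#' every domain of every partition.  Deterministic given the config
#' (including its seed).
#'
#' @param config A `run_config`.
#' @param structure Optional pre-built `protein_structure` (bypasses
#'   file loading, e.g. for fixtures).
#' @return A `result_bundle` list; see [write_outputs()] for
#'   serialization.
#' @export
run_pipeline <- function(config = run_config(), structure = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  st <- stage("structure_io", {
    if (!is.null(structure)) structure
    else if (is.null(config$input_path))
      stop("no input_path and no structure supplied")
    else load_structure(config$input_path, config$chain, config$model_index)
  })
  ss <- stage("ss_annotation", {
    if (!is.null(config$dssp_path))
      parse_dssp(config$dssp_path, st$chain_id, st)
    else assign_ss_from_ca(st)
  })
  cm <- stage("contact_map",
              compute_contact_map(st, config$d0, config$delta,
                                  config$min_sequence_separation))
  tree <- stage("peeling",
                peel(cm, min_pu_size = config$min_pu_size,
                     max_pus = config$max_pus, max_cuts = config$max_cuts,
                     pi_gain_threshold = config$pi_gain_threshold))
  pus <- tree$terminal_pus
  partitions <- stage("assembly",
                      merge_search(cm, pus, beam_width = config$beam_width))
  optimal <- stage("assembly", select_optimal(partitions))
  opt_idx <- which(vapply(partitions, function(p)
    identical(p$domains, optimal$domains), logical(1L)))[1L]
  qualities <- vapply(partitions, `[[`, 0L, "quality")
  aidx <- a_index(qualities)
  junctions <- stage("assembly", junction_stats(partitions, pus))
  dom_freq <- stage("assembly", domain_frequency(partitions))

  table <- stage("pseudo_energy", load_propensity_table())
  # one deterministic sub-seed per assessed unit, derived from config$seed
  seed_for <- function(k) (config$seed * 1000L + k) %% .Machine$integer.max
  assess_k <- 0L
  assess <- function(unit) {
    assess_k <<- assess_k + 1L
    assess_unit(st, unit, table, n_decoys = config$n_decoys,
                seed = seed_for(assess_k))
  }
  pu_assess <- stage("pseudo_energy", lapply(seq_len(nrow(pus)), function(i)
    c(list(unit = ranges_label(pus[i, 1L]:pus[i, 2L])),
      unclass(assess(pus[i, 1L]:pus[i, 2L])))))
  dom_assess <- stage("pseudo_energy", {
    seen <- new.env(parent = emptyenv())
    out <- list()
    for (p in partitions) for (d in p$domains) {
      key <- ranges_label(d)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- c(list(unit = key), unclass(assess(d)))
      }
    }
    out
  })

  orig <- st$residues$original_number
  base::structure(list(
    tool = list(name = "peeldom",
                version = as.character(utils::packageVersion("peeldom"))),
    config = unclass(config),
    structure = list(source_label = st$source_label, chain = st$chain_id,
                     n_residues = n_residues(st),
                     sequence = paste(st$residues$amino_acid, collapse = ""),
                     original_numbers = orig),
    secondary_structure = list(states8 = ss$states8, states3 = ss$states3,
                               method = ss$method),
    contact_map = list(d0 = cm$d0, delta = cm$delta,
                       min_sequence_separation = cm$min_sequence_separation),
    peeling = list(criterion = tree$criterion,
                   n_levels = length(tree$levels),
                   pu_table = pu_table(tree, cm, st)),
    partitions = lapply(seq_along(partitions), function(i) {
      p <- partitions[[i]]
      list(index = i,
           n_domains = p$n_domains,
           quality = p$quality,
           is_acceptable = p$is_acceptable,
           is_optimal = identical(i, as.integer(opt_idx)),
           separation_fraction = p$separation_fraction,
           min_compactness_ratio = p$min_compactness_ratio,
           mean_compactness = p$mean_compactness,
           domains = lapply(p$domains, function(d) list(
             internal = ranges_label(d),
             original = ranges_label(orig[d]))),
           pu_members = p$pu_members)
    }),
    optimal_index = as.integer(opt_idx),
    a_index = aidx,
    junctions = transform(junctions,
                          original_position = orig[junctions$position]),
    domain_frequency = dom_freq,
    energy = list(potential = table$source_label,
                  potential_kind = "synthetic-hydrophobicity-log-odds",
                  pu_assessments = pu_assess,
                  domain_assessments = dom_assess)),
    class = "result_bundle")
}

#' Serialize a result bundle to disk
#'
#' Writes up to six artifacts into `dir`: `results.json` (full bundle),
#' `summary.txt` (optimal partition first, then alternatives sorted by
#' ascending number of domains), `pus.tsv`, `junctions.tsv`,
#' `domain_frequency.tsv`, and the contact-map text files (computed on
#' demand from the stored configuration when requested).
#'
#' @param bundle A `result_bundle`.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("json", "summary", "tsv", "map")`.
#' @param structure Needed only for `"map"` output (to recompute the
#'   contact map).
#' @return Character vector of written paths.
#' @export
write_outputs <- function(bundle, dir,
                          formats = c("json", "summary", "tsv"),
                          structure = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L)
    stop("write_outputs: directory not writable: ", dir)
  written <- character(0)
  if ("json" %in% formats) {
    p <- file.path(dir, "results.json")
    jsonlite::write_json(unclass(bundle), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }
  if ("summary" %in% formats) {
    p <- file.path(dir, "summary.txt")
    writeLines(format_summary(bundle), p)
    written <- c(written, p)
  }
  if ("tsv" %in% formats) {
    p1 <- file.path(dir, "pus.tsv")
    write.table(bundle$peeling$pu_table, p1, sep = "\t",
                row.names = FALSE, quote = FALSE)
    p2 <- file.path(dir, "junctions.tsv")
    write.table(bundle$junctions, p2, sep = "\t",
                row.names = FALSE, quote = FALSE)
    p3 <- file.path(dir, "domain_frequency.tsv")
    write.table(bundle$domain_frequency, p3, sep = "\t",
                row.names = FALSE, quote = FALSE)
    written <- c(written, p1, p2, p3)
  }
  if ("map" %in% formats) {
    if (is.null(structure))
      stop("write_outputs: 'map' format needs the structure")
    cm <- compute_contact_map(structure, bundle$contact_map$d0,
                              bundle$contact_map$delta,
                              bundle$contact_map$min_sequence_separation)
    written <- c(written,
                 write_contact_map(cm,
                                   dense_path = file.path(dir, "contact_map.txt"),
                                   sparse_path = file.path(dir, "contact_map.tsv")))
  }
  written
}

#' Human-readable summary of a result bundle
#'
#' @param bundle A `result_bundle`.
#' @return Character vector of lines.
#' @export
format_summary <- function(bundle) {
  ln <- c(sprintf("%s %s | %s chain %s | %d residues",
                  bundle$tool$name, bundle$tool$version,
                  bundle$structure$source_label, bundle$structure$chain,
                  bundle$structure$n_residues),
          sprintf("A-index: %d | partitions: %d | PU criterion: %s",
                  bundle$a_index, length(bundle$partitions),
                  bundle$peeling$criterion),
          "")
  fmt_part <- function(p, tag) {
    doms <- vapply(p$domains, function(d)
      sprintf("[%s | orig %s]", d$internal, d$original), "")
    sprintf("%s %d domain(s), quality %d/5%s: %s", tag, p$n_domains,
            p$quality, if (p$is_acceptable) "" else " (not acceptable)",
            paste(doms, collapse = " "))
  }
  opt <- bundle$partitions[[bundle$optimal_index]]
  ln <- c(ln, fmt_part(opt, "OPTIMAL:"), "")
  rest <- bundle$partitions[vapply(bundle$partitions, function(p)
    !p$is_optimal, logical(1L))]
  rest <- rest[order(vapply(rest, `[[`, 0L, "n_domains"))]
  for (p in rest) ln <- c(ln, fmt_part(p, sprintf("alt %d:", p$index)))
  ln
}

#' @export
print.result_bundle <- function(x, ...) {
  writeLines(format_summary(x))
  invisible(x)
}
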