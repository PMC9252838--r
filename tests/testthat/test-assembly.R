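test_that("separation and compactness follow their closed forms", {
  cm <- make_block_map(c(4), intra_p = 0.5)
  expect_equal(compactness(cm, 1:4), 6 * 0.5 / 4)        # 0.75 by hand
  expect_equal(compactness(cm, 2L), 0)                   # single residue
  # adding an isolated residue strictly decreases compactness
  p <- matrix(0, 5, 5); p[1:4, 1:4] <- 0.5; diag(p) <- 0
  cm5 <- new_contact_map(p)
  expect_lt(compactness(cm5, 1:5), compactness(cm5, 1:4))

  blocks <- make_block_map(c(3, 3), intra_p = 0.9, inter_p = 0)
  expect_equal(separation(blocks, 1:3, 4:6), 0)          # zero inter-mass
  set.seed(5)
  cmr <- new_contact_map(random_prob_matrix(10))
  expect_equal(separation(cmr, 1:4, 7:10), separation(cmr, 7:10, 1:4))
  expect_error(separation(cmr, 1:5, 4:8), "overlap")
  # two halves of one globule are far less separable than two globules
  fx <- two_globule_fixture(seed = 6)
  cmf <- compute_contact_map(fx$structure)
  expect_gt(separation(cmf, 1:15, 16:30),                # halves of globule 1
            separation(cmf, 1:30, 36:65))                # the two globules
})

test_that("partition quality ranks clean cuts above globule-splitting cuts", {
  fx <- two_globule_fixture(seed = 8)
  cm <- compute_contact_map(fx$structure)
  n <- n_residues(fx$structure)
  whole <- partition_quality(cm, list(1:n))
  expect_equal(whole$quality, 5L)                        # single domain
  expect_equal(whole$separation_fraction, 0)
  expect_equal(whole$min_compactness_ratio, 1)
  at_linker <- partition_quality(cm, list(1:33, 34:n))
  expect_gte(at_linker$quality, 4L)
  mid_globule <- partition_quality(cm, list(1:15, 16:n))
  expect_lt(mid_globule$quality, at_linker$quality)
  expect_error(partition_quality(cm, list(1:10, 12:n)), "cover")
})

test_that("merge_search enumerates the full agglomerative ladder", {
  cm <- make_block_map(c(5, 5), intra_p = 0.8, inter_p = 0.1)
  pus <- rbind(c(1L, 5L), c(6L, 10L))
  parts <- merge_search(cm, pus, beam_width = Inf, keep_all = TRUE)
  expect_equal(sort(vapply(parts, `[[`, 0L, "n_domains")), c(1L, 2L))

  one <- merge_search(cm, rbind(c(1L, 10L)))
  expect_length(one, 1L)
  expect_equal(one[[1]]$n_domains, 1L)

  # 4 PUs, unbounded beam: visited states = all 15 set-partitions
  cm4 <- make_block_map(c(3, 3, 3, 3), intra_p = 0.7, inter_p = 0.2)
  pus4 <- cbind(start = c(1L, 4L, 7L, 10L), end = c(3L, 6L, 9L, 12L))
  all4 <- merge_search(cm4, pus4, beam_width = Inf, keep_all = TRUE)
  got_keys <- sort(vapply(all4, function(p) partition_key(p$pu_members), ""))
  want_keys <- sort(vapply(all_set_partitions(4), partition_key, ""))
  expect_equal(got_keys, unique(want_keys))
  # every returned partition disjointly covers 1..N
  for (p in all4) expect_equal(sort(unlist(p$domains)), 1:12)
})

test_that("acceptable partitions are sorted and the optimal obeys its three rules", {
  mk <- function(nd, q, mc) list(n_domains = nd, quality = q,
                                 is_acceptable = q >= 2, mean_compactness = mc,
                                 domains = list(seq_len(nd)))
  p2 <- mk(2L, 4L, 0.9); p3a <- mk(3L, 3L, 0.75); p3b <- mk(3L, 2L, 0.80)
  expect_equal(select_optimal(list(p2, p3a, p3b))$mean_compactness, 0.80)
  expect_equal(select_optimal(list(p2, p3a))$n_domains, 3L)     # rule (i)
  expect_equal(select_optimal(list(p2))$n_domains, 2L)
  # only the single-domain partition is acceptable -> it is returned
  bad <- mk(2L, 1L, 0.5); single <- mk(1L, 5L, 1)
  expect_equal(select_optimal(list(bad, single))$n_domains, 1L)
  # nothing acceptable at all -> fall back to the single-domain partition
  bad1 <- mk(1L, 1L, 0.5)
  expect_warning(opt <- select_optimal(list(bad, bad1)), "falling back")
  expect_equal(opt$n_domains, 1L)
})

test_that("a_index equals its definition on every multiset of size <= 6", {
  for (q in all_quality_multisets(6))
    expect_identical(a_index(q), as.integer(oracle_a_index(q)))
  expect_equal(a_index(integer(0)), 0L)
  expect_equal(a_index(c(5, 5, 5)), 3L)
  expect_equal(a_index(c(5, 1, 1)), 1L)
  expect_error(a_index(c(3, 6)), "1..5")
})

test_that("junction statistics follow the count/frequency/weight definitions", {
  pus <- cbind(start = c(1L, 11L, 21L), end = c(10L, 20L, 30L))
  part <- function(blocks, q) {
    dsets <- lapply(blocks, function(b)
      sort(unlist(lapply(b, function(i) pus[i, 1]:pus[i, 2]))))
    list(domains = dsets, pu_members = lapply(blocks, as.integer),
         n_domains = length(dsets), quality = q)
  }
  # 4 partitions; junction at 10 appears in all, at 20 in all as a PU
  # extremity even when PUs 2+3 share a domain
  parts <- list(part(list(1, 2, 3), 5L), part(list(1, c(2, 3)), 5L),
                part(list(c(1, 2), 3), 5L), part(list(c(1, 2, 3)), 5L))
  js <- junction_stats(parts, pus)
  expect_equal(js$position, c(10L, 20L))
  expect_equal(js$count, c(4L, 4L))
  expect_equal(js$frequency, c(1, 1))
  expect_equal(js$weight, c(1, 1))       # all quality 5 -> weight = frequency

  parts2 <- list(part(list(1, 2, 3), 5L), part(list(c(1, 2, 3)), 5L))
  # drop PU-extremity junctions: the single-domain partition has none
  js2 <- junction_stats(parts2, pus, include_pu_extremities = FALSE)
  expect_equal(js2$count, c(1L, 1L))
  expect_equal(js2$frequency, c(0.5, 0.5))

  parts3 <- list(part(list(1, 2, 3), 4L), part(list(c(1, 2, 3)), 5L))
  js3 <- junction_stats(parts3, pus)
  expect_equal(js3$frequency, js3$count / length(parts3))
  expect_true(all(js3$weight <= js3$frequency + 1e-12))
  expect_equal(js3$weight, c((4 / 5 + 5 / 5) / 2, (4 / 5 + 5 / 5) / 2))
})

test_that("domain frequencies count identical residue sets across partitions", {
  pus <- cbind(start = c(1L, 11L), end = c(10L, 20L))
  part <- function(blocks, q) {
    dsets <- lapply(blocks, function(b)
      sort(unlist(lapply(b, function(i) pus[i, 1]:pus[i, 2]))))
    list(domains = dsets, pu_members = lapply(blocks, as.integer),
         n_domains = length(dsets), quality = q)
  }
  parts <- list(part(list(1, 2), 4L), part(list(1, 2), 4L),
                part(list(c(1, 2)), 5L))
  df <- domain_frequency(parts)
  expect_equal(df$count[1], 2L)                       # 1-10 and 11-20 twice
  expect_equal(df$domain[df$count == 1], "1-20")
  expect_equal(sum(df$count), 5L)
})

test_that("discontinuous domains render as comma-separated ranges", {
  expect_equal(ranges_label(c(1:5, 9:12)), "1-5,9-12")
  expect_equal(ranges_label(7L), "7")
  expect_equal(ranges_label(c(3, 1, 2)), "1-3")
})
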