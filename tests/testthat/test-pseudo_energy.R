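test_that("the bundled propensity table is a symmetric finite 20x20 log-odds", {
  tab <- load_propensity_table()
  lo <- tab$log_odds
  expect_equal(dim(lo), c(20L, 20L))
  expect_equal(rownames(lo), aa_alphabet())
  expect_equal(lo, t(lo))
  expect_true(all(is.finite(lo)))
})

test_that("pseudo-energy is the negated sum of qualifying contact log-odds", {
  tab <- load_propensity_table()
  # 5 residues on a line: only pairs with |i-j| >= 3 AND d <= 8 qualify;
  # with 3 A steps those are exactly (1,4) and (2,5) at 9 A -> none;
  # shrink steps to 2.5 A: (1,4),(2,5) at 7.5 A qualify, (1,5) at 10 A not
  xyz <- cbind(2.5 * (0:4), 0, 0)
  st <- new_structure(xyz, c("A", "C", "D", "L", "V"))
  lo <- tab$log_odds
  expect_equal(pseudo_energy(st, 1:5, tab),
               -(lo["A", "L"] + lo["C", "V"]))
  # no qualifying pairs -> 0
  far <- new_structure(cbind(10 * (0:4), 0, 0), c("A", "C", "D", "L", "V"))
  expect_equal(pseudo_energy(far, 1:5, tab), 0)
  # swapping identical residues leaves E unchanged
  st2 <- new_structure(xyz, c("A", "C", "D", "L", "V"))
  st2$residues$amino_acid <- c("A", "C", "D", "L", "V")
  expect_equal(pseudo_energy(st2, 1:5, tab), pseudo_energy(st, 1:5, tab))
})

test_that("pseudo-energy is invariant under rigid-body motion", {
  fx <- make_globule_chain(c(15), globule_radius = 8, seed = 12)
  st <- fx$structure
  tab <- load_propensity_table()
  e0 <- pseudo_energy(st, 1:15, tab)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  st_rot <- new_structure(ca_coords(st) %*% R + rep(1, 15) %o% c(5, -3, 2),
                          st$residues$amino_acid)
  expect_equal(pseudo_energy(st_rot, 1:15, tab), e0, tolerance = 1e-9)
})

test_that("decoy distribution is seed-deterministic and matches the permutation mean", {
  fx <- make_globule_chain(c(8), globule_radius = 6, seed = 21)
  st <- fx$structure
  tab <- load_propensity_table()
  d1 <- decoy_distribution(st, 1:8, tab, n_decoys = 200, seed = 99)
  d2 <- decoy_distribution(st, 1:8, tab, n_decoys = 200, seed = 99)
  expect_identical(d1$mu, d2$mu)
  expect_identical(d1$sigma, d2$sigma)

  # exact permutation expectation (closed form) vs sampled mean
  pr <- peeldom:::.energy_pairs(st, 1:8)
  mu_exact <- oracle_permutation_mean(st$residues$amino_acid[1:8],
                                      nrow(pr), tab$log_odds)
  d <- decoy_distribution(st, 1:8, tab, n_decoys = 2000, seed = 5)
  se <- d$sigma / sqrt(length(d$energies))
  expect_lt(abs(d$mu - mu_exact), 3 * se + 1e-12)
})

test_that("closed-form permutation mean agrees with explicit enumeration at n = 4", {
  # independent validation of the oracle itself on 4! = 24 permutations
  xyz <- cbind(2.5 * (0:3), 0, 0)    # pair (1,4) qualifies
  st <- new_structure(xyz, c("A", "L", "D", "K"))
  tab <- load_propensity_table()
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  labels <- st$residues$amino_acid
  energies <- apply(perms, 1, function(r) {
    lab <- labels[unlist(r)]
    -tab$log_odds[lab[1], lab[4]]
  })
  pr <- peeldom:::.energy_pairs(st, 1:4)
  expect_equal(nrow(pr), 1L)
  expect_equal(mean(energies),
               oracle_permutation_mean(labels, 1, tab$log_odds),
               tolerance = 1e-12)
})

test_that("homopolymer units are degenerate with sigma = 0", {
  fx <- make_globule_chain(c(10), globule_radius = 7, seed = 31)
  st <- fx$structure
  st$residues$amino_acid <- rep("A", 10)
  tab <- load_propensity_table()
  d <- decoy_distribution(st, 1:10, tab, n_decoys = 50, seed = 1)
  expect_true(d$degenerate)
  expect_equal(d$sigma, 0)
  a <- assess_unit(st, 1:10, tab, n_decoys = 50, seed = 1)
  expect_true(a$degenerate)
  expect_true(is.na(a$z_score))
  expect_true(is.na(a$aul_percent))    # reported n/a, never 0
})

test_that("z_score follows (E - mu)/sigma and rejects sigma = 0", {
  expect_equal(z_score(-4, -4, 3), 0)
  expect_equal(z_score(-10, -4, 3), -2)
  expect_error(z_score(-10, -4, 0), "degenerate")
})

test_that("the Chebyshev AUL mapping is exact at its anchor points", {
  expect_equal(aul_from_zscore(-2.0), 75)
  expect_equal(aul_from_zscore(-4.0), 94)            # 93.75 -> nearest %
  expect_equal(aul_from_zscore(-4.0, digits = 2), 93.75)
  expect_equal(aul_from_zscore(-0.8), 0)
  expect_equal(aul_from_zscore(0), 0)
  expect_equal(aul_from_zscore(3), 0)
  expect_equal(aul_from_zscore(-1), 0)               # bound is vacuous at -1
  expect_error(aul_from_zscore(Inf), "finite")
})

test_that("AUL is monotone non-increasing in Z below -1 and zero above", {
  zs <- seq(-10, -1, by = 0.25)
  auls <- vapply(zs, aul_from_zscore, 0, digits = 6)
  expect_true(all(diff(auls) <= 1e-9))
  expect_true(all(vapply(seq(-0.99, 5, by = 0.5), aul_from_zscore, 0) == 0))
})
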