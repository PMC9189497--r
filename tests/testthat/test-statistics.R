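# AOD, karyotype fitness summaries, load decomposition, outcome
# classification, per-arrangement mutation accumulation and the
# invasion-probability tiling.

test_that("karyotype fitness summary averages within classes and is
          order-invariant", {
  muts <- data.frame(pos = c(5e5 + 1, 5e5 + 2), s = c(-0.6, -0.4), h = c(0, 0))
  # two AA individuals (fitness 0.4 and 0.6 via homozygous muts), one AB at 1
  pop <- tiny_population(muts,
                         list(c(1L), c(1L),      # AA hom for m1: w = 0.4
                              c(2L), c(2L),      # AA hom for m2: w = 0.6
                              integer(0), integer(0)), # AB, w = 1
                         c(1L, 1L, 1L, 1L, 1L, 0L))
  ks <- karyotype_fitness_summary(pop)
  expect_equal(ks$W_AA, 0.5)
  expect_equal(ks$W_AB, 1.0)
  expect_true(is.na(ks$W_BB))
  expect_equal(ks$n_AA + ks$n_AB + ks$n_BB, pop$N)
  # permuting individuals leaves the summary unchanged
  perm <- c(3L, 1L, 2L)
  idx <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  pop2 <- new_population("P1", pop$haps[idx], pop$arr[idx], pop$catalog,
                         pop$map)
  expect_equal(karyotype_fitness_summary(pop2)[, 1:6],
               ks[, 1:6])
})

test_that("AOD follows the Ohta definition with hand arithmetic", {
  s <- function(W_AA, W_AB, W_BB) {
    compute_aod(data.frame(W_AA = W_AA, W_AB = W_AB, W_BB = W_BB))
  }
  r <- s(0.8, 1.0, 0.9)
  expect_equal(r$s1p, 0.2)
  expect_equal(r$s2p, 0.1)
  expect_equal(r$sp, 0.1)
  expect_equal(r$symmetry, 0.1)
  flat <- s(1, 1, 1)
  expect_equal(c(flat$sp, flat$symmetry), c(0, 0))
  over <- s(1.2, 1.0, 1.0)   # homokaryotype fitter: negative AOD
  expect_equal(over$sp, -0.2)
  und <- s(NA, 1.0, 0.9)     # missing class propagates, not fabricated
  expect_true(is.na(und$s1p) && is.na(und$sp) && is.na(und$symmetry))
  expect_equal(und$s2p, 1 - 0.9)
  expect_true(all(is.na(s(0.5, 0, 0.5)[, c("s1p", "s2p", "sp")])))
})

test_that("AOD equals a brute-force recomputation from individual fitness
          lists", {
  set.seed(30)
  cfg <- desk_config()
  for (k in 1:20) {
    n_aa <- sample(1:5, 1); n_ab <- sample(1:5, 1); n_bb <- sample(1:5, 1)
    muts <- data.frame(pos = 5e5 + seq_len(6), s = -runif(6, 0, 0.9), h = 0)
    N <- n_aa + n_ab + n_bb
    assign_list <- lapply(seq_len(2 * N), function(i)
      sort(sample(1:6, sample(0:3, 1))))
    pop <- tiny_population(muts, assign_list,
                           c(rep(1L, 2 * n_aa), rep(c(1L, 0L), n_ab),
                             rep(0L, 2 * n_bb)), cfg)
    ks <- karyotype_fitness_summary(pop)
    w <- pop$fitness
    kar <- population_karyotypes(pop)
    s1_oracle <- 1 - mean(w[kar == "AA"]) / mean(w[kar == "AB"])
    s2_oracle <- 1 - mean(w[kar == "BB"]) / mean(w[kar == "AB"])
    aod <- compute_aod(ks)
    if (mean(w[kar == "AB"]) > 0) {
      expect_equal(aod$s1p, s1_oracle)
      expect_equal(aod$s2p, s2_oracle)
      expect_equal(aod$sp, min(s1_oracle, s2_oracle))
      expect_equal(aod$symmetry, abs(s1_oracle - s2_oracle))
    }
  }
})

test_that("load decomposition composes multiplicatively with hand values", {
  cfg <- sim_config(N_BI = 4)
  st <- make_divergent_pair(1, 0, -0.1, cfg)
  l1 <- compute_loads(st$P1, st$P2, "supergene")
  expect_equal(l1$drift_load, 0.1)
  expect_equal(l1$mutational_load, 0)
  expect_equal(l1$segregation_load, 0.1)
  expect_equal(l1$drift_fraction, 1)
  l2 <- compute_loads(st$P2, st$P1, "supergene")
  expect_equal(l2$drift_load, 0)
  expect_true(is.na(l2$drift_fraction))
  # empty regions carry no load
  lc2 <- compute_loads(st$P1, st$P2, "chr2")
  expect_equal(lc2$segregation_load, 0)
  # a shared fixed mutation is invisible (not private)
  both <- catalog_add(st$P1$catalog, 3e6 + 5, -0.5, 0, 1L, 0L)
  st$P1$fixed <- c(st$P1$fixed, both)
  st$P2$fixed <- c(st$P2$fixed, both)
  expect_equal(compute_loads(st$P1, st$P2, "supergene")$drift_load, 0.1)
})

test_that("segregating mutations enter the mutational load component", {
  cfg <- desk_config()
  muts <- data.frame(pos = c(3e6 + 1, 1.5e7 + 1), s = c(-0.5, -0.5), h = c(0, 0))
  # one of two individuals homozygous for a supergene mutation
  pop <- tiny_population(muts, list(c(1L), c(1L), integer(0), integer(0)),
                         rep(0L, 4), cfg)
  ref <- tiny_population(muts[0, ], rep(list(integer(0)), 4), rep(0L, 4), cfg)
  l <- compute_loads(pop, ref, "supergene")
  expect_equal(l$mutational_load, 1 - mean(c(0.5, 1)))
  expect_equal(l$drift_load, 0)
  expect_equal(l$segregation_load, l$mutational_load)
})

test_that("outcome classification thresholds homokaryotype means and is
          monotone in the threshold", {
  cfg <- desk_config()
  mk <- function(saa, sbb) {
    muts <- data.frame(pos = c(3e6 + 1, 4e6 + 1), s = c(saa, sbb), h = c(0, 0))
    tiny_population(muts, list(c(1L), c(2L), c(1L), c(2L)),
                    c(1L, 0L, 1L, 0L), cfg)  # all AB; A carries m1, B m2
  }
  # both homokaryotypes viable
  expect_equal(classify_outcome(mk(-0.5, -0.4)), "POLY_BOTH_VIABLE")
  # one inviable
  expect_equal(classify_outcome(mk(-0.995, -0.4)), "HALF_LETHAL")
  # both inviable
  expect_equal(classify_outcome(mk(-0.995, -0.999)), "BALANCED_LETHAL")
  # threshold monotonicity: raising it can only move toward more "lethal"
  ranks <- c(POLY_BOTH_VIABLE = 0, HALF_LETHAL = 1, BALANCED_LETHAL = 2)
  pop <- mk(-0.9, -0.6)
  cls <- vapply(c(0.01, 0.2, 0.5, 0.99),
                function(th) classify_outcome(pop, th), character(1))
  expect_true(all(diff(ranks[cls]) >= 0))
  # monomorphic populations cannot be classified
  mono <- tiny_population(data.frame(pos = numeric(0), s = numeric(0),
                                     h = numeric(0))[0, ],
                          rep(list(integer(0)), 4), rep(0L, 4), cfg)
  expect_error(classify_outcome(mono), "polymorphic")
})

test_that("masking: with h = 0, arrangement-private fixed load never touches
          heterokaryotype fitness", {
  cfg <- desk_config()
  base <- data.frame(pos = 3e6 + 1, s = -0.8, h = 0)
  pop <- tiny_population(base, list(c(1L), integer(0), c(1L), integer(0)),
                         c(1L, 0L, 1L, 0L), cfg)   # both AB; A carries the mut
  ks0 <- karyotype_fitness_summary(pop)
  ek0 <- expected_karyotype_fitness(pop)
  expect_equal(ks0$W_AB, 1)      # masked in heterokaryotypes
  expect_equal(ek0$W_AA, 1 - 0.8) # exposed in (expected) homokaryotypes
  # add a second private fixed-within-A mutation: W_AB still 1
  extra <- catalog_add(pop$catalog, 5e6 + 1, -0.9, 0, 2L, 0L)
  pop$haps[[1]] <- sort(c(pop$haps[[1]], extra))
  pop$haps[[3]] <- sort(c(pop$haps[[3]], extra))
  pop$haps <- lapply(pop$haps, function(h) h[order(pop$catalog$pos[h])])
  pop2 <- new_population("P1", pop$haps, pop$arr, pop$catalog, pop$map)
  expect_equal(karyotype_fitness_summary(pop2)$W_AB, 1)
  expect_equal(expected_karyotype_fitness(pop2)$W_AA, 0.2 * 0.1)
})

test_that("per-arrangement mutation counts match hand means", {
  cfg <- desk_config()
  muts <- data.frame(pos = c(3e6 + 1, 4e6 + 1, 1.2e7 + 1),
                     s = c(-0.1, -0.2, -0.3), h = c(0, 0, 0))
  # A haps: {m1}, {m1, m2}; B haps: {} and {m3 outside supergene}
  pop <- tiny_population(muts, list(c(1L), integer(0), c(1L, 2L), c(3L)),
                         c(1L, 0L, 1L, 0L), cfg)
  mpa <- mutations_per_arrangement(pop, "supergene")
  expect_equal(mpa$n_mut_A, 1.5)
  expect_equal(mpa$n_mut_B, 0)
  expect_equal(mpa$load_A, mean(c(0.1, 1 - 0.9 * 0.8)))
  # all mutation-free
  empty <- tiny_population(muts[0, ], rep(list(integer(0)), 4),
                           c(1L, 0L, 1L, 0L), cfg)
  expect_equal(mutations_per_arrangement(empty)$n_mut_A, 0)
})

test_that("invasion tiling bins at the stated half-widths and suppresses
          thin tiles", {
  rec <- data.frame(sp = c(rep(0.002, 30), rep(0.012, 40), rep(0.012, 21)),
                    symmetry = c(rep(0.001, 30), rep(0.001, 40), rep(0.02, 21)),
                    invaded = c(rep(TRUE, 30), rep(TRUE, 10), rep(FALSE, 30),
                                rep(TRUE, 21)))
  tiles <- bin_invasion_by_aod_symmetry(rec)
  expect_equal(nrow(tiles), 3L)
  t1 <- tiles[tiles$aod_mid == 0.005 & tiles$sym_mid == 0.0075, ]
  expect_equal(t1$p_invasion, 1)
  t2 <- tiles[tiles$aod_mid == 0.015 & tiles$sym_mid == 0.0075, ]
  expect_equal(t2$p_invasion, 0.25)
  # a tile with exactly min_n observations is suppressed
  tiles20 <- bin_invasion_by_aod_symmetry(rec[-nrow(rec), ])
  expect_equal(nrow(tiles20), 2L)
})
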