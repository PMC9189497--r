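# Fitness evaluation, karyotypes, meiosis (inversion-aware recombination)
# and the one-generation Wright-Fisher update. Distributional checks are run
# against independent oracles (hand products, Haldane's map function,
# Poisson/binomial expectations); both the reference R engine and the
# compiled engine are exercised.

test_that("multiplicative fitness matches hand products and the log oracle", {
  muts <- data.frame(pos = c(5e5 + 10, 1e6 + 20, 1.5e6 + 30),
                     s = c(-0.2, -0.1, -0.5), h = c(0, 0.1, 0))
  # ind 1: m1 homozygous, m2 heterozygous; ind 2: mutation-free
  pop <- tiny_population(muts,
                         list(c(1L, 2L), c(1L), integer(0), integer(0)),
                         c(0L, 0L, 0L, 0L))
  expect_equal(pop$fitness[1], 0.8 * (1 + 0.1 * -0.1))
  expect_equal(pop$fitness[2], 1)
  # brute-force oracle over random genotypes
  set.seed(42)
  catalog <- new_catalog()
  ids <- catalog_add(catalog, runif(60, 0, 5000), -runif(60, 0, 0.6),
                     runif(60, 0, 0.3), 1L, 0L)
  for (k in 1:100) {
    h1 <- sort(sample(ids, sample(0:12, 1)))
    h2 <- sort(sample(ids, sample(0:12, 1)))
    h1 <- h1[order(catalog$pos[h1])]
    h2 <- h2[order(catalog$pos[h2])]
    expect_equal(individual_fitness(h1, h2, catalog),
                 fitness_oracle(h1, h2, catalog))
  }
})

test_that("fitness factors are floored at zero (recessive lethality)", {
  muts <- data.frame(pos = c(5e5 + 1, 5e5 + 2), s = c(-1.5, -0.5), h = c(0, 0))
  pop <- tiny_population(muts, list(c(1L), c(1L), c(2L), integer(0)),
                         c(0L, 0L, 0L, 0L))
  expect_equal(pop$fitness[1], 0)   # homozygous s = -1.5 is lethal, not +0.5
  expect_equal(pop$fitness[2], 1)   # heterozygous with h = 0 is masked
  expect_error(individual_fitness(c(99L), integer(0), pop$catalog),
               "unknown mutation id")
})

test_that("karyotype is order-insensitive and counts partition N", {
  expect_equal(karyotype(1L, 1L), "AA")
  expect_equal(karyotype(c(1L, 0L, 0L), c(0L, 1L, 0L)), c("AB", "AB", "BB"))
  pop <- make_balanced_lethal_fixture(10)
  expect_true(all(population_karyotypes(pop) == "AB"))
})

test_that("gametes of AB parents carry each arrangement half the time and never
          recombine inside the inversion by crossover", {
  set.seed(7)
  cfg <- desk_config()
  cfg$mu <- 0; cfg$gamma_gc <- 0
  muts <- data.frame(pos = c(3e6 + 100, 4e6 + 200), s = c(-0.5, -0.5), h = c(0, 0))
  pop <- tiny_population(muts, list(c(1L), c(2L), integer(0), integer(0)),
                         c(1L, 0L, 1L, 0L), cfg)
  idA <- pop$haps[[1]]; idB <- pop$haps[[2]]
  nA <- 0; n <- 4000; incoherent <- 0
  for (i in seq_len(n)) {
    g <- meiosis(pop, 1, cfg)
    if (g$arr == 1L) nA <- nA + 1
    ok <- (g$arr == 1L && identical(g$ids, idA)) ||
      (g$arr == 0L && identical(g$ids, idB))
    if (!ok) incoherent <- incoherent + 1
  }
  expect_equal(incoherent, 0)  # crossover suppression is absolute
  expect_lt(abs(nA / n - 0.5), 3 * sqrt(0.25 / n))  # Mendelian segregation
})

test_that("explicit crossover breakpoints avoid the inversion in AB meioses
          and have the configured Poisson mean otherwise", {
  set.seed(8)
  cfg <- desk_config()
  map <- build_genome_map(cfg)
  n_in_inv <- 0; counts <- integer(2000)
  for (i in 1:2000) {
    bp <- sample_crossover_breakpoints(TRUE, cfg, map)
    n_in_inv <- n_in_inv +
      sum(bp >= map$inversion[1] & bp < map$inversion[2])
  }
  expect_equal(n_in_inv, 0)
  for (i in 1:2000) {
    counts[i] <- length(sample_crossover_breakpoints(FALSE, cfg, map))
  }
  lam <- cfg$rho * cfg$L
  expect_lt(abs(mean(counts) - lam), 4 * sqrt(lam / 2000))
})

test_that("gene conversion transfers content at rate ~ 2*gamma*lambda per
          heterokaryotype meiosis and never changes the arrangement", {
  set.seed(9)
  cfg <- desk_config(); cfg$mu <- 0
  muts <- data.frame(pos = c(3e6 + 100, 4e6 + 200), s = c(-0.5, -0.5), h = c(0, 0))
  pop <- tiny_population(muts, list(c(1L), c(2L), integer(0), integer(0)),
                         c(1L, 0L, 1L, 0L), cfg)
  idA <- pop$haps[[1]]; idB <- pop$haps[[2]]
  n <- 20000; exchanged <- 0; nA <- 0
  for (i in seq_len(n)) {
    g <- meiosis(pop, 1, cfg)
    nA <- nA + (g$arr == 1L)
    ok <- (g$arr == 1L && identical(g$ids, idA)) ||
      (g$arr == 0L && identical(g$ids, idB))
    if (!ok) exchanged <- exchanged + 1
  }
  expected <- n * 2 * cfg$gamma_gc * cfg$lambda_gc
  expect_gt(exchanged, 0.4 * expected)
  expect_lt(exchanged, 2 * expected)
  expect_lt(abs(nA / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("two-point recombination fractions follow Haldane's map function
          in both engines", {
  cfg <- desk_config(); cfg$mu <- 0; cfg$gamma_gc <- 0
  # 0.1 Mb apart on chr2 at desk scale: c = (1 - exp(-2*rho*d))/2
  d <- 1e5
  muts <- data.frame(pos = c(1.5e7 + 10, 1.5e7 + 10 + d),
                     s = c(-0.5, -0.5), h = c(0, 0))
  cexp <- 0.5 * (1 - exp(-2 * cfg$rho * d))
  for (engine in c("R", "cpp")) {
    set.seed(10)
    pop <- tiny_population(muts, list(c(1L, 2L), integer(0),
                                      c(1L, 2L), integer(0)),
                           c(0L, 0L, 0L, 0L), cfg)
    n <- 3000; rec <- 0
    off <- pop
    for (i in seq_len(n / pop$N / 2)) {
      off2 <- next_generation(pop, pop$N, cfg, engine = engine)
      for (h in off2$haps) if (length(h) == 1L) rec <- rec + 1
    }
    # each generation produces 4 gametes; count recombinant haplotypes
    n_gam <- (n / pop$N / 2) * 4
    expect_lt(abs(rec / n_gam - cexp), 4 * sqrt(cexp * (1 - cexp) / n_gam))
  }
})

test_that("chromosomes assort independently", {
  set.seed(12)
  cfg <- desk_config(); cfg$mu <- 0; cfg$gamma_gc <- 0; cfg$rho <- 0
  muts <- data.frame(pos = c(5e5 + 10, 1.5e7 + 10), s = c(-0.5, -0.5), h = c(0, 0))
  pop <- tiny_population(muts, list(c(1L, 2L), integer(0),
                                    integer(0), integer(0)),
                         c(0L, 0L, 0L, 0L), cfg)
  n <- 4000; rec <- 0
  for (i in seq_len(n)) {
    g <- meiosis(pop, 1, cfg)
    if (length(g$ids) == 1L) rec <- rec + 1
  }
  expect_lt(abs(rec / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("no-op meiosis returns a parental haplotype verbatim (within a
          chromosome; chromosomes always assort freely)", {
  set.seed(13)
  cfg <- desk_config(); cfg$mu <- 0; cfg$gamma_gc <- 0; cfg$rho <- 0
  muts <- data.frame(pos = c(5e5 + 10, 5e5 + 20, 8e6 + 5),
                     s = rep(-0.3, 3), h = rep(0, 3))
  pop <- tiny_population(muts, list(c(1L, 3L), c(2L), integer(0), integer(0)),
                         c(0L, 0L, 0L, 0L), cfg)
  for (i in 1:50) {
    g <- meiosis(pop, 1, cfg)
    expect_true(identical(g$ids, pop$haps[[1]]) ||
                  identical(g$ids, pop$haps[[2]]))
  }
})

test_that("neutral Wright-Fisher sampling is binomial around parental
          frequencies", {
  set.seed(14)
  cfg <- desk_config(); cfg$mu <- 0; cfg$gamma_gc <- 0; cfg$rho <- 0
  N <- 20L
  muts <- data.frame(pos = 5e5 + 10, s = -1e-9, h = 0)
  hap_assign <- c(lapply(1:20, function(i) c(1L)),       # 20 carrier haps
                  rep(list(integer(0)), 20))             # 20 empty haps
  pop <- tiny_population(muts, hap_assign, rep(0L, 40), cfg)
  p0 <- 0.5
  freqs <- replicate(400, {
    off <- next_generation(pop, N, cfg)
    mean(lengths(off$haps) > 0)
  })
  expect_lt(abs(mean(freqs) - p0), 0.02)
  expect_lt(abs(var(freqs) - p0 * (1 - p0) / (2 * N)) / (p0 * (1 - p0) / (2 * N)),
            0.35)
})

test_that("extinction is raised when all fitnesses are zero and single
          viable parents self", {
  cfg <- desk_config(); cfg$mu <- 0
  muts <- data.frame(pos = 5e5 + 10, s = -1, h = 0)
  dead <- tiny_population(muts, list(c(1L), c(1L), c(1L), c(1L)),
                          rep(0L, 4), cfg)
  expect_true(all(dead$fitness == 0))
  expect_error(next_generation(dead, 2L, cfg), "extinct")
  # one viable + one dead parent: all offspring are selfed progeny
  half <- tiny_population(muts, list(c(1L), c(1L), integer(0), integer(0)),
                          rep(0L, 4), cfg)
  set.seed(15)
  off <- next_generation(half, 10L, cfg)
  expect_equal(off$N, 10L)
  expect_true(all(lengths(off$haps) == 0))  # viable parent is mutation-free
})

test_that("fixed mutations are pruned into the registry and relative
          fitness ratios are unchanged", {
  cfg <- desk_config()
  muts <- data.frame(pos = c(5e5 + 10, 5e5 + 20), s = c(-0.2, -0.1), h = c(0.5, 0.5))
  # m1 on all four haplotypes (fixed), m2 on two
  pop <- tiny_population(muts, list(c(1L, 2L), c(1L), c(1L, 2L), c(1L)),
                         rep(0L, 4), cfg)
  w_before <- pop$fitness
  pruned <- prune_fixed(pop)
  expect_true(1L %in% pruned$fixed)
  expect_false(any(vapply(pruned$haps, function(h) 1L %in% h, logical(1))))
  expect_true(all(vapply(pruned$haps[c(1, 3)], function(h) 2L %in% h, logical(1))))
  expect_equal(pruned$fitness[1] / pruned$fitness[2],
               w_before[1] / w_before[2])
  # frequency 0.99 is untouched: nothing at exactly 2N stays put
  expect_identical(prune_fixed(pruned)$fixed, pruned$fixed)
})

test_that("neutral molecular clock: fixation rate equals the per-gamete
          mutation rate (both engines)", {
  cfg <- desk_config(); cfg$s_scale <- 0
  map <- build_genome_map(cfg)
  u <- gamete_mutation_rates(cfg, map)$u_del
  for (engine in c("cpp", "R")) {
    set.seed(16)
    gens <- if (engine == "cpp") 4000 else 1500
    pop <- founder_population("P1", 10L, "B", new_catalog(), map)
    for (g in seq_len(gens)) pop <- next_generation(pop, 10L, cfg, engine = engine)
    rate <- length(pop$fixed) / gens
    expect_lt(abs(rate - u) / u, 0.15)
  }
})

test_that("a single-copy neutral mutation fixes with probability ~ 1/2N", {
  set.seed(17)
  cfg <- desk_config(); cfg$mu <- 0; cfg$gamma_gc <- 0; cfg$rho <- 0
  N <- 5L
  muts <- data.frame(pos = 5e5 + 10, s = -1e-12, h = 0)
  hap_assign <- c(list(c(1L)), rep(list(integer(0)), 2L * N - 1L))
  pop <- tiny_population(muts, hap_assign, rep(0L, 2L * N), cfg)
  fixed <- 0; n <- 2000
  for (i in seq_len(n)) {
    p <- pop
    repeat {
      p <- next_generation(p, N, cfg)
      if (length(p$fixed)) { fixed <- fixed + 1; break }
      if (sum(vapply(p$haps, length, integer(1))) == 0L) break
    }
  }
  p0 <- 1 / (2 * N)
  expect_lt(abs(fixed / n - p0), 4 * sqrt(p0 * (1 - p0) / n))
})

test_that("catalog compaction and cloning preserve genotypes, fitness and
          within-haplotype order", {
  set.seed(19)
  cfg <- desk_config(T_BI = 30000)
  map <- build_genome_map(cfg)
  catalog <- new_catalog()
  P1 <- founder_population("P1", 10L, "B", catalog, map)
  P2 <- founder_population("P2", 10L, "A", catalog, map)
  for (g in 1:150) {
    P1 <- next_generation(P1, 10L, cfg)
    P2 <- next_generation(P2, 10L, cfg)
  }
  pos_before <- lapply(P1$haps, function(h) P1$catalog$pos[h])
  w_before <- P1$fitness
  fixed_pos_before <- sort(P1$catalog$pos[P1$fixed])
  both <- compact_catalog(list(P1, P2))
  C1 <- both[[1]]; C2 <- both[[2]]
  expect_lte(C1$catalog$n, catalog$n)
  expect_identical(lapply(C1$haps, function(h) C1$catalog$pos[h]), pos_before)
  expect_identical(sort(C1$catalog$pos[C1$fixed]), fixed_pos_before)
  expect_equal(population_fitness(C1), w_before)
  # remapped ids are valid and shared across the pair
  expect_identical(C1$catalog, C2$catalog)
  expect_true(all(unlist(C1$haps) <= C1$catalog$n))
  # cloning decouples subsequent additions
  cl <- catalog_clone(C1$catalog)
  n0 <- C1$catalog$n
  catalog_add(cl, 5e5 + 1, -0.5, 0, 1L, 0L)
  expect_equal(cl$n, n0 + 1L)
  expect_equal(C1$catalog$n, n0)  # original untouched by the clone
})

test_that("both engines produce statistically consistent burn-in outcomes", {
  cfg <- desk_config(T_BI = 40000)  # 400 scaled generations
  set.seed(18)
  f_cpp <- replicate(6, {
    st <- run_burnin(cfg, seed = sample.int(1e6, 1))
    st$summary$n_fixed_P1
  })
  old <- options(aodsim.engine = "R"); on.exit(options(old))
  f_r <- replicate(4, {
    st <- run_burnin(cfg, seed = sample.int(1e6, 1))
    st$summary$n_fixed_P1
  })
  # same process: counts on a common Poisson-ish scale
  expect_gt(stats::wilcox.test(f_cpp, f_r, exact = FALSE)$p.value, 0.001)
})
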