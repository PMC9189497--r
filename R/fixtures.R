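# Deterministic fixture populations: hand-specified karyotypes, mutation
# lists and fixed registries with the statistical structure the analysis
# assumes, so every downstream statistic is testable without running
# evolution. Fixtures inject mutations directly into a fresh catalog.

# k positions evenly spread over the mutable segments inside the inversion;
# phase in (0,1) shifts the grid so different calls give disjoint sites.
.supergene_positions <- function(map, k, phase = 0.5) {
  inside <- map$seg_start >= map$inversion[1] & map$seg_end <= map$inversion[2]
  if (!any(inside)) stop("no mutable segments inside the inversion", call. = FALSE)
  starts <- map$seg_start[inside]
  len <- map$seg_end[inside][1] - starts[1]
  total <- sum(inside) * len
  u <- (seq_len(k) - phase) / k * total
  j <- findInterval(u, (seq_len(sum(inside)) - 1) * len)
  starts[j] + (u - (j - 1) * len)
}

#' Build a population from an explicit specification
#'
#' The specification is a list with:
#' * `N`: number of individuals, or implicitly `n_AA + n_AB + n_BB`;
#' * `n_AA`, `n_AB`, `n_BB`: karyotype counts (individuals are laid out in
#'   that order; AB individuals carry the A haplotype first);
#' * `muts`: optional data.frame with columns `pos`, `s`, `h` and `on` — a
#'   list-column (or character vector) naming the carriers: `"A"` / `"B"`
#'   (every haplotype of that arrangement) or an integer vector of haplotype
#'   indices (1..2N);
#' * `fixed`: optional data.frame `pos`, `s`, `h` of mutations placed in the
#'   population's fixed registry (pruned from genotypes);
#' * `label`: population label (default `"P1"`).
#'
#' @param spec The specification list.
#' @param cfg A [sim_config()] giving the genome layout (default
#'   `sim_config()`).
#' @param catalog Optional shared catalog (default: a fresh one).
#' @return An `sg_pop` with fitness caches computed.
#' @export
make_population <- function(spec, cfg = sim_config(), catalog = new_catalog()) {
  map <- build_genome_map(cfg)
  n_AA <- spec$n_AA %||% 0L
  n_AB <- spec$n_AB %||% 0L
  n_BB <- spec$n_BB %||% 0L
  N <- spec$N %||% (n_AA + n_AB + n_BB)
  if (N != n_AA + n_AB + n_BB) {
    stop("fixture spec invalid: karyotype counts must sum to N", call. = FALSE)
  }
  arr <- c(rep(1L, 2L * n_AA), rep(c(1L, 0L), n_AB), rep(0L, 2L * n_BB))
  haps <- rep(list(integer(0)), 2L * N)
  if (!is.null(spec$muts) && nrow(spec$muts)) {
    m <- spec$muts
    seg_ok <- vapply(m$pos, function(p) {
      any(p >= map$seg_start & p < map$seg_end)
    }, logical(1))
    if (!all(seg_ok)) {
      stop("fixture spec invalid: mutation position outside mutable segments",
           call. = FALSE)
    }
    ids <- catalog_add(catalog, m$pos, m$s, m$h, 0L, 0L)
    on <- if (is.list(m$on)) m$on else as.list(m$on)
    for (r in seq_along(ids)) {
      carriers <- on[[r]]
      idx <- if (identical(carriers, "A")) which(arr == 1L)
             else if (identical(carriers, "B")) which(arr == 0L)
             else as.integer(carriers)
      if (length(idx) && (min(idx) < 1L || max(idx) > 2L * N)) {
        stop("fixture spec invalid: haplotype index out of range", call. = FALSE)
      }
      for (i in idx) haps[[i]] <- c(haps[[i]], ids[r])
    }
    pos <- catalog$pos
    haps <- lapply(haps, function(h) h[order(pos[h])])
  }
  fixed <- integer(0)
  if (!is.null(spec$fixed) && nrow(spec$fixed)) {
    fixed <- catalog_add(catalog, spec$fixed$pos, spec$fixed$s, spec$fixed$h,
                         0L, 0L)
  }
  new_population(spec$label %||% "P1", haps, arr, catalog, map,
                 generation = spec$generation %||% 0L, fixed = fixed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Balanced-lethal fixture population
#'
#' All-heterokaryotype population in which the A haplotypes all share one
#' set of recessive deleterious mutations and the B haplotypes a disjoint
#' set, each set strong enough that the expected homokaryotype fitness is
#' below 0.01 while every heterokaryotype has fitness 1 (with `h = 0`). One
#' Wright-Fisher generation on this population loses about half the zygotes
#' (the Mendelian AA/BB half of an AB x AB cross).
#'
#' @param N Even number of individuals.
#' @param load_s Homozygous selection coefficient of each lethal-set
#'   mutation (default -1: unconditional recessive lethals).
#' @param cfg A [sim_config()] for the genome layout; `h` of the fixture
#'   mutations is 0 regardless of `cfg$h_del`.
#' @return An `sg_pop`, all AB, fitness 1 everywhere.
#' @export
make_balanced_lethal_fixture <- function(N, load_s = -1, cfg = sim_config()) {
  stopifnot(N %% 2 == 0, load_s < 0)
  k <- if (load_s <= -1) 1L else max(1L, ceiling(log(0.005) / log1p(load_s)))
  map <- build_genome_map(cfg)
  posA <- .supergene_positions(map, k, phase = 0.25)
  posB <- .supergene_positions(map, k, phase = 0.75)
  spec <- list(n_AB = N,
               muts = data.frame(pos = c(posA, posB),
                                 s = load_s, h = 0,
                                 on = I(as.list(rep(c("A", "B"), each = k)))))
  make_population(spec, cfg)
}

#' Divergent population pair with known private fixed load
#'
#' Two monomorphic, mutation-free populations of size `cfg$N_BI` whose
#' fixed registries hold `k1` (P1) and `k2` (P2) private recessive
#' deleterious mutations of effect `s_each`, evenly placed in the supergene
#' region. After [admix()], the expected-pairing AOD has the closed form
#' `s1' = 1 - (1 + s_each)^k2` and `s2' = 1 - (1 + s_each)^k1` (with
#' `h = 0`), which makes the whole admixture/AOD path checkable against
#' hand arithmetic.
#'
#' @param k1,k2 Number of private fixed deleterious mutations per
#'   population.
#' @param s_each Their common selection coefficient (negative).
#' @param cfg A [sim_config()].
#' @return A `burnin_state` (with summary) ready for [run_replicate()].
#' @export
make_divergent_pair <- function(k1, k2, s_each, cfg = sim_config()) {
  stopifnot(k1 >= 0, k2 >= 0, s_each < 0)
  map <- build_genome_map(cfg)
  catalog <- new_catalog()
  P1 <- founder_population("P1", cfg$N_BI, "B", catalog, map)
  P2 <- founder_population("P2", cfg$N_BI, "A", catalog, map)
  if (k1 + k2 > 0) {
    pos_all <- .supergene_positions(map, k1 + k2, 0.5)
    if (k1 > 0) {
      P1$fixed <- catalog_add(catalog, pos_all[seq_len(k1)],
                              s_each, 0, 1L, 0L)
    }
    if (k2 > 0) {
      P2$fixed <- catalog_add(catalog, pos_all[k1 + seq_len(k2)],
                              s_each, 0, 2L, 0L)
    }
  }
  P1$generation <- cfg$T_BI
  P2$generation <- cfg$T_BI
  state <- list(P1 = P1, P2 = P2, config = cfg,
                burnin_id = sprintf("divergent_%d_%d", k1, k2), seed = NULL,
                summary = NULL)
  class(state) <- "burnin_state"
  state$summary <- summarize_burnin(state)
  state
}
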