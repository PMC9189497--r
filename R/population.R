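# Mutation catalog and population containers.
#
# The catalog is an environment holding parallel vectors indexed directly by
# mutation id (ids are assigned sequentially from 1). It is shared by
# reference between the two burn-in populations so that they use one id
# namespace, as required when fixed differences are re-materialized at
# admixture. Fixture-made mutations use the same machinery.

#' Create an empty mutation catalog
#'
#' @param init Initial capacity (grows by doubling).
#' @return An environment of class `mut_catalog` with fields `pos`, `s`, `h`,
#'   `origin_pop` (1 = P1, 2 = P2, 3 = post-admixture), `origin_gen` and `n`
#'   (number of mutations registered).
#' @export
new_catalog <- function(init = 4096L) {
  cat <- new.env(parent = emptyenv())
  cat$pos <- numeric(init)
  cat$s <- numeric(init)
  cat$h <- numeric(init)
  cat$origin_pop <- integer(init)
  cat$origin_gen <- integer(init)
  cat$n <- 0L
  class(cat) <- "mut_catalog"
  cat
}

#' Register mutations in a catalog
#'
#' @param cat A [new_catalog()] environment.
#' @param pos,s,h Equal-length vectors of positions (bp, may be fractional
#'   under the continuous infinite-sites model), selection coefficients
#'   (signed; negative = deleterious) and dominance coefficients.
#' @param origin_pop Integer code of the population of origin.
#' @param origin_gen Generation of origin.
#' @return Integer vector of the newly assigned mutation ids.
#' @export
catalog_add <- function(cat, pos, s, h, origin_pop, origin_gen) {
  k <- length(pos)
  if (k == 0L) return(integer(0))
  need <- cat$n + k
  if (need > length(cat$pos)) {
    newcap <- max(need, 2L * length(cat$pos))
    cat$pos <- c(cat$pos, numeric(newcap - length(cat$pos)))
    cat$s <- c(cat$s, numeric(newcap - length(cat$s)))
    cat$h <- c(cat$h, numeric(newcap - length(cat$h)))
    cat$origin_pop <- c(cat$origin_pop, integer(newcap - length(cat$origin_pop)))
    cat$origin_gen <- c(cat$origin_gen, integer(newcap - length(cat$origin_gen)))
  }
  ids <- cat$n + seq_len(k)
  cat$pos[ids] <- pos
  cat$s[ids] <- s
  cat$h[ids] <- rep_len(h, k)
  cat$origin_pop[ids] <- rep_len(as.integer(origin_pop), k)
  cat$origin_gen[ids] <- rep_len(as.integer(origin_gen), k)
  cat$n <- cat$n + k
  as.integer(ids)
}

#' Clone a mutation catalog
#'
#' Independent copy sharing no state with the original. Replicates started
#' from a common burn-in state clone its catalog so that de novo mutations
#' of one replicate never accumulate in the shared state (ids stay in the
#' same namespace: clones start from the same `n`).
#'
#' @param cat A catalog.
#' @return A new `mut_catalog` with identical contents.
#' @export
catalog_clone <- function(cat) {
  out <- new.env(parent = emptyenv())
  out$pos <- cat$pos
  out$s <- cat$s
  out$h <- cat$h
  out$origin_pop <- cat$origin_pop
  out$origin_gen <- cat$origin_gen
  out$n <- cat$n
  class(out) <- "mut_catalog"
  out
}

#' Compact a shared catalog to the mutations still referenced
#'
#' Rebuilds the catalog of one or more populations (which must share it),
#' keeping only mutations referenced by a haplotype or a fixed registry, and
#' remaps all ids to the compact sequential namespace. Long runs create many
#' short-lived mutations; without compaction the catalog vectors grow without
#' bound and their copy-on-write traffic dominates runtime. Ids are remapped
#' in increasing order, so within-haplotype ordering is untouched.
#'
#' @param pops List of `sg_pop` objects sharing one catalog.
#' @return The list of populations, rebound to the compact catalog.
#' @export
compact_catalog <- function(pops) {
  catalog <- pops[[1]]$catalog
  ids <- unlist(lapply(pops, function(p) {
    c(unlist(p$haps, use.names = FALSE), p$fixed)
  }), use.names = FALSE)
  ids <- sort(unique(ids))
  newcat <- new_catalog(max(16L, length(ids)))
  if (length(ids)) {
    k <- seq_along(ids)
    newcat$pos[k] <- catalog$pos[ids]
    newcat$s[k] <- catalog$s[ids]
    newcat$h[k] <- catalog$h[ids]
    newcat$origin_pop[k] <- catalog$origin_pop[ids]
    newcat$origin_gen[k] <- catalog$origin_gen[ids]
    newcat$n <- length(ids)
  }
  remap <- integer(catalog$n)
  remap[ids] <- seq_along(ids)
  lapply(pops, function(p) {
    p$haps <- lapply(p$haps, function(h) remap[h])
    p$fixed <- remap[p$fixed]
    p$catalog <- newcat
    p
  })
}

#' Catalog as a data frame
#'
#' @param cat A catalog.
#' @param ids Optional subset of ids (default: all registered mutations).
#' @return A data.frame with columns `id`, `pos`, `s`, `h`, `origin_pop`,
#'   `origin_gen`.
#' @export
catalog_df <- function(cat, ids = seq_len(cat$n)) {
  ids <- as.integer(ids)
  data.frame(id = ids, pos = cat$pos[ids], s = cat$s[ids], h = cat$h[ids],
             origin_pop = cat$origin_pop[ids], origin_gen = cat$origin_gen[ids])
}

#' @export
print.mut_catalog <- function(x, ...) {
  cat(sprintf("<mut_catalog> %d mutations\n", x$n))
  invisible(x)
}

#' Construct a population object
#'
#' A population holds `N` diploid individuals as `2N` haplotypes. Haplotype
#' `2i-1` and `2i` belong to individual `i`. Each haplotype is an integer
#' vector of mutation ids sorted by genomic position, with an arrangement
#' label (0 = standard B, 1 = inverted A).
#'
#' @param label Population label, `"P1"` or `"P2"`.
#' @param haps List of `2N` sorted integer id vectors.
#' @param arr Integer vector of `2N` arrangement labels (0/1).
#' @param catalog Shared [new_catalog()].
#' @param map [build_genome_map()] of the governing config.
#' @param generation Current generation counter.
#' @param fixed Integer vector of mutation ids fixed in this population and
#'   pruned from genotypes.
#' @return An object of class `sg_pop`.
#' @export
new_population <- function(label, haps, arr, catalog, map,
                           generation = 0L, fixed = integer(0)) {
  stopifnot(length(haps) %% 2 == 0, length(arr) == length(haps))
  pop <- list(label = label,
              N = length(haps) %/% 2L,
              haps = haps,
              arr = as.integer(arr),
              catalog = catalog,
              map = map,
              generation = as.integer(generation),
              fixed = as.integer(fixed),
              fitness = NULL)
  class(pop) <- "sg_pop"
  pop$fitness <- population_fitness(pop)
  pop
}

#' Mutation-free monomorphic population
#'
#' @param label Population label.
#' @param N Number of diploid individuals.
#' @param arrangement `"A"` (inverted) or `"B"` (standard); all haplotypes
#'   receive this label.
#' @inheritParams new_population
#' @return An `sg_pop` of `N` identical mutation-free individuals.
#' @export
founder_population <- function(label, N, arrangement, catalog, map) {
  arr <- if (identical(arrangement, "A")) 1L else 0L
  new_population(label,
                 haps = rep(list(integer(0)), 2L * N),
                 arr = rep(arr, 2L * N),
                 catalog = catalog, map = map)
}

#' Individual fitness under multiplicative selection
#'
#' Fitness is relative to a genotype carrying none of the currently
#' segregating mutations: `w = prod(1 + s)` over homozygous mutations times
#' `prod(1 + h*s)` over heterozygous ones. Each factor is floored at 0, so a
#' homozygous mutation with `s <= -1` is unconditionally lethal.
#'
#' @param h1,h2 Sorted integer id vectors (the two haplotypes).
#' @param catalog The mutation catalog.
#' @return A single non-negative fitness value; 1 for a mutation-free
#'   genotype.
#' @export
individual_fitness <- function(h1, h2, catalog) {
  n1 <- length(h1); n2 <- length(h2)
  if (n1 == 0L && n2 == 0L) return(1)
  if (max(h1, h2, 0L) > catalog$n) stop("unknown mutation id", call. = FALSE)
  m <- match(h1, h2, nomatch = 0L)
  hom <- h1[m > 0L]
  het2 <- if (length(hom)) h2[-m[m > 0L]] else h2
  het <- c(h1[m == 0L], het2)
  w <- 1
  if (length(hom)) w <- prod(pmax(0, 1 + catalog$s[hom]))
  if (length(het) && w > 0) {
    w <- w * prod(pmax(0, 1 + catalog$h[het] * catalog$s[het]))
  }
  w
}

#' Fitness of every individual in a population
#'
#' @param pop An `sg_pop`.
#' @return Numeric vector of length `N`.
#' @export
population_fitness <- function(pop) {
  N <- pop$N
  w <- numeric(N)
  for (i in seq_len(N)) {
    w[i] <- individual_fitness(pop$haps[[2L * i - 1L]], pop$haps[[2L * i]],
                               pop$catalog)
  }
  w
}

#' Karyotype of an individual
#'
#' @param a1,a2 Arrangement labels of the two haplotypes (0 = B, 1 = A).
#' @return `"AA"`, `"AB"` or `"BB"` (order-insensitive).
#' @export
karyotype <- function(a1, a2) {
  k <- a1 + a2
  c("BB", "AB", "AA")[k + 1L]
}

#' Karyotypes of all individuals
#'
#' @param pop An `sg_pop`.
#' @return Character vector of length `N` with values `"AA"`, `"AB"`, `"BB"`.
#' @export
population_karyotypes <- function(pop) {
  i1 <- seq(1L, 2L * pop$N, by = 2L)
  karyotype(pop$arr[i1], pop$arr[i1 + 1L])
}

#' Inversion (A arrangement) frequency
#'
#' @param pop An `sg_pop`.
#' @return Frequency of inverted haplotypes among the `2N` haplotypes.
#' @export
inversion_frequency <- function(pop) {
  mean(pop$arr)
}

#' Remove mutations fixed in the population
#'
#' A mutation present on all `2N` haplotypes is removed from every genotype
#' and moved to the population's `fixed` registry; individual fitnesses are
#' rescaled accordingly (relative fitness ratios are unchanged). During the
#' burn-in the registries are per population, so private fixed load remains
#' recoverable at admixture.
#'
#' @param pop An `sg_pop`.
#' @return The updated population.
#' @export
prune_fixed <- function(pop) {
  ids <- unlist(pop$haps, use.names = FALSE)
  if (!length(ids)) return(pop)
  srt <- sort.int(ids, method = "radix")
  r <- rle(srt)
  fixed_now <- r$values[r$lengths == 2L * pop$N]
  if (!length(fixed_now)) return(pop)
  pop$haps <- lapply(pop$haps, function(h) h[!(h %in% fixed_now)])
  pop$fixed <- c(pop$fixed, as.integer(fixed_now))
  pop$fitness <- population_fitness(pop)
  pop
}

#' @export
print.sg_pop <- function(x, ...) {
  k <- table(factor(population_karyotypes(x), levels = c("AA", "AB", "BB")))
  cat(sprintf("<sg_pop %s> N = %d, generation %d, freq(A) = %.3f [AA %d | AB %d | BB %d]\n",
              x$label, x$N, x$generation, inversion_frequency(x),
              k[["AA"]], k[["AB"]], k[["BB"]]))
  cat(sprintf("  segregating ids on haplotypes: %d distinct; fixed registry: %d\n",
              length(unique(unlist(x$haps, use.names = FALSE))), length(x$fixed)))
  invisible(x)
}
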