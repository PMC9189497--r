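# Meiosis with inversion-aware recombination.
#
# A gamete is assembled from the two parental chromatids by a piecewise
# source function over the linear genome: the source chromatid at position x
# is the starting chromatid XOR the parity of the number of recombination
# "toggles" at or below x. Crossover breakpoints are toggles; each
# gene-conversion tract contributes a toggle at its start and one at its
# end, which is exactly the semantics of copying the homologous chromatid's
# content over the tract (a crossover falling inside a tract is handled
# correctly by the same parity rule). The gamete's arrangement label is the
# label of the chromatid carrying the inversion interval after crossover
# resolution only: gene conversion moves allelic content, never the
# arrangement.
#
# The implementation never materializes full breakpoint lists. The source
# function is only ever evaluated at the parental mutation positions plus
# the inversion start (for the label), so per informative interval the
# crossover count parity is drawn directly: an interval of effective length
# d flips the source with probability (1 - exp(-2*rho*d))/2 (Haldane), where
# the effective length excludes the inversion interval for inversion
# heterokaryotypes (crossover suppression) and chromosomes assort
# independently through an obligate 1/2 toggle at the chr1/chr2 boundary.
# This is an exact realization of the Poisson crossover process restricted
# to the sites where it is observable. Gene-conversion initiations are
# likewise thinned to the windows that can reach a mutable segment
# (`gc_win_*` in the genome map); tracts initiating elsewhere cannot touch
# any mutation.

#' Sample crossover breakpoints for one meiosis
#'
#' Breakpoint count is Poisson with mean `rho * L_eff`, where `L_eff`
#' excludes the inversion interval for inversion heterokaryotypes (crossover
#' suppression); positions are uniform on the permitted region. This is the
#' explicit-position view of the crossover process the engine realizes
#' through interval parities; it is exposed for inspection and testing.
#'
#' @param heterokaryotype Logical; is the parent AB at the inversion?
#' @param cfg A [sim_config()].
#' @param map The corresponding [build_genome_map()].
#' @return Numeric vector of breakpoint positions (possibly empty),
#'   unsorted.
#' @export
sample_crossover_breakpoints <- function(heterokaryotype, cfg, map) {
  inv_len <- map$inversion[2] - map$inversion[1]
  if (heterokaryotype) {
    n <- rpois(1L, cfg$rho * (map$L - inv_len))
    if (n == 0L) return(numeric(0))
    u <- runif(n, 0, map$L - inv_len)
    ifelse(u >= map$inversion[1], u + inv_len, u)
  } else {
    n <- rpois(1L, cfg$rho * map$L)
    if (n == 0L) return(numeric(0))
    runif(n, 0, map$L)
  }
}

# Draw de novo mutation positions uniformly over the mutable segments.
.denovo_positions <- function(n, map) {
  if (n == 0L) return(numeric(0))
  u <- runif(n, 0, map$seg_total)
  j <- findInterval(u, c(0, map$seg_cum), rightmost.closed = FALSE,
                    all.inside = TRUE)
  map$seg_start[j] + (u - c(0, map$seg_cum)[j])
}

# Core gamete assembly. h1/h2: sorted id vectors; a1/a2: arrangement
# labels; ngc: pre-drawn count of gene-conversion initiations inside the
# GC windows; dn: de novo ids already registered in the catalog; pos: the
# catalog position vector (fetched once per generation, after all de novo
# registrations); remaining arguments are hoisted map/config constants.
# Returns list(ids, arr).
#
# Informative points are the parental mutation positions plus, for
# inversion heterokaryotypes, the inversion start (the label's anchor); the
# crossover parity chain is realized jointly over all of them, which
# preserves the linkage between the arrangement label and nearby content.
# Merging of the (already sorted) point sets uses findInterval rank
# arithmetic instead of order(); `left.open` breaks the ties that arise at
# homozygous sites present on both haplotypes.
.assemble_gamete <- function(h1, h2, a1, a2, ngc, dn, pos,
                             rho, inv1, inv2, chrb,
                             gws, gwcum, gwtot, lambda) {
  n1 <- length(h1); n2 <- length(h2)
  if (n1 == 0L && n2 == 0L) {
    # no observable content: only the label segregates, Mendelian 1/2
    arr_out <- if (a1 == a2 || runif(1L) < 0.5) a1 else a2
    g <- as.integer(dn)
    if (length(g) > 1L) g <- g[sort.list(pos[g], na.last = NA, method = "quick")]
    return(list(ids = g, arr = arr_out))
  }
  p1 <- pos[h1]; p2 <- pos[h2]
  het <- a1 != a2
  if (n1 && n2) {
    r1 <- seq_len(n1) + findInterval(p1, p2)
    r2 <- seq_len(n2) + findInterval(p2, p1, left.open = TRUE)
  } else if (n1) {
    r1 <- seq_len(n1); r2 <- integer(0)
  } else {
    r2 <- seq_len(n2); r1 <- integer(0)
  }
  if (het) {
    np <- n1 + n2 + 1L
    if (n1) r1 <- r1 + (p1 > inv1)
    if (n2) r2 <- r2 + (p2 > inv1)
    ri <- np - sum(p1 > inv1) - sum(p2 > inv1)
    sp <- numeric(np)
    sp[r1] <- p1; sp[r2] <- p2; sp[ri] <- inv1
    ecum <- sp - pmin(pmax(sp - inv1, 0), inv2 - inv1)
  } else {
    np <- n1 + n2
    sp <- numeric(np)
    sp[r1] <- p1; sp[r2] <- p2
    ecum <- sp
  }
  effs <- ecum - c(0, ecum[-np])
  flips <- runif(np) < 0.5 - 0.5 * exp(-2 * rho * effs)
  par_co <- cumsum(flips) %% 2L
  if (runif(1L) < 0.5) par_co <- (par_co + (sp >= chrb)) %% 2L
  if (ngc > 0L) {
    u <- runif(ngc, 0, gwtot)
    j <- findInterval(u, gwcum, left.open = TRUE) + 1L
    st <- gws[j] + (u - c(0, gwcum)[j])
    tg <- sort.int(c(st, st + rpois(ngc, lambda)), method = "quick")
    par_all <- (par_co + findInterval(sp, tg)) %% 2L
  } else {
    par_all <- par_co
  }
  k0 <- if (runif(1L) < 0.5) 1L else 2L
  arr_out <- if (!het) a1
             else if ((par_co[ri] == 0L) == (k0 == 1L)) a1 else a2
  sel1 <- (par_all[r1] == 0L) == (k0 == 1L)
  sel2 <- (par_all[r2] == 0L) == (k0 == 2L)
  take1 <- h1[sel1]; take2 <- h2[sel2]
  l1 <- length(take1); l2 <- length(take2)
  if (l1 && l2) {
    q1 <- p1[sel1]; q2 <- p2[sel2]
    g <- integer(l1 + l2)
    g[seq_len(l1) + findInterval(q1, q2)] <- take1
    g[seq_len(l2) + findInterval(q2, q1, left.open = TRUE)] <- take2
  } else {
    g <- c(take1, take2)
  }
  if (length(dn)) {
    g <- c(g, dn)
    g <- g[sort.list(pos[g], na.last = NA, method = "quick")]
  }
  list(ids = g, arr = arr_out)
}

#' Perform one meiosis for a parent individual
#'
#' Draws crossover and gene-conversion events, resolves the gamete's
#' arrangement label, and adds de novo mutations (deleterious, and
#' beneficial when `beneficial = TRUE`) registered in the population's
#' catalog.
#'
#' @param pop An `sg_pop`.
#' @param parent Index of the parent individual (1..N).
#' @param cfg A [sim_config()].
#' @param beneficial Whether beneficial mutations can arise (they are off
#'   during the burn-in).
#' @return A list with `ids` (sorted mutation ids of the gamete) and `arr`
#'   (its arrangement label, 0 = B / 1 = A).
#' @export
meiosis <- function(pop, parent, cfg, beneficial = FALSE) {
  map <- pop$map
  rates <- gamete_mutation_rates(cfg, map)
  i1 <- 2L * parent - 1L
  ngc <- rpois(1L, cfg$gamma_gc * map$gc_win_total)
  nd <- rpois(1L, rates$u_del)
  nb <- if (beneficial) rpois(1L, rates$u_ben) else 0L
  gen <- pop$generation + 1L
  opop <- if (isTRUE(pop$post_admixture)) 3L
          else switch(pop$label, P1 = 1L, P2 = 2L, 3L)
  ids <- integer(0)
  if (nd > 0L) {
    ids <- c(ids, catalog_add(pop$catalog, .denovo_positions(nd, map),
                              sample_deleterious_effect(nd, cfg), cfg$h_del,
                              opop, gen))
  }
  if (nb > 0L) {
    ids <- c(ids, catalog_add(pop$catalog, .denovo_positions(nb, map),
                              sample_beneficial_effect(nb, cfg), cfg$h_ben,
                              opop, gen))
  }
  .assemble_gamete(pop$haps[[i1]], pop$haps[[i1 + 1L]],
                   pop$arr[i1], pop$arr[i1 + 1L],
                   ngc, ids, pop$catalog$pos,
                   cfg$rho, map$inversion[1], map$inversion[2],
                   map$chrom_bounds[1L, 2L],
                   map$gc_win_start, map$gc_win_cum, map$gc_win_total,
                   cfg$lambda_gc)
}
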