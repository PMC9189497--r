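# One-generation Wright-Fisher update with multiplicative viability
# selection, implemented with per-generation batching of the Poisson draws
# (crossover, gene-conversion and mutation counts for all meioses at once,
# and a single catalog insertion per generation).

.extinction_error <- function(pop) {
  structure(class = c("sg_extinction", "error", "condition"),
            list(message = sprintf(
              "population %s extinct at generation %d: all fitnesses are zero",
              pop$label, pop$generation), call = NULL))
}

# Strip fixed ids from haplotypes without touching fitness (caller
# recomputes once afterwards). Returns list(haps, fixed_added).
.strip_fixed <- function(haps, n_hap) {
  ids <- unlist(haps, use.names = FALSE)
  if (!length(ids)) return(list(haps = haps, fixed_added = integer(0)))
  r <- rle(sort.int(ids, method = "radix"))
  fixed_now <- r$values[r$lengths == n_hap]
  if (!length(fixed_now)) return(list(haps = haps, fixed_added = integer(0)))
  list(haps = lapply(haps, function(h) h[!(h %in% fixed_now)]),
       fixed_added = as.integer(fixed_now))
}

#' Advance a population by one Wright-Fisher generation
#'
#' `N_next` offspring are produced, each from two parents drawn
#' independently with probability proportional to fitness (selfing permitted
#' unless `cfg$allow_selfing` is `FALSE`), with one meiosis per parent.
#' Mutations that reach fixation among the offspring are pruned into the
#' population's fixed registry, the generation counter is incremented and
#' fitnesses are recomputed.
#'
#' @param pop An `sg_pop` with at least one individual of positive fitness.
#' @param N_next Offspring population size (defaults to the current size).
#' @param cfg A [sim_config()].
#' @param beneficial Whether beneficial mutations can arise this generation.
#' @param engine `"cpp"` (default, compiled core) or `"R"` (the reference
#'   implementation). Both draw from R's RNG and realize the same process;
#'   the compiled core is ~100x faster and is what the simulation drivers
#'   use.
#' @return The next-generation `sg_pop`.
#' @export
next_generation <- function(pop, N_next = pop$N, cfg, beneficial = FALSE,
                            engine = getOption("aodsim.engine", "cpp")) {
  if (identical(engine, "cpp")) {
    return(.next_generation_cpp(pop, N_next, cfg, beneficial))
  }
  w <- pop$fitness
  if (all(w <= 0)) stop(.extinction_error(pop))
  N_next <- as.integer(N_next)
  M <- 2L * N_next
  parents <- sample.int(pop$N, M, replace = TRUE, prob = w)
  if (!cfg$allow_selfing && pop$N > 1L && sum(w > 0) > 1L) {
    p1 <- parents[seq(1L, M, by = 2L)]
    p2 <- parents[seq(2L, M, by = 2L)]
    bad <- which(p1 == p2)
    while (length(bad)) {
      p2[bad] <- sample.int(pop$N, length(bad), replace = TRUE, prob = w)
      bad <- bad[p2[bad] == p1[bad]]
    }
    parents[seq(2L, M, by = 2L)] <- p2
  }
  map <- pop$map
  catalog <- pop$catalog
  rates <- gamete_mutation_rates(cfg, map)
  ngc_v <- rpois(M, cfg$gamma_gc * map$gc_win_total)
  nd_v <- rpois(M, rates$u_del)
  nb_v <- if (beneficial && rates$u_ben > 0) rpois(M, rates$u_ben)
          else integer(M)
  gen <- pop$generation + 1L
  opop <- if (isTRUE(pop$post_admixture)) 3L
          else switch(pop$label, P1 = 1L, P2 = 2L, 3L)
  nd_tot <- sum(nd_v); nb_tot <- sum(nb_v)
  del_ids <- if (nd_tot) {
    catalog_add(catalog, .denovo_positions(nd_tot, map),
                sample_deleterious_effect(nd_tot, cfg), cfg$h_del, opop, gen)
  } else integer(0)
  ben_ids <- if (nb_tot) {
    catalog_add(catalog, .denovo_positions(nb_tot, map),
                sample_beneficial_effect(nb_tot, cfg), cfg$h_ben, opop, gen)
  } else integer(0)
  del_off <- c(0L, cumsum(nd_v))
  ben_off <- c(0L, cumsum(nb_v))
  haps_new <- vector("list", M)
  arr_new <- integer(M)
  pos <- catalog$pos
  haps <- pop$haps
  arr <- pop$arr
  rho <- cfg$rho
  inv1 <- map$inversion[1]; inv2 <- map$inversion[2]
  chrb <- map$chrom_bounds[1L, 2L]
  gws <- map$gc_win_start; gwcum <- map$gc_win_cum
  gwtot <- map$gc_win_total; lambda <- cfg$lambda_gc
  for (j in seq_len(M)) {
    jj <- 2L * parents[j] - 1L
    dn <- c(if (nd_v[j]) del_ids[(del_off[j] + 1L):del_off[j + 1L]],
            if (nb_v[j]) ben_ids[(ben_off[j] + 1L):ben_off[j + 1L]])
    g <- .assemble_gamete(haps[[jj]], haps[[jj + 1L]], arr[jj], arr[jj + 1L],
                          ngc_v[j], dn, pos, rho, inv1, inv2, chrb,
                          gws, gwcum, gwtot, lambda)
    haps_new[[j]] <- g$ids
    arr_new[j] <- g$arr
  }
  st <- .strip_fixed(haps_new, M)
  out <- pop
  out$N <- N_next
  out$haps <- st$haps
  out$arr <- arr_new
  out$generation <- gen
  out$fixed <- c(pop$fixed, st$fixed_added)
  out$fitness <- population_fitness(out)
  out
}

# Compiled-engine path: one C++ call per generation; de novo mutations are
# created inside the call with ids following the catalog, then registered.
.next_generation_cpp <- function(pop, N_next, cfg, beneficial) {
  w <- pop$fitness
  if (all(w <= 0)) stop(.extinction_error(pop))
  map <- pop$map
  catalog <- pop$catalog
  rates <- gamete_mutation_rates(cfg, map)
  res <- .cpp_next_generation(
    pop$haps, pop$arr, w, as.integer(N_next),
    cfg$rho, map$inversion[1], map$inversion[2], map$chrom_bounds[1L, 2L],
    map$gc_win_start, map$gc_win_cum, map$gc_win_total,
    cfg$lambda_gc, cfg$gamma_gc * map$gc_win_total,
    rates$u_del, if (beneficial) rates$u_ben else 0,
    cfg$h_del, cfg$h_ben, cfg$s_scale, cfg$alpha_gamma, cfg$beta_gamma,
    cfg$kappa_exp, catalog$pos, catalog$s, catalog$h, catalog$n,
    map$seg_start, map$seg_cum, map$seg_total, cfg$allow_selfing)
  gen <- pop$generation + 1L
  if (length(res$new_pos)) {
    opop <- if (isTRUE(pop$post_admixture)) 3L
            else switch(pop$label, P1 = 1L, P2 = 2L, 3L)
    catalog_add(catalog, res$new_pos, res$new_s, res$new_h, opop, gen)
  }
  out <- pop
  out$N <- as.integer(N_next)
  out$haps <- res$haps
  out$arr <- res$arr
  out$generation <- gen
  out$fixed <- c(pop$fixed, res$fixed)
  out$fitness <- res$fitness
  out
}

#' Evolve a population for several generations
#'
#' Repeatedly applies [next_generation()] at constant size.
#'
#' @inheritParams next_generation
#' @param generations Number of generations to run.
#' @return The evolved `sg_pop`.
#' @export
evolve <- function(pop, generations, cfg, beneficial = FALSE) {
  for (g in seq_len(generations)) {
    pop <- next_generation(pop, pop$N, cfg, beneficial)
  }
  pop
}
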