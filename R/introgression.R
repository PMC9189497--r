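# Stage 2: bottleneck, single-migrant admixture and the post-admixture fate
# of the inversion polymorphism. The focal population is P1 throughout; P2
# is only the source of the one migrant.

#' Reduce a population to its post-admixture size
#'
#' `N_post` individuals are sampled uniformly without replacement. The
#' bottleneck precedes migration, so the migrant cannot be discarded by it.
#'
#' @param pop An `sg_pop` (P1 at burn-in end).
#' @param N_post Target size, at most the current size.
#' @return The bottlenecked `sg_pop`.
#' @export
bottleneck <- function(pop, N_post) {
  N_post <- as.integer(N_post)
  if (N_post > pop$N) stop("N_post exceeds the current population size",
                           call. = FALSE)
  if (N_post == pop$N) return(pop)
  keep <- sample.int(pop$N, N_post)
  hap_idx <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  out <- pop
  out$N <- N_post
  out$haps <- pop$haps[hap_idx]
  out$arr <- pop$arr[hap_idx]
  out$fitness <- pop$fitness[keep]
  out
}

#' Single-migrant admixture
#'
#' One uniformly chosen P2 individual replaces one uniformly chosen resident
#' of (bottlenecked) P1, so the population size is conserved and the
#' inverted arrangement enters at frequency `1/N`. Mutations fixed privately
#' in either population are re-materialized as segregating sites in the
#' merged context: every resident haplotype receives P1's private fixed
#' mutations, the migrant's haplotypes receive P2's, and mutations fixed in
#' both populations stay pruned (they are invisible to relative fitness).
#' The merged population starts at generation 1, the migration generation.
#'
#' @param P1 The bottlenecked focal population.
#' @param P2 The donor population (burn-in end).
#' @return The admixed `sg_pop` (label `"P1"`, `post_admixture = TRUE`).
#' @export
admix <- function(P1, P2) {
  catalog <- P1$catalog
  p1_priv <- setdiff(P1$fixed, P2$fixed)
  p2_priv <- setdiff(P2$fixed, P1$fixed)
  shared <- intersect(P1$fixed, P2$fixed)
  inject <- function(h, priv) {
    if (!length(priv)) return(h)
    h2 <- c(h, priv)
    h2[order(catalog$pos[h2])]
  }
  haps <- lapply(P1$haps, inject, priv = p1_priv)
  arr <- P1$arr
  migrant <- sample.int(P2$N, 1L)
  resident <- sample.int(P1$N, 1L)
  mi <- c(2L * migrant - 1L, 2L * migrant)
  ri <- c(2L * resident - 1L, 2L * resident)
  haps[ri] <- lapply(P2$haps[mi], inject, priv = p2_priv)
  arr[ri] <- P2$arr[mi]
  pop <- new_population("P1", haps, arr, catalog, P1$map,
                        generation = 1L, fixed = as.integer(shared))
  pop$post_admixture <- TRUE
  pop
}

# One time-series record: realized and expected-pairing karyotype fitness,
# AOD, mean fitness and per-arrangement supergene mutation counts.
.ts_record <- function(pop) {
  ks <- karyotype_fitness_summary(pop)
  aod <- compute_aod(ks)
  ek <- expected_karyotype_fitness(pop)
  aod_e <- compute_aod(ek)
  mpa <- mutations_per_arrangement(pop, "supergene")
  data.frame(generation = pop$generation,
             freq_A = inversion_frequency(pop),
             W_AA = ks$W_AA, W_AB = ks$W_AB, W_BB = ks$W_BB,
             n_AA = ks$n_AA, n_AB = ks$n_AB, n_BB = ks$n_BB,
             s1p = aod$s1p, s2p = aod$s2p, sp = aod$sp,
             symmetry = aod$symmetry,
             s1p_exp = aod_e$s1p, s2p_exp = aod_e$s2p, sp_exp = aod_e$sp,
             symmetry_exp = aod_e$symmetry,
             mean_fitness = mean(pop$fitness),
             n_mut_A = mpa$n_mut_A, n_mut_B = mpa$n_mut_B)
}

#' Run the post-admixture phase of one replicate
#'
#' Iterates Wright-Fisher generations (beneficial mutations enabled unless
#' `beneficial = FALSE`) until the inverted arrangement fixes or is lost,
#' the population goes extinct, or the generation cap `cfg$T_max` is
#' reached. Time-series records are collected at `cfg$sample_grid`
#' generations and outcome classification is applied at `cfg$checkpoints`
#' while the population is still polymorphic.
#'
#' @param pop The admixed population from [admix()] (generation 1).
#' @param cfg A [sim_config()]; `cfg$N_post` is the constant size and also
#'   the invasion horizon (present after `N` generations = invasion).
#' @param beneficial Whether beneficial mutations occur post-admixture.
#' @param replicate_id,burnin_id,seed Identifiers stored in the result;
#'   `seed`, when non-NULL, is set before the first random draw.
#' @param keep_population If `TRUE` the final population is kept in the
#'   result (`$final_pop`).
#' @param record_timeseries If `FALSE`, skip the per-gridpoint statistics
#'   (karyotype/AOD records); status, invasion and checkpoint outcomes are
#'   still collected. Use for mass replicate production where only outcomes
#'   matter.
#' @return An object of class `replicate_result`: list with `status`
#'   (`"LOST"`, `"FIXED"`, `"POLYMORPHIC_AT_TMAX"`, `"EXTINCT"`),
#'   `end_generation`, `invasion`, `freq_at_N`, `timeseries` (data.frame),
#'   `outcome_at` (named character vector per checkpoint) and ids.
#' @export
run_post_admixture <- function(pop, cfg, beneficial = TRUE,
                               replicate_id = "rep", burnin_id = NA_character_,
                               seed = NULL, keep_population = FALSE,
                               record_timeseries = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  grid <- if (record_timeseries) cfg$sample_grid else numeric(0)
  checkpoints <- cfg$checkpoints
  ts <- vector("list", length(grid) + 1L)
  nts <- 0L
  if (pop$generation %in% grid) {
    nts <- nts + 1L; ts[[nts]] <- .ts_record(pop)
  }
  outcome_at <- stats::setNames(rep(NA_character_, length(checkpoints)),
                                as.character(checkpoints))
  status <- NA_character_
  invasion <- NA
  freq_at_N <- NA_real_
  repeat {
    if (pop$generation >= cfg$T_max) { status <- "POLYMORPHIC_AT_TMAX"; break }
    pop <- tryCatch(next_generation(pop, cfg$N_post, cfg, beneficial),
                    sg_extinction = function(e) e)
    if (inherits(pop, "sg_extinction")) { status <- "EXTINCT"; break }
    f <- inversion_frequency(pop)
    g <- pop$generation
    if (g == cfg$N_post) { invasion <- f > 0; freq_at_N <- f }
    if (f == 0 || f == 1) {
      if (is.na(invasion)) { invasion <- f == 1; freq_at_N <- f }
      status <- if (f == 0) "LOST" else "FIXED"
      break
    }
    if (g %in% grid) { nts <- nts + 1L; ts[[nts]] <- .ts_record(pop) }
    if (g %in% checkpoints) {
      outcome_at[as.character(g)] <- classify_outcome(pop, cfg$viability_threshold)
    }
  }
  if (identical(status, "POLYMORPHIC_AT_TMAX") && is.na(invasion)) {
    # T_max shorter than the invasion horizon: still present, so invaded
    invasion <- TRUE
    freq_at_N <- inversion_frequency(pop)
  }
  end_gen <- if (inherits(pop, "sg_extinction")) NA_integer_ else pop$generation
  res <- list(replicate_id = replicate_id, burnin_id = burnin_id, seed = seed,
              status = status, end_generation = end_gen,
              invasion = invasion, freq_at_N = freq_at_N,
              timeseries = if (nts) do.call(rbind, ts[seq_len(nts)]) else NULL,
              outcome_at = outcome_at)
  if (keep_population && !inherits(pop, "sg_extinction")) res$final_pop <- pop
  class(res) <- "replicate_result"
  res
}

#' Did the inverted arrangement invade?
#'
#' Invasion is defined as the inverted arrangement still being present in
#' the focal population `N` generations after the migration event.
#'
#' @param result A `replicate_result`.
#' @param N_post The invasion horizon (defaults to the recorded one).
#' @return Logical.
#' @export
invasion_success <- function(result, N_post = NULL) {
  if (is.null(N_post)) return(isTRUE(result$invasion))
  if (identical(result$status, "EXTINCT")) return(NA)
  if (result$end_generation <= N_post) {
    return(switch(result$status, FIXED = TRUE, LOST = FALSE,
                  POLYMORPHIC_AT_TMAX = TRUE, NA))
  }
  # ran beyond N generations, so it was present at generation N
  TRUE
}

#' Run one full replicate from a burn-in state
#'
#' Convenience wrapper: bottleneck P1 to `cfg$N_post`, admix one migrant
#' from P2 and run the post-admixture phase.
#'
#' @param state A `burnin_state`.
#' @param cfg Config for the post-admixture phase (defaults to the state's
#'   config).
#' @inheritParams run_post_admixture
#' @return A `replicate_result`.
#' @export
run_replicate <- function(state, cfg = state$config, beneficial = TRUE,
                          replicate_id = "rep", seed = NULL,
                          keep_population = FALSE, record_timeseries = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  pop <- bottleneck(state$P1, cfg$N_post)
  # isolate this replicate's mutations from the shared burn-in catalog
  pop$catalog <- catalog_clone(state$P1$catalog)
  pop <- admix(pop, state$P2)
  run_post_admixture(pop, cfg, beneficial = beneficial,
                     replicate_id = replicate_id, burnin_id = state$burnin_id,
                     seed = NULL, keep_population = keep_population,
                     record_timeseries = record_timeseries)
}

#' Flatten replicate time series to one table
#'
#' @param results List of `replicate_result` objects.
#' @return Data.frame with a `replicate_id` column prepended to the
#'   concatenated per-replicate time series.
#' @export
results_timeseries <- function(results) {
  keep <- !vapply(results, function(r) is.null(r$timeseries), logical(1))
  do.call(rbind, lapply(results[keep], function(r) {
    cbind(replicate_id = r$replicate_id, burnin_id = r$burnin_id,
          r$timeseries)
  }))
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("<replicate_result %s> %s at generation %s (invasion: %s)\n",
              x$replicate_id, x$status, x$end_generation,
              x$invasion))
  invisible(x)
}
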