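# Stage 1: divergence burn-in. Two isolated Wright-Fisher populations
# accumulate deleterious mutations (no beneficials pre-admixture); drift
# fixes a private subset in each, generating drift load and fixed
# differences. P2 carries the inverted arrangement (A), P1 the standard (B);
# the labels are inert while each population is monomorphic.

#' Run a divergence burn-in
#'
#' Evolves P1 (standard arrangement) and P2 (inverted arrangement), each of
#' size `N_BI`, independently for `T_BI` generations from mutation-free
#' founders, sharing one mutation-id namespace. Beneficial mutations are
#' disabled. The state summary records the supergene-region load
#' decomposition of both populations and the fixed-difference count.
#'
#' @param cfg A [sim_config()]; at full scale this takes cluster time, so
#'   rescale with [rescale_config()] for interactive use.
#' @param seed Optional integer seed (set before any random draw).
#' @param burnin_id Identifier stored with the state.
#' @return An object of class `burnin_state`: list with `P1`, `P2`,
#'   `config`, `burnin_id`, `seed`, `summary`.
#' @export
run_burnin <- function(cfg, seed = NULL, burnin_id = "burnin") {
  validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  map <- build_genome_map(cfg)
  catalog <- new_catalog()
  P1 <- founder_population("P1", cfg$N_BI, "B", catalog, map)
  P2 <- founder_population("P2", cfg$N_BI, "A", catalog, map)
  for (g in seq_len(cfg$T_BI)) {
    P1 <- next_generation(P1, cfg$N_BI, cfg, beneficial = FALSE)
    P2 <- next_generation(P2, cfg$N_BI, cfg, beneficial = FALSE)
    if (g %% 500L == 0L) {
      both <- compact_catalog(list(P1, P2))
      P1 <- both[[1]]; P2 <- both[[2]]
    }
  }
  both <- compact_catalog(list(P1, P2))
  P1 <- both[[1]]; P2 <- both[[2]]
  state <- list(P1 = P1, P2 = P2, config = cfg,
                burnin_id = burnin_id, seed = seed, summary = NULL)
  class(state) <- "burnin_state"
  state$summary <- summarize_burnin(state)
  state
}

#' Summarize a burn-in state
#'
#' @param state A `burnin_state`.
#' @return List with the fixed-difference count, per-population fixed and
#'   segregating mutation counts, and the supergene-region load
#'   decomposition of each population (see [compute_loads()]).
#' @export
summarize_burnin <- function(state) {
  seg1 <- unique(unlist(state$P1$haps, use.names = FALSE))
  seg2 <- unique(unlist(state$P2$haps, use.names = FALSE))
  list(fixed_diff = count_fixed_differences(state),
       n_fixed_P1 = length(state$P1$fixed),
       n_fixed_P2 = length(state$P2$fixed),
       n_seg_P1 = length(seg1),
       n_seg_P2 = length(seg2),
       loads_P1 = compute_loads(state$P1, state$P2, "supergene"),
       loads_P2 = compute_loads(state$P2, state$P1, "supergene"))
}

#' Count fixed differences between the two burn-in populations
#'
#' The number of mutations present in exactly one population's fixed
#' registry (privately fixed).
#'
#' @param state A `burnin_state`.
#' @return Integer count.
#' @export
count_fixed_differences <- function(state) {
  length(setdiff(state$P1$fixed, state$P2$fixed)) +
    length(setdiff(state$P2$fixed, state$P1$fixed))
}

#' Generate a bank of independent burn-ins
#'
#' Replicate banks reuse burn-in states across post-admixture replicates, so
#' stochastic variation among burn-ins (which can eclipse parameter effects)
#' is measurable. Per-burn-in seeds are derived deterministically from
#' `seed`.
#'
#' @param cfg A [sim_config()].
#' @param n_burnins Number of independent burn-ins.
#' @param seed Root seed for the bank.
#' @param out_dir Optional directory; when given, each state is persisted
#'   via [write_burnin_state()] under `burnin_<k>/` together with a
#'   `manifest.tsv` (burnin_id, seed, fixed counts, fixed differences,
#'   drift fractions).
#' @return List of `burnin_state` objects (invisibly carries the manifest as
#'   attribute `"manifest"`).
#' @export
make_burnin_bank <- function(cfg, n_burnins, seed = 1L, out_dir = NULL) {
  stopifnot(n_burnins >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_burnins)
  bank <- vector("list", n_burnins)
  for (k in seq_len(n_burnins)) {
    bank[[k]] <- run_burnin(cfg, seed = seeds[k],
                            burnin_id = sprintf("burnin_%03d", k))
  }
  manifest <- data.frame(
    burnin_id = vapply(bank, function(s) s$burnin_id, character(1)),
    seed = seeds,
    fixed_P1 = vapply(bank, function(s) s$summary$n_fixed_P1, numeric(1)),
    fixed_P2 = vapply(bank, function(s) s$summary$n_fixed_P2, numeric(1)),
    fixed_diff = vapply(bank, function(s) s$summary$fixed_diff, numeric(1)),
    drift_fraction_P1 = vapply(bank, function(s)
      s$summary$loads_P1$drift_fraction, numeric(1)),
    drift_fraction_P2 = vapply(bank, function(s)
      s$summary$loads_P2$drift_fraction, numeric(1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n_burnins)) {
      write_burnin_state(bank[[k]], file.path(out_dir, bank[[k]]$burnin_id))
    }
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  attr(bank, "manifest") <- manifest
  bank
}

#' @export
print.burnin_state <- function(x, ...) {
  cat(sprintf("<burnin_state %s> T_BI = %d, N_BI = %d, fixed diffs = %d\n",
              x$burnin_id, x$config$T_BI, x$config$N_BI, x$summary$fixed_diff))
  invisible(x)
}
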