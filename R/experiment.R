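# Orchestration of the full block design: burn-in banks per burn-in cell
# (dominance x divergence time), post-admixture cells (gene conversion x
# population size), deterministic seed derivation, and aggregation into
# outcome tables, persistence (transition) tables and the balanced-lethal
# probability curve.

# Counter-based seed splitting (Lehmer step on a 31-bit state): every
# (root, index...) tuple maps to a reproducible seed independent of the
# global RNG state.
.derive_seed <- function(root, ...) {
  m <- 2147483647
  state <- (as.numeric(root) %% m) + 1
  for (i in c(...)) {
    state <- (state * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(state %% (m - 2) + 1)
}

#' Remove gene conversion at constant total recombination rate
#'
#' All recombination events become crossovers: the gene-conversion
#' initiation rate is folded into the crossover rate (`rho' = rho + gamma`,
#' `gamma' = 0`), so the total rate `r` outside the supergene is unchanged.
#' Inside the supergene of heterokaryotypes this removes all gene flux.
#'
#' @param cfg A [sim_config()].
#' @return The transformed config (idempotent when `gamma_gc` is 0).
#' @export
gc_off_transform <- function(cfg) {
  out <- cfg
  out$rho <- cfg$rho + cfg$gamma_gc
  out$gamma_gc <- 0
  out
}

#' Define a block design
#'
#' Crosses post-admixture factors (gene conversion on/off, population size)
#' with burn-in factors (dominance coefficient, burn-in length). By default
#' cells with intermediate population sizes are restricted to `h = 0`,
#' GC off — the only conditions under which they are informative for the
#' balanced-lethal size sweep.
#'
#' @param base_cfg Base [sim_config()] carrying everything not varied.
#' @param N_post Population sizes to cross.
#' @param gc Logical vector: gene conversion present / absent.
#' @param h_del Dominance coefficients to cross.
#' @param T_BI Burn-in lengths to cross.
#' @param n_burnins Burn-ins per burn-in cell.
#' @param n_replicates Replicates per burn-in per cell.
#' @param restrict_intermediate_N If `TRUE`, sizes other than
#'   `min(N_post)`/`max(N_post)` appear only with `h = 0`, GC off.
#' @return An object of class `block_design`: list with `cells`
#'   (data.frame), `base_cfg`, `n_burnins`, `n_replicates`.
#' @export
block_design <- function(base_cfg, N_post, gc = c(TRUE, FALSE),
                         h_del = c(0, 0.1), T_BI = base_cfg$T_BI,
                         n_burnins = 2L, n_replicates = 50L,
                         restrict_intermediate_N = TRUE) {
  cells <- expand.grid(N_post = N_post, gc = gc, h_del = h_del, T_BI = T_BI,
                       KEEP.OUT.ATTRS = FALSE)
  if (restrict_intermediate_N && length(N_post) > 2) {
    mid <- !(cells$N_post %in% range(N_post))
    cells <- cells[!mid | (cells$h_del == 0 & !cells$gc), , drop = FALSE]
  }
  rownames(cells) <- NULL
  cells$cell_id <- sprintf("N%d_gc%d_h%g_T%d", cells$N_post, cells$gc,
                           cells$h_del, cells$T_BI)
  out <- list(cells = cells, base_cfg = base_cfg,
              n_burnins = as.integer(n_burnins),
              n_replicates = as.integer(n_replicates))
  class(out) <- "block_design"
  out
}

# Burn-in cell key: burn-ins depend only on (h_del, T_BI).
.burnin_key <- function(h_del, T_BI) sprintf("h%g_T%d", h_del, T_BI)

#' Generate the burn-in bank for a design
#'
#' One bank of `n_burnins` burn-ins per distinct (dominance, burn-in
#' length) combination, with seeds derived from `seed`.
#'
#' @param design A [block_design()].
#' @param seed Root seed.
#' @return Named list of burn-in banks keyed by burn-in cell.
#' @export
make_design_bank <- function(design, seed = 1L) {
  combos <- unique(design$cells[, c("h_del", "T_BI")])
  bank <- list()
  for (r in seq_len(nrow(combos))) {
    cfg <- design$base_cfg
    cfg$h_del <- combos$h_del[r]
    cfg$T_BI <- as.integer(combos$T_BI[r])
    key <- .burnin_key(cfg$h_del, cfg$T_BI)
    bank[[key]] <- lapply(seq_len(design$n_burnins), function(k) {
      run_burnin(cfg, seed = .derive_seed(seed, r, k),
                 burnin_id = sprintf("%s_b%02d", key, k))
    })
  }
  bank
}

#' Execute a block design
#'
#' Runs `n_replicates` post-admixture replicates per burn-in per cell, with
#' per-replicate seeds split deterministically from `seed`, and aggregates
#' the outcome table. The whole block is reproducible bit for bit from
#' (`design`, `bank`, `seed`).
#'
#' @param design A [block_design()].
#' @param bank A bank from [make_design_bank()] covering all burn-in cells.
#' @param seed Root seed for replicate-level randomness.
#' @param beneficial Whether beneficial mutations occur post-admixture.
#' @param record_timeseries Whether each replicate collects the full
#'   per-gridpoint statistics (off by default: the block aggregates outcomes,
#'   and skipping the records makes large replicate counts cheap).
#' @return Object of class `block_result`: list with `replicates` (one row
#'   per replicate: cell, burn-in, status, invasion, outcomes at
#'   checkpoints), `outcome_table` (per-cell counts, see
#'   [outcome_table()]), `design`, `seed`.
#' @export
run_block <- function(design, bank, seed = 1L, beneficial = TRUE,
                      record_timeseries = FALSE) {
  cells <- design$cells
  need <- unique(.burnin_key(cells$h_del, cells$T_BI))
  missing <- setdiff(need, names(bank))
  if (length(missing)) {
    stop("burn-in bank is missing cells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    key <- .burnin_key(cell$h_del, cell$T_BI)
    cfg <- design$base_cfg
    cfg$h_del <- cell$h_del
    cfg$T_BI <- as.integer(cell$T_BI)
    cfg$N_post <- as.integer(cell$N_post)
    if (!cell$gc) cfg <- gc_off_transform(cfg)
    for (bi in seq_along(bank[[key]])) {
      state <- bank[[key]][[bi]]
      for (ri in seq_len(design$n_replicates)) {
        res <- run_replicate(state, cfg, beneficial = beneficial,
                             replicate_id = sprintf("%s_b%02d_r%04d",
                                                    cell$cell_id, bi, ri),
                             seed = .derive_seed(seed, ci, bi, ri),
                             record_timeseries = record_timeseries)
        oc <- res$outcome_at
        row <- data.frame(cell_id = cell$cell_id, N_post = cell$N_post,
                          gc = cell$gc, h_del = cell$h_del, T_BI = cell$T_BI,
                          burnin_id = state$burnin_id,
                          replicate_id = res$replicate_id,
                          status = res$status,
                          end_generation = res$end_generation,
                          invasion = res$invasion)
        for (cp in names(oc)) row[[paste0("outcome_", cp)]] <- oc[[cp]]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  replicates <- do.call(rbind, rows)
  out <- list(replicates = replicates,
              outcome_table = outcome_table(replicates),
              design = design, seed = seed)
  class(out) <- "block_result"
  out
}

#' Aggregate replicate rows into a per-cell outcome table
#'
#' @param replicates The `replicates` data.frame of a [run_block()] result.
#' @return Data.frame, one row per cell: replicate count, counts of each
#'   terminal status, counts of each outcome class at the final checkpoint,
#'   and the invasion rate.
#' @export
outcome_table <- function(replicates) {
  oc_cols <- grep("^outcome_", names(replicates), value = TRUE)
  final_oc <- if (length(oc_cols)) oc_cols[length(oc_cols)] else NULL
  by_cell <- split(replicates, replicates$cell_id)
  out <- do.call(rbind, lapply(by_cell, function(d) {
    data.frame(cell_id = d$cell_id[1], N_post = d$N_post[1], gc = d$gc[1],
               h_del = d$h_del[1], T_BI = d$T_BI[1],
               n = nrow(d),
               n_lost = sum(d$status == "LOST"),
               n_fixed = sum(d$status == "FIXED"),
               n_extinct = sum(d$status == "EXTINCT"),
               n_poly = sum(d$status == "POLYMORPHIC_AT_TMAX"),
               n_poly_viable = if (is.null(final_oc)) NA_integer_ else
                 sum(d[[final_oc]] == "POLY_BOTH_VIABLE", na.rm = TRUE),
               n_half_lethal = if (is.null(final_oc)) NA_integer_ else
                 sum(d[[final_oc]] == "HALF_LETHAL", na.rm = TRUE),
               n_balanced_lethal = if (is.null(final_oc)) NA_integer_ else
                 sum(d[[final_oc]] == "BALANCED_LETHAL", na.rm = TRUE),
               invasion_rate = mean(d$invasion, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out[order(out$cell_id), , drop = FALSE]
}

#' Balanced-lethal probability as a function of population size
#'
#' For each burn-in and population size: the probability that a replicate
#' that invaded is classified `BALANCED_LETHAL` at the final checkpoint.
#' Cells without any invasion yield `NA`, not 0.
#'
#' @param replicates Replicate rows from [run_block()] (typically the
#'   `h = 0`, GC-off cells).
#' @return Data.frame with `N_post`, `burnin_id`, `n_invaded`,
#'   `p_balanced_lethal`.
#' @export
balanced_lethal_probability_vs_N <- function(replicates) {
  oc_cols <- grep("^outcome_", names(replicates), value = TRUE)
  final_oc <- oc_cols[length(oc_cols)]
  grp <- interaction(replicates$N_post, replicates$burnin_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(replicates, grp), function(d) {
    inv <- d[isTRUE_vec(d$invasion), , drop = FALSE]
    oc <- inv[[final_oc]]
    data.frame(N_post = d$N_post[1], burnin_id = d$burnin_id[1],
               n_invaded = nrow(inv),
               p_balanced_lethal = if (nrow(inv) == 0) NA_real_ else
                 mean(!is.na(oc) & oc == "BALANCED_LETHAL"))
  }))
  rownames(out) <- NULL
  out[order(out$N_post, out$burnin_id), , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Outcome persistence between checkpoints
#'
#' For each consecutive checkpoint pair and each outcome class at the
#' earlier checkpoint: the fractions of those replicates found in each class
#' (or terminal status, for replicates that ended in between) at the later
#' checkpoint.
#'
#' @param replicates Replicate rows from [run_block()].
#' @param checkpoints Checkpoint generations (must match the
#'   `outcome_<g>` columns present).
#' @return Data.frame with `from_gen`, `to_gen`, `from_class`, `to_class`,
#'   `n`, `fraction` (of the `from_class` row).
#' @export
outcome_persistence <- function(replicates, checkpoints) {
  checkpoints <- sort(checkpoints)
  rows <- list()
  for (i in seq_len(length(checkpoints) - 1L)) {
    c1 <- checkpoints[i]; c2 <- checkpoints[i + 1L]
    col1 <- paste0("outcome_", c1); col2 <- paste0("outcome_", c2)
    d <- replicates[!is.na(replicates[[col1]]), , drop = FALSE]
    if (!nrow(d)) next
    to_class <- ifelse(!is.na(d[[col2]]), d[[col2]], d$status)
    for (fc in unique(d[[col1]])) {
      sel <- d[[col1]] == fc
      tab <- table(to_class[sel])
      for (tc in names(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          from_gen = c1, to_gen = c2, from_class = fc, to_class = tc,
          n = as.integer(tab[[tc]]), fraction = tab[[tc]] / sum(sel))
      }
    }
  }
  if (!length(rows)) return(data.frame(from_gen = numeric(0),
                                       to_gen = numeric(0),
                                       from_class = character(0),
                                       to_class = character(0),
                                       n = integer(0), fraction = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.block_result <- function(x, ...) {
  cat(sprintf("<block_result> %d replicates over %d cells (root seed %s)\n",
              nrow(x$replicates), nrow(x$design$cells), x$seed))
  print(x$outcome_table)
  invisible(x)
}
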