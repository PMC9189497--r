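# Shared helpers: small configs and hand-built populations used across the
# unit tests. Everything is generated in code; nothing is read from disk.

# Desk-scale config: the study conditions accelerated 100-fold
# (N_BI = 25, T_BI = 2000), used where a test needs evolution to happen in
# seconds.
desk_config <- function(...) {
  rescale_config(sim_config(...), 100)
}

# A two-individual population with explicit haplotypes, for fitness and
# meiosis micro-tests. muts: data.frame(pos, s, h); hap_assign: list of 4
# integer vectors of row indices into muts; arr: 4 arrangement labels.
tiny_population <- function(muts, hap_assign, arr, cfg = sim_config()) {
  map <- build_genome_map(cfg)
  catalog <- new_catalog()
  ids <- if (nrow(muts)) {
    catalog_add(catalog, muts$pos, muts$s, muts$h, 1L, 0L)
  } else integer(0)
  haps <- lapply(hap_assign, function(idx) {
    h <- ids[idx]
    h[order(catalog$pos[h])]
  })
  new_population("P1", haps, as.integer(arr), catalog, map)
}

# Brute-force fitness oracle: log-sum over per-mutation factors, written
# independently of individual_fitness.
fitness_oracle <- function(h1, h2, catalog) {
  ids <- c(h1, h2)
  if (!length(ids)) return(1)
  tab <- table(ids)
  logw <- 0
  for (id_chr in names(tab)) {
    id <- as.integer(id_chr)
    s <- catalog$s[id]; h <- catalog$h[id]
    f <- if (tab[[id_chr]] == 2L) 1 + s else 1 + h * s
    if (f <= 0) return(0)
    logw <- logw + log(f)
  }
  exp(logw)
}
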