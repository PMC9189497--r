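# Plain-text snapshot serialization.
#
# A population snapshot is a JSON-lines file (first line: header with label,
# generation, N and the fixed-mutation registry; one line per individual
# with the arrangement pair and the two mutation-id lists) plus a
# mutation-catalog TSV (id, pos, s, h, origin_pop, origin_gen). Only
# mutations referenced by genotypes or registries are written, keeping their
# original ids; positions and coefficients are printed with 17 significant
# digits so the round trip is lossless.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a population snapshot
#'
#' @param pop An `sg_pop`.
#' @param prefix Path prefix; writes `<prefix>.jsonl` and, when
#'   `write_catalog = TRUE`, `<prefix>.catalog.tsv`.
#' @param write_catalog Whether to write the catalog TSV (set `FALSE` when a
#'   shared catalog is written once elsewhere).
#' @return `prefix`, invisibly.
#' @export
write_population <- function(pop, prefix, write_catalog = TRUE) {
  con <- file(paste0(prefix, ".jsonl"), "w")
  on.exit(close(con))
  header <- list(type = "header", label = pop$label, N = pop$N,
                 generation = pop$generation, fixed = pop$fixed,
                 post_admixture = isTRUE(pop$post_admixture))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(pop$N)) {
    rec <- list(a = pop$arr[c(2L * i - 1L, 2L * i)],
                h1 = pop$haps[[2L * i - 1L]],
                h2 = pop$haps[[2L * i]])
    writeLines(jsonlite::toJSON(rec, digits = NA), con)
  }
  if (write_catalog) {
    ids <- sort(unique(c(unlist(pop$haps, use.names = FALSE), pop$fixed)))
    write_catalog_tsv(pop$catalog, paste0(prefix, ".catalog.tsv"), ids)
  }
  invisible(prefix)
}

#' Write a mutation catalog TSV
#'
#' @param cat A catalog.
#' @param path Output file.
#' @param ids Ids to write (default all registered).
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(cat, path, ids = seq_len(cat$n)) {
  df <- catalog_df(cat, ids)
  df$pos <- .fmt_num(df$pos)
  df$s <- .fmt_num(df$s)
  df$h <- .fmt_num(df$h)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation catalog TSV
#'
#' Ids are preserved: the catalog is sized to the largest id and rows are
#' inserted at their original indices.
#'
#' @param path Catalog TSV file.
#' @return A `mut_catalog`.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric", "numeric",
                                         "numeric", "integer", "integer"))
  n <- if (nrow(df)) max(df$id) else 0L
  cat <- new_catalog(max(16L, n))
  cat$n <- as.integer(n)
  if (nrow(df)) {
    cat$pos[df$id] <- df$pos
    cat$s[df$id] <- df$s
    cat$h[df$id] <- df$h
    cat$origin_pop[df$id] <- df$origin_pop
    cat$origin_gen[df$id] <- df$origin_gen
  }
  cat
}

#' Read a population snapshot
#'
#' @param prefix Path prefix used by [write_population()].
#' @param map A [build_genome_map()] for the governing config.
#' @param catalog Optional pre-loaded shared catalog; when `NULL`,
#'   `<prefix>.catalog.tsv` is read.
#' @return An `sg_pop`.
#' @export
read_population <- function(prefix, map, catalog = NULL) {
  lines <- readLines(paste0(prefix, ".jsonl"))
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$type, "header")) {
    stop("malformed snapshot: missing header line", call. = FALSE)
  }
  if (is.null(catalog)) catalog <- read_catalog_tsv(paste0(prefix, ".catalog.tsv"))
  N <- header$N
  haps <- vector("list", 2L * N)
  arr <- integer(2L * N)
  for (i in seq_len(N)) {
    rec <- jsonlite::fromJSON(lines[i + 1L])
    arr[2L * i - 1L] <- rec$a[1]
    arr[2L * i] <- rec$a[2]
    haps[[2L * i - 1L]] <- as.integer(unlist(rec$h1))
    haps[[2L * i]] <- as.integer(unlist(rec$h2))
  }
  pop <- new_population(header$label, haps, arr, catalog, map,
                        generation = header$generation,
                        fixed = as.integer(unlist(header$fixed)))
  if (isTRUE(header$post_admixture)) pop$post_admixture <- TRUE
  pop
}

#' Persist / load a burn-in state
#'
#' A burn-in state (the two diverged populations plus their shared catalog,
#' config and summary) is stored as a directory: `p1.jsonl`, `p2.jsonl`,
#' `catalog.tsv`, `config.json`, `meta.json`.
#'
#' @param state A `burnin_state` (see [run_burnin()]).
#' @param dir Directory to create/fill.
#' @return `dir` (for `write_burnin_state`) or the state (for
#'   `read_burnin_state`).
#' @export
write_burnin_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_population(state$P1, file.path(dir, "p1"), write_catalog = FALSE)
  write_population(state$P2, file.path(dir, "p2"), write_catalog = FALSE)
  ids <- sort(unique(c(unlist(state$P1$haps, use.names = FALSE),
                       unlist(state$P2$haps, use.names = FALSE),
                       state$P1$fixed, state$P2$fixed)))
  write_catalog_tsv(state$P1$catalog, file.path(dir, "catalog.tsv"), ids)
  write_config(state$config, file.path(dir, "config.json"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(list(burnin_id = state$burnin_id, seed = state$seed,
                            summary = strip(state$summary)),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_burnin_state
#' @export
read_burnin_state <- function(dir) {
  cfg <- read_config(file.path(dir, "config.json"))
  map <- build_genome_map(cfg)
  catalog <- read_catalog_tsv(file.path(dir, "catalog.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  state <- list(P1 = read_population(file.path(dir, "p1"), map, catalog),
                P2 = read_population(file.path(dir, "p2"), map, catalog),
                config = cfg, burnin_id = meta$burnin_id, seed = meta$seed,
                summary = meta$summary)
  class(state) <- "burnin_state"
  state
}
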