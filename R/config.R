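#' Simulation configuration
#'
#' Builds a validated parameter set for the supergene introgression model.
#' Defaults are the unscaled study conditions: a 20 Mb diploid genome in two
#' 10 Mb chromosomes, deleterious mutations at `mu = 4.5e-9` per bp per
#' generation restricted to 40 uniformly spaced 5 kb segments (200 kb of
#' allelic content), crossing over at `rho = 3.0e-8` and gene-conversion
#' initiation at `gamma_gc = 1.8e-8` per bp per meiosis with Poisson tract
#' lengths of mean `lambda_gc = 500` bp, gamma-distributed deleterious effects
#' (shape `alpha_gamma = 0.5`, rate `beta_gamma = 10`, so `E|s| = 0.05`), and
#' pre-admixture populations of `N_BI = 2500` evolved for `T_BI` generations.
#' Post-admixture, beneficial mutations arise at a 1000-fold lower rate with
#' exponential effects of mean `kappa_exp = 0.001` and `h = 0.5`.
#'
#' Use [rescale_config()] to trade population size and time for rate and
#' effect size at constant `N*mu*L`, `N*r*L` and `N*s`.
#'
#' @param mu Deleterious mutation rate per bp per generation (applies inside
#'   the mutable segments; see `compensate_segment_mu`).
#' @param beneficial_mu Beneficial mutation rate per bp per generation
#'   (post-admixture only).
#' @param L Total genome length in bp.
#' @param rho Crossover rate per bp per meiosis.
#' @param gamma_gc Gene-conversion initiation rate per bp per meiosis.
#' @param lambda_gc Mean gene-conversion tract length (bp).
#' @param T_BI Burn-in length in generations (divergence time).
#' @param T_max Post-admixture generation cap.
#' @param h_del Dominance coefficient of deleterious mutations.
#' @param h_ben Dominance coefficient of beneficial mutations.
#' @param N_BI Pre-admixture population size (each population).
#' @param N_post Post-admixture size of the focal population.
#' @param alpha_gamma,beta_gamma Shape and rate of the gamma distribution of
#'   deleterious effect magnitudes.
#' @param kappa_exp Mean of the exponential distribution of beneficial
#'   effect magnitudes.
#' @param s_scale Multiplier applied to all sampled effect magnitudes
#'   (changed by [rescale_config()]; `s_scale = 0` gives a neutral model,
#'   useful for calibration).
#' @param scale_Q Cumulative rescaling factor already applied (bookkeeping).
#' @param viability_threshold Mean karyotype fitness below which a karyotype
#'   class is considered inviable when classifying outcomes.
#' @param n_segments,segment_len Number and length (bp) of the uniformly
#'   spaced segments in which mutations may occur.
#' @param compensate_segment_mu If `TRUE`, `mu` is inflated inside segments by
#'   `L / (n_segments*segment_len)` so the per-gamete mutational input equals
#'   `mu*L`; if `FALSE` (default) `mu` applies per bp of segment, so the
#'   per-gamete input is `mu * n_segments * segment_len`.
#' @param allow_selfing If `TRUE` (default) the two parents of an offspring
#'   are drawn independently, so selfing can occur.
#' @param sample_grid Generations (post-admixture) at which time-series
#'   records are collected.
#' @param checkpoints Generations at which outcome classification is applied
#'   to still-polymorphic replicates.
#' @param seed Optional integer seed recorded with the config.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config()
#' cfg10 <- rescale_config(cfg, 10) # the accelerated-evolution scaling
#' @export
sim_config <- function(mu = 4.5e-9,
                       beneficial_mu = 4.5e-12,
                       L = 2e7,
                       rho = 3.0e-8,
                       gamma_gc = 1.8e-8,
                       lambda_gc = 500,
                       T_BI = 200000L,
                       T_max = 200000L,
                       h_del = 0,
                       h_ben = 0.5,
                       N_BI = 2500L,
                       N_post = 100L,
                       alpha_gamma = 0.5,
                       beta_gamma = 10,
                       kappa_exp = 0.001,
                       s_scale = 1,
                       scale_Q = 1,
                       viability_threshold = 0.01,
                       n_segments = 40L,
                       segment_len = 5000,
                       compensate_segment_mu = FALSE,
                       allow_selfing = TRUE,
                       sample_grid = c(10, 50, 100, 200, 500, 1000, 5000,
                                       10000, 25000, 50000, 100000, 125000,
                                       150000, 200000),
                       checkpoints = c(100000, 150000, 200000),
                       seed = NULL) {
  cfg <- list(mu = mu, beneficial_mu = beneficial_mu, L = L, rho = rho,
              gamma_gc = gamma_gc, lambda_gc = lambda_gc,
              T_BI = as.integer(T_BI), T_max = as.integer(T_max),
              h_del = h_del, h_ben = h_ben,
              N_BI = as.integer(N_BI), N_post = as.integer(N_post),
              alpha_gamma = alpha_gamma, beta_gamma = beta_gamma,
              kappa_exp = kappa_exp, s_scale = s_scale, scale_Q = scale_Q,
              viability_threshold = viability_threshold,
              n_segments = as.integer(n_segments), segment_len = segment_len,
              compensate_segment_mu = isTRUE(compensate_segment_mu),
              allow_selfing = isTRUE(allow_selfing),
              sample_grid = sort(unique(as.numeric(sample_grid))),
              checkpoints = sort(unique(as.numeric(checkpoints))),
              seed = seed)
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()] object and stops with
#' an informative error on the first violation.
#'
#' @param cfg A `sim_config` object or a named list with the same fields.
#' @return The validated config, invisibly.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  nonneg <- c("mu", "beneficial_mu", "L", "rho", "gamma_gc", "lambda_gc",
              "T_BI", "T_max", "kappa_exp", "s_scale")
  for (f in nonneg) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 0,
        paste0("config field '", f, "' must be a single non-negative number"))
  }
  chk(cfg$L > 0, "genome length L must be positive")
  chk(cfg$h_del >= 0 && cfg$h_del <= 1, "h_del must lie in [0, 1]")
  chk(cfg$h_ben >= 0 && cfg$h_ben <= 1, "h_ben must lie in [0, 1]")
  chk(cfg$N_BI >= 2, "N_BI must be at least 2")
  chk(cfg$N_post >= 1, "N_post must be at least 1")
  chk(cfg$alpha_gamma > 0 && cfg$beta_gamma > 0,
      "gamma DFE parameters must be positive")
  chk(cfg$scale_Q >= 1, "scale_Q must be >= 1")
  chk(cfg$viability_threshold > 0 && cfg$viability_threshold < 1,
      "viability_threshold must lie in (0, 1)")
  chk(cfg$n_segments >= 1 && cfg$segment_len > 0,
      "segment layout must be non-degenerate")
  chk(cfg$n_segments * cfg$segment_len <= cfg$L,
      "segments exceed genome length: n_segments * segment_len must be <= L")
  invisible(cfg)
}

#' Build the genome coordinate map
#'
#' The genome is linear, 0-based and half-open: chromosome 1 is
#' `[0, L/2)`, chromosome 2 is `[L/2, L)`. The inversion covers the central
#' 50% of chromosome 1 (25% of the genome). Mutable segments of length
#' `segment_len` are placed deterministically at uniform spacing `L /
#' n_segments`, starting at 0.
#'
#' @param cfg A [sim_config()] object.
#' @return An object of class `genome_map`: a list with `L`, `chrom_bounds`
#'   (2x2 matrix of half-open intervals), `inversion` (length-2 vector),
#'   `seg_start`/`seg_end` (segment intervals), `seg_total` (total mutable
#'   length) and `seg_cum` (cumulative segment lengths, used to map uniform
#'   draws to positions).
#' @examples
#' map <- build_genome_map(sim_config())
#' diff(map$inversion) # 5 Mb
#' @export
build_genome_map <- function(cfg) {
  validate_config(cfg)
  L <- cfg$L
  chr1_len <- L / 2
  spacing <- L / cfg$n_segments
  if (cfg$segment_len > spacing) {
    stop("segments cannot be placed disjointly: segment_len exceeds L/n_segments",
         call. = FALSE)
  }
  seg_start <- (seq_len(cfg$n_segments) - 1) * spacing
  seg_end <- seg_start + cfg$segment_len
  inversion <- c(chr1_len / 4, 3 * chr1_len / 4)
  # Windows from which a gene-conversion tract can reach a mutable segment:
  # segments extended leftwards by 4*lambda + 100 bp, beyond which the
  # Poisson tract-length tail underflows to zero. Used to thin GC events to
  # the ones that can touch allelic content (tract initiations elsewhere
  # cannot move any mutation and never change arrangement labels).
  w0 <- 4 * cfg$lambda_gc + 100
  ws <- pmax(0, seg_start - w0)
  we <- seg_end
  keep_w <- ws[-1] > we[-length(we)]
  if (!all(keep_w)) {
    grp <- cumsum(c(TRUE, keep_w))
    ws <- vapply(split(ws, grp), min, numeric(1))
    we <- vapply(split(we, grp), max, numeric(1))
  }
  map <- list(L = L,
              chrom_bounds = rbind(chr1 = c(0, chr1_len),
                                   chr2 = c(chr1_len, L)),
              inversion = inversion,
              seg_start = seg_start,
              seg_end = seg_end,
              seg_total = cfg$n_segments * cfg$segment_len,
              seg_cum = cumsum(rep(cfg$segment_len, cfg$n_segments)),
              gc_win_start = unname(ws),
              gc_win_end = unname(we),
              gc_win_cum = unname(cumsum(we - ws)),
              gc_win_total = sum(we - ws))
  class(map) <- "genome_map"
  map
}

#' Sample deleterious selection coefficients
#'
#' Magnitudes `|s|` are gamma distributed with shape `alpha_gamma` and rate
#' `beta_gamma` (default mean 0.05), multiplied by `s_scale`; the returned
#' coefficients are negative. Draws with `1 + s < 0` are kept: such genotypes
#' are handled by flooring fitness at zero (effective lethality), not by
#' truncating the distribution.
#'
#' @param n Number of draws.
#' @param cfg A [sim_config()] object.
#' @return Numeric vector of `n` negative (or zero when `s_scale = 0`)
#'   selection coefficients.
#' @export
sample_deleterious_effect <- function(n, cfg) {
  -cfg$s_scale * stats::rgamma(n, shape = cfg$alpha_gamma, rate = cfg$beta_gamma)
}

#' Sample beneficial selection coefficients
#'
#' Magnitudes are exponential with mean `kappa_exp` (default 0.001),
#' multiplied by `s_scale`; the returned coefficients are positive.
#'
#' @inheritParams sample_deleterious_effect
#' @return Numeric vector of `n` positive selection coefficients.
#' @export
sample_beneficial_effect <- function(n, cfg) {
  cfg$s_scale * stats::rexp(n, rate = 1 / cfg$kappa_exp)
}

#' Sample gene-conversion tract lengths
#'
#' Tract lengths are Poisson with mean `lambda_gc` (default 500 bp); a
#' length of zero is permitted and corresponds to a no-op tract.
#'
#' @param n Number of draws.
#' @param lambda_gc Mean tract length in bp.
#' @return Integer-valued numeric vector of tract lengths.
#' @export
sample_gc_tract_length <- function(n, lambda_gc) {
  stats::rpois(n, lambda_gc)
}

#' Rescale a configuration for accelerated evolution
#'
#' Standard diffusion rescaling by a factor `Q`: population sizes and time
#' spans are divided by `Q` while per-bp rates (`mu`, `beneficial_mu`, `rho`,
#' `gamma_gc`) and the selection-coefficient scale are multiplied by `Q`, so
#' the products `N*mu*L`, `N*r*L` and `N*s` are preserved. The time-series
#' sampling grid and outcome checkpoints are divided by `Q` (floored at
#' generation 1). Tract length `lambda_gc` and dominance are untouched.
#'
#' @param cfg A [sim_config()] object.
#' @param Q Rescaling factor, `>= 1`. Resulting population sizes must be
#'   whole numbers of at least 2 (`N_BI`) and 1 (`N_post`).
#' @return A rescaled `sim_config` with `scale_Q` multiplied by `Q`.
#' @export
rescale_config <- function(cfg, Q) {
  validate_config(cfg)
  stopifnot(is.numeric(Q), length(Q) == 1, Q >= 1)
  if (Q == 1) return(cfg)
  n_bi <- cfg$N_BI / Q
  n_post <- cfg$N_post / Q
  if (abs(n_bi - round(n_bi)) > 1e-9 || abs(n_post - round(n_post)) > 1e-9) {
    stop("rescaling must yield integer population sizes", call. = FALSE)
  }
  if (round(n_bi) < 2) stop("rescaled N_BI would fall below 2", call. = FALSE)
  if (round(n_post) < 1) stop("rescaled N_post would fall below 1", call. = FALSE)
  out <- cfg
  out$N_BI <- as.integer(round(n_bi))
  out$N_post <- as.integer(round(n_post))
  out$T_BI <- as.integer(max(1, round(cfg$T_BI / Q)))
  out$T_max <- as.integer(max(1, round(cfg$T_max / Q)))
  out$mu <- cfg$mu * Q
  out$beneficial_mu <- cfg$beneficial_mu * Q
  out$rho <- cfg$rho * Q
  out$gamma_gc <- cfg$gamma_gc * Q
  out$s_scale <- cfg$s_scale * Q
  out$scale_Q <- cfg$scale_Q * Q
  out$sample_grid <- sort(unique(pmax(1, round(cfg$sample_grid / Q))))
  out$checkpoints <- sort(unique(pmax(1, round(cfg$checkpoints / Q))))
  validate_config(out)
  out
}

#' Per-gamete mutation rates implied by a configuration
#'
#' @param cfg A [sim_config()] object.
#' @param map The [build_genome_map()] of `cfg`.
#' @return Named list with `u_del` and `u_ben`, the expected numbers of new
#'   deleterious and beneficial mutations per gamete per generation.
#' @export
gamete_mutation_rates <- function(cfg, map) {
  target <- if (cfg$compensate_segment_mu) cfg$L else map$seg_total
  list(u_del = cfg$mu * target, u_ben = cfg$beneficial_mu * target)
}

#' Read / write configurations as JSON
#'
#' Plain-JSON persistence mirroring the `sim_config` field names; all
#' defaults are the documented study conditions, so a minimal file need only
#' state deviations.
#'
#' @param path File path.
#' @param cfg A `sim_config` object (for writing).
#' @return `read_config()` returns a validated `sim_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: L = %.3g bp, %d x %g bp segments, inversion 50%% of chr1\n",
              x$L, x$n_segments, x$segment_len))
  cat(sprintf("  rates:  mu = %.3g, ben = %.3g, rho = %.3g, gamma = %.3g, lambda = %g\n",
              x$mu, x$beneficial_mu, x$rho, x$gamma_gc, x$lambda_gc))
  cat(sprintf("  DFE:    |s| ~ Gamma(%g, rate %g) * %g, h_del = %g; ben ~ Exp(mean %g), h_ben = %g\n",
              x$alpha_gamma, x$beta_gamma, x$s_scale, x$h_del, x$kappa_exp, x$h_ben))
  cat(sprintf("  sizes:  N_BI = %d, N_post = %d, T_BI = %d, T_max = %d (scale_Q = %g)\n",
              x$N_BI, x$N_post, x$T_BI, x$T_max, x$scale_Q))
  invisible(x)
}
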