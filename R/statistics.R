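# Bespoke statistics of the supergene model: karyotype fitness summaries,
# associative overdominance (AOD) following Ohta, segregation-load
# decomposition, symmetry, and the three-way outcome classification.

.region_filter <- function(pos, region, map) {
  if (is.character(region)) {
    switch(region,
           supergene = pos >= map$inversion[1] & pos < map$inversion[2],
           chr1_outside = pos < map$chrom_bounds[1L, 2L] &
             !(pos >= map$inversion[1] & pos < map$inversion[2]),
           chr2 = pos >= map$chrom_bounds[2L, 1L],
           genome = rep(TRUE, length(pos)),
           stop("unknown region '", region, "'", call. = FALSE))
  } else {
    stopifnot(is.numeric(region), length(region) == 2)
    pos >= region[1] & pos < region[2]
  }
}

#' Mean fitness per karyotype class
#'
#' Arithmetic means of individual fitness within each karyotype class
#' present in the population; absent classes yield `NA`.
#'
#' @param pop An `sg_pop`.
#' @return One-row data.frame with `W_AA`, `W_AB`, `W_BB`, counts `n_AA`,
#'   `n_AB`, `n_BB` and `generation`.
#' @export
karyotype_fitness_summary <- function(pop) {
  k <- population_karyotypes(pop)
  w <- pop$fitness
  cls <- function(x) if (any(k == x)) mean(w[k == x]) else NA_real_
  data.frame(W_AA = cls("AA"), W_AB = cls("AB"), W_BB = cls("BB"),
             n_AA = sum(k == "AA"), n_AB = sum(k == "AB"),
             n_BB = sum(k == "BB"), generation = pop$generation)
}

#' Expected karyotype fitness from random haplotype pairings
#'
#' The expected mean fitness of each karyotype class formed by pairing
#' random haplotypes of the appropriate arrangements, regardless of whether
#' such individuals exist in the standing population. Used as the fallback
#' when a homokaryotype class is absent (typical once a class is lethal) and
#' for closed-form checks on constructed populations. Pairs are enumerated
#' exhaustively when the number of combinations is at most `max_exact`,
#' otherwise `n_mc` Monte Carlo pairs are drawn.
#'
#' @param pop An `sg_pop`.
#' @param max_exact Combination count up to which enumeration is exact.
#' @param n_mc Number of sampled pairs beyond that.
#' @return One-row data.frame with `W_AA`, `W_AB`, `W_BB` and haplotype
#'   counts `n_hap_A`, `n_hap_B`.
#' @export
expected_karyotype_fitness <- function(pop, max_exact = 2000L, n_mc = 400L) {
  idxA <- which(pop$arr == 1L)
  idxB <- which(pop$arr == 0L)
  pair_mean <- function(ii, jj) {
    # mean fitness over pairs (ii[k], jj[k])
    w <- numeric(length(ii))
    for (k in seq_along(ii)) {
      w[k] <- individual_fitness(pop$haps[[ii[k]]], pop$haps[[jj[k]]],
                                 pop$catalog)
    }
    mean(w)
  }
  homo <- function(idx) {
    n <- length(idx)
    if (n == 0L) return(NA_real_)
    if (n == 1L) return(pair_mean(idx, idx))
    np <- n * (n - 1) / 2
    if (np <= max_exact) {
      cmb <- utils::combn(idx, 2L)
      pair_mean(cmb[1L, ], cmb[2L, ])
    } else {
      ii <- integer(n_mc); jj <- integer(n_mc)
      for (k in seq_len(n_mc)) {
        p <- sample(idx, 2L)
        ii[k] <- p[1L]; jj[k] <- p[2L]
      }
      pair_mean(ii, jj)
    }
  }
  hetero <- function() {
    nA <- length(idxA); nB <- length(idxB)
    if (nA == 0L || nB == 0L) return(NA_real_)
    if (nA * nB <= max_exact) {
      grid <- expand.grid(i = idxA, j = idxB)
      pair_mean(grid$i, grid$j)
    } else {
      pair_mean(sample(idxA, n_mc, replace = TRUE),
                sample(idxB, n_mc, replace = TRUE))
    }
  }
  data.frame(W_AA = homo(idxA), W_AB = hetero(), W_BB = homo(idxB),
             n_hap_A = length(idxA), n_hap_B = length(idxB))
}

#' Associative overdominance following Ohta
#'
#' From the karyotype means, `s1' = 1 - W_AA/W_AB` and
#' `s2' = 1 - W_BB/W_AB`; the strength of AOD is `s' = min(s1', s2')` (the
#' fitness deficit of the fitter homokaryotype relative to the
#' heterokaryotype) and the asymmetry of the two arrangement loads is
#' `|s1' - s2'|`. Positive `s'` means the heterokaryotype is fitter than
#' both homokaryotypes; negative values indicate the reverse. Undefined
#' inputs (`W_AB` missing or zero, or a missing homokaryotype mean) yield
#' `NA` components rather than fabricated values.
#'
#' @param summary A one-row data.frame with `W_AA`, `W_AB`, `W_BB` (e.g.
#'   from [karyotype_fitness_summary()] or [expected_karyotype_fitness()]).
#' @return One-row data.frame `s1p`, `s2p`, `sp`, `symmetry`, `generation`
#'   (NA when the input has no generation column).
#' @export
compute_aod <- function(summary) {
  gen <- if ("generation" %in% names(summary)) summary$generation else NA_integer_
  wab <- summary$W_AB
  if (is.na(wab) || wab <= 0) {
    return(data.frame(s1p = NA_real_, s2p = NA_real_, sp = NA_real_,
                      symmetry = NA_real_, generation = gen))
  }
  s1p <- 1 - summary$W_AA / wab
  s2p <- 1 - summary$W_BB / wab
  sp <- if (is.na(s1p) || is.na(s2p)) NA_real_ else min(s1p, s2p)
  sym <- if (is.na(s1p) || is.na(s2p)) NA_real_ else abs(s1p - s2p)
  data.frame(s1p = s1p, s2p = s2p, sp = sp, symmetry = sym, generation = gen)
}

#' Segregation-load decomposition for a genomic region
#'
#' Decomposes the load a population contributes to the post-admixture
#' segregation load of a region into:
#' * mutational load: `1 -` the population mean of individual fitness
#'   restricted to segregating mutations inside the region;
#' * drift load: `1 - prod(1 + s)` over deleterious mutations fixed in this
#'   population but not in `reference` (private fixed; these re-segregate
#'   after admixture), restricted to the region.
#'
#' The two compose multiplicatively, consistent with multiplicative fitness:
#' `1 - L_seg = (1 - L_drift)(1 - L_mut)`; `drift_fraction` is
#' `L_drift / L_seg` (NA when the segregation load is zero).
#'
#' @param pop An `sg_pop`.
#' @param reference The sister population (other side of the split).
#' @param region `"supergene"`, `"chr1_outside"`, `"chr2"`, `"genome"`, or a
#'   numeric `c(start, end)` half-open interval.
#' @return List of class `load_summary`: `region`, `drift_load`,
#'   `mutational_load`, `segregation_load`, `drift_fraction`.
#' @export
compute_loads <- function(pop, reference, region = "supergene") {
  map <- pop$map
  catalog <- pop$catalog
  restrict <- function(h) h[.region_filter(catalog$pos[h], region, map)]
  w <- numeric(pop$N)
  for (i in seq_len(pop$N)) {
    w[i] <- individual_fitness(restrict(pop$haps[[2L * i - 1L]]),
                               restrict(pop$haps[[2L * i]]), catalog)
  }
  mut_load <- 1 - mean(w)
  priv <- setdiff(pop$fixed, reference$fixed)
  priv <- priv[catalog$s[priv] < 0]
  priv <- priv[.region_filter(catalog$pos[priv], region, map)]
  drift_load <- 1 - prod(pmax(0, 1 + catalog$s[priv]))
  seg <- 1 - (1 - drift_load) * (1 - mut_load)
  out <- list(region = if (is.character(region)) region else "interval",
              drift_load = drift_load,
              mutational_load = mut_load,
              segregation_load = seg,
              drift_fraction = if (seg > 0) drift_load / seg else NA_real_)
  class(out) <- "load_summary"
  out
}

#' @export
print.load_summary <- function(x, ...) {
  cat(sprintf("<load_summary %s> drift %.4f + mutational %.4f -> segregation %.4f (drift fraction %.2f)\n",
              x$region, x$drift_load, x$mutational_load, x$segregation_load,
              x$drift_fraction))
  invisible(x)
}

#' Classify the state of a polymorphic supergene population
#'
#' Karyotype classes with mean fitness below `threshold` are considered
#' inviable. Outcomes: `POLY_BOTH_VIABLE` (both homokaryotypes viable),
#' `HALF_LETHAL` (exactly one inviable) and `BALANCED_LETHAL` (both
#' inviable). Realized class means are used when a class is present in the
#' standing population; an absent homokaryotype class (the rule rather than
#' the exception once that class is lethal, since such individuals are
#' removed by selection) is scored by [expected_karyotype_fitness()] on
#' random within-arrangement haplotype pairs.
#'
#' @param pop A polymorphic `sg_pop` (both arrangements present).
#' @param threshold Viability threshold on mean karyotype fitness.
#' @return A single character string, one of the three outcome classes.
#' @export
classify_outcome <- function(pop, threshold = 0.01) {
  f <- inversion_frequency(pop)
  if (f <= 0 || f >= 1) {
    stop("outcome classification requires a polymorphic population",
         call. = FALSE)
  }
  ks <- karyotype_fitness_summary(pop)
  w_aa <- ks$W_AA
  w_bb <- ks$W_BB
  if (is.na(w_aa) || is.na(w_bb)) {
    ek <- expected_karyotype_fitness(pop)
    if (is.na(w_aa)) w_aa <- ek$W_AA
    if (is.na(w_bb)) w_bb <- ek$W_BB
  }
  n_inviable <- (w_aa < threshold) + (w_bb < threshold)
  c("POLY_BOTH_VIABLE", "HALF_LETHAL", "BALANCED_LETHAL")[n_inviable + 1L]
}

#' Mean deleterious mutation count (and haploid load) per arrangement
#'
#' Mean number of deleterious mutations per haplotype inside a region,
#' separately for inverted (A) and standard (B) haplotypes, plus the mean
#' haploid load `1 - prod(1 + s)` over each haplotype's regional deleterious
#' mutations (the fitness a homozygote for that haplotype would lose from
#' the region). Arrangement classes with no haplotypes yield `NA`.
#'
#' @param pop An `sg_pop`.
#' @param region As in [compute_loads()].
#' @return One-row data.frame: `n_mut_A`, `n_mut_B`, `load_A`, `load_B`,
#'   `n_hap_A`, `n_hap_B`.
#' @export
mutations_per_arrangement <- function(pop, region = "supergene") {
  catalog <- pop$catalog
  map <- pop$map
  one <- function(h) {
    h <- h[catalog$s[h] < 0]
    h <- h[.region_filter(catalog$pos[h], region, map)]
    c(n = length(h), load = 1 - prod(pmax(0, 1 + catalog$s[h])))
  }
  per <- vapply(pop$haps, one, numeric(2))
  cls <- function(sel, row) if (any(sel)) mean(per[row, sel]) else NA_real_
  a <- pop$arr == 1L
  data.frame(n_mut_A = cls(a, 1L), n_mut_B = cls(!a, 1L),
             load_A = cls(a, 2L), load_B = cls(!a, 2L),
             n_hap_A = sum(a), n_hap_B = sum(!a))
}

#' Invasion probability binned by initial AOD and symmetry
#'
#' Tiles the (AOD, symmetry) plane into rectangles of half-widths `d_aod`
#' and `d_sym` and reports the invasion probability per tile; tiles with
#' `min_n` or fewer observations are suppressed.
#'
#' @param records Data.frame with columns `sp` (AOD at the reference
#'   generation), `symmetry` and logical `invaded`.
#' @param d_aod,d_sym Tile half-widths.
#' @param min_n Minimum observation count: tiles are kept only when
#'   `n > min_n`.
#' @return Data.frame with tile centres `aod_mid`, `sym_mid`, counts `n` and
#'   `p_invasion`.
#' @export
bin_invasion_by_aod_symmetry <- function(records, d_aod = 0.005,
                                         d_sym = 0.0075, min_n = 20L) {
  ok <- stats::complete.cases(records[, c("sp", "symmetry", "invaded")])
  records <- records[ok, , drop = FALSE]
  wa <- 2 * d_aod
  ws <- 2 * d_sym
  ia <- floor(records$sp / wa)
  is <- floor(records$symmetry / ws)
  key <- paste(ia, is, sep = ":")
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(idx) {
    data.frame(aod_mid = ia[idx[1]] * wa + d_aod,
               sym_mid = is[idx[1]] * ws + d_sym,
               n = length(idx),
               p_invasion = mean(records$invaded[idx]))
  }))
  out <- out[out$n > min_n, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$aod_mid, out$sym_mid), , drop = FALSE]
}
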