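#' Configuration for a structured diversity panel
#'
#' Defaults emulate the common-bean diversity panel this package is
#' modeled on: 71 Andean and 115 Mesoamerican inbred genotypes, strongly
#' diverged genepools (the SNP assays were ascertained as polymorphic
#' between the genepool parents), weaker race substructure inside each
#' pool with more of it in the Mesoamerican pool, and deep within-race
#' haplotype structure so intra-chromosomal LD decays with genetic
#' distance on the tens-of-cM scale reported for domesticated bean
#' germplasm.
#'
#' @param pool_sizes integer vector of the two genepool sizes.
#' @param pool_names names for the pools.
#' @param divergence fraction (0,1) of markers at which each genepool's
#'   haplotype clades are re-drawn from the ancestral distribution
#'   (lineage sorting), separating the pools' allele frequencies.
#' @param races number of race subpopulations per pool (length 1 or 2).
#' @param race_drift strength (0,1) of race substructure: each race's
#'   clade-usage probability is drawn from a symmetric Beta whose
#'   spread grows with this value (0 = all races use both clades
#'   equally, i.e. no substructure).
#' @param hap_divergence drift parameter for the two haplotype clades
#'   each race carries; large values give strong local LD.
#' @param block_cm haplotype-block correlation length in cM: individuals
#'   are Markov mosaics of the two clades with switch probability
#'   `1 - exp(-d / block_cm)` between adjacent markers.
#' @param missing_rate per-cell missing probability.
#' @param het_rate per-cell residual heterozygosity probability.
#' @param seed RNG seed (required).
#' @return list of class `panel_config`.
#' @export
panel_config <- function(pool_sizes = c(71, 115),
                         pool_names = c("Andean", "Mesoamerican"),
                         divergence = 0.4, races = c(1, 3),
                         race_drift = 0.3, hap_divergence = 0.9,
                         block_cm = 30, missing_rate = 0.02,
                         het_rate = 0.005, seed = 1) {
  stopifnot(length(pool_sizes) == 2, all(pool_sizes >= 1),
            divergence >= 0, divergence < 1,
            race_drift >= 0, race_drift < 1,
            hap_divergence >= 0, hap_divergence < 1,
            length(races) %in% c(1, 2), all(races >= 1), block_cm > 0)
  if (length(races) == 1) races <- rep(races, 2)
  structure(list(pool_sizes = as.integer(pool_sizes),
                 pool_names = pool_names, divergence = divergence,
                 races = as.integer(races), race_drift = race_drift,
                 hap_divergence = hap_divergence, block_cm = block_cm,
                 missing_rate = missing_rate, het_rate = het_rate,
                 seed = seed),
            class = "panel_config")
}

# Balding-Nichols draw: frequencies drifted from `p` with parameter F.
# F -> 0 degenerates to no drift (returns p unchanged).
bn_drift <- function(p, f, rng) {
  if (f <= 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  rng$rbeta(length(p), a, b)
}

#' Simulate a two-genepool diversity panel of inbred lines
#'
#' Hierarchical model in haplotype-clade space: ancestral allele
#' frequencies are drawn once per marker and split into two deep
#' haplotype clades (Balding-Nichols drift with `hap_divergence`); each
#' genepool inherits the ancestral clade pair with a `divergence`
#' fraction of markers re-drawn (lineage sorting). Races within a pool
#' share the pool's clade content but differ in clade usage: each race
#' is biased toward one clade with strength controlled by `race_drift`.
#' Every inbred individual is a block mosaic of the two clades along
#' the genetic map (block boundaries fall with correlation length
#' `block_cm`; the clade of each block is drawn from the race's usage
#' probability), with alleles drawn from the clade-specific
#' frequencies. Nearby markers therefore share clade blocks and show
#' high r-squared that decays with genetic distance, while pool
#' divergence and race usage bias add the long-range LD component -
#' pooling usage-biased races inflates LD at all distances, as race
#' substructure does in real germplasm.
#'
#' @param genome a [genome_spec()].
#' @param cfg a [panel_config()].
#' @return list with `calls` (lines x markers character matrix with
#'   codes A/B/H/NA), `labels` (data.frame line, pool, race) and the
#'   config.
#' @export
simulate_diversity_panel <- function(genome, cfg = panel_config()) {
  stopifnot(inherits(genome, "genome_spec"), inherits(cfg, "panel_config"))
  if (any(cfg$pool_sizes < 1)) stop("pool size must be >= 1")
  rng <- local_rng(cfg$seed)
  mk <- genome$markers
  m <- nrow(mk)
  chroms <- unique(mk$chrom)
  g_cm <- numeric(m)
  for (ch in chroms) {
    idx <- which(mk$chrom == ch)
    g_cm[idx] <- genetic_pos(genome, ch, mk$pos_bp[idx])
  }
  chrom_of <- mk$chrom
  # per-marker clade switch probability to the previous marker
  switch_p <- numeric(m)
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    d <- c(Inf, diff(g_cm[idx]))
    switch_p[idx] <- 1 - exp(-d / cfg$block_cm)
  }

  p_anc <- rng$runif(m, 0.1, 0.9)
  n_total <- sum(cfg$pool_sizes)
  calls <- matrix(NA_character_, nrow = n_total, ncol = m,
                  dimnames = list(sprintf("G%03d", seq_len(n_total)),
                                  mk$marker))
  labels <- data.frame(line = rownames(calls),
                       pool = rep(cfg$pool_names, cfg$pool_sizes),
                       race = NA_character_,
                       stringsAsFactors = FALSE)

  # hierarchy lives in haplotype-clade space: two deep ancestral clades,
  # and descendant (pool, race) clades diverge by lineage sorting - each
  # inherits the parent clade but re-draws a `rate` fraction of markers
  # from the ancestral frequency distribution. Near-fixed clade
  # frequencies (strong local LD) survive the divergence, and zero
  # divergence/drift collapses every subpopulation onto the same pair.
  resample_clade <- function(clade, rate, source) {
    if (rate <= 0) return(clade)
    idx <- which(rng$runif(length(clade)) < rate)
    if (length(idx))
      clade[idx] <- bn_drift(source[idx], cfg$hap_divergence, rng)
    clade
  }
  clade_anc <- rbind(bn_drift(p_anc, cfg$hap_divergence, rng),
                     bn_drift(p_anc, cfg$hap_divergence, rng))
  row0 <- 0L
  for (pool in 1:2) {
    clade_pool <- rbind(
      resample_clade(clade_anc[1, ], cfg$divergence, p_anc),
      resample_clade(clade_anc[2, ], cfg$divergence, p_anc))
    n_races <- cfg$races[pool]
    race_of <- sort(rng$sample(n_races, cfg$pool_sizes[pool],
                               replace = TRUE))
    for (rc in seq_len(n_races)) {
      # races share the pool's clade CONTENT but differ in clade USAGE:
      # each race is biased toward one clade (usage probability drawn
      # from a symmetric Beta whose spread grows with race_drift), which
      # creates genome-wide admixture LD when races are pooled while
      # leaving the shared short-range block structure intact
      pi_rc <- if (cfg$race_drift <= 0 || n_races == 1) 0.5 else {
        conc <- 0.5 * (1 / cfg$race_drift - 1)
        rng$rbeta(1, conc, conc)
      }
      for (ind in which(race_of == rc)) {
        sw <- rng$runif(m) < switch_p    # block boundaries (chrom starts = 1)
        sw[1] <- TRUE
        bid <- cumsum(sw)
        z <- (rng$runif(max(bid)) < pi_rc)[bid]
        hap <- rng$runif(m) < clade_pool[cbind(ifelse(z, 2L, 1L),
                                               seq_len(m))]
        calls[row0 + ind, ] <- ifelse(hap, "B", "A")
      }
      labels$race[row0 + which(race_of == rc)] <-
        sprintf("%s_race%d", cfg$pool_names[pool], rc)
    }
    row0 <- row0 + cfg$pool_sizes[pool]
  }

  if (cfg$het_rate > 0) {
    flip <- rng$runif(length(calls)) < cfg$het_rate
    calls[flip] <- "H"
  }
  if (cfg$missing_rate > 0) {
    miss <- rng$runif(length(calls)) < cfg$missing_rate
    calls[miss] <- NA_character_
  }
  list(calls = calls, labels = labels, config = cfg)
}
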