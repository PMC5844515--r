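#' Configuration for RIL population simulation
#'
#' @param n_lines number of recombinant inbred lines (>= 2). The reference
#'   mapping population this emulates is of typical core-population size, so
#'   the default is 80 lines.
#' @param generations selfing generation k of the final lines (>= 2);
#'   k = 11 corresponds to an advanced F11 population.
#' @param missing_rate per-cell probability of a failed (missing) call.
#' @param het_rate target residual heterozygosity rate. Heterozygosity
#'   arising naturally from finite selfing counts toward this target; extra
#'   cells are recoded H only to make up any shortfall in expectation.
#' @param seed RNG seed (required).
#' @return list of class `ril_config`.
#' @export
ril_config <- function(n_lines = 80, generations = 11,
                       missing_rate = 0.02, het_rate = 0.005, seed = 1) {
  stopifnot(n_lines >= 2, generations >= 2,
            missing_rate >= 0, missing_rate <= 1,
            het_rate >= 0, het_rate <= 1)
  structure(list(n_lines = as.integer(n_lines),
                 generations = as.integer(generations),
                 missing_rate = missing_rate, het_rate = het_rate,
                 seed = seed),
            class = "ril_config")
}

# One meiotic gamete from a heterozygous-phase parent. Crossovers fall as a
# Poisson process on the genetic scale (no interference); `g_cm` are marker
# genetic positions, `len_cm` the chromosome genetic length.
meiosis_gamete <- function(h1, h2, g_cm, len_cm, rng) {
  n_xo <- rng$rpois(1, len_cm / 100)
  phase0 <- rng$sample(2, 1) - 1L
  if (n_xo == 0) return(if (phase0 == 0) h1 else h2)
  xo <- sort(rng$runif(n_xo, 0, len_cm))
  phase <- (phase0 + findInterval(g_cm, xo)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate a selfing RIL population
#'
#' Starting from an F1 heterozygous at every marker, each line is advanced
#' by `generations - 1` rounds of selfing; every round draws two independent
#' meiotic gametes (crossovers as a Poisson process along the genetic length
#' implied by the intensity profile, without interference). Final calls are
#' coded `A`/`B` for the two parental alleles, `H` for residual
#' heterozygotes and `NA` for missing.
#'
#' @param genome a [genome_spec()].
#' @param cfg a [ril_config()].
#' @return list with `calls` (lines x markers character matrix), and
#'   `truth` - a data.frame of the generating marker order with columns
#'   `marker`, `chrom`, `pos_bp`, `pos_cm`, and `r_next`, the meiotic
#'   recombination fraction to the next marker on the same chromosome
#'   (Haldane transform of the generating genetic distance).
#' @export
simulate_ril_population <- function(genome, cfg = ril_config()) {
  stopifnot(inherits(genome, "genome_spec"), inherits(cfg, "ril_config"))
  if (nrow(genome$markers) == 0L) stop("genome has zero markers")
  rng <- local_rng(cfg$seed)
  mk <- genome$markers
  chroms <- unique(mk$chrom)

  calls <- matrix(NA_character_, nrow = cfg$n_lines, ncol = nrow(mk),
                  dimnames = list(sprintf("RIL%03d", seq_len(cfg$n_lines)),
                                  mk$marker))
  truth <- mk
  truth$pos_cm <- NA_real_
  truth$r_next <- NA_real_

  for (ch in chroms) {
    idx <- which(mk$chrom == ch)
    g_cm <- genetic_pos(genome, ch, mk$pos_bp[idx])
    len_cm <- chrom_genetic_length(genome, ch)
    truth$pos_cm[idx] <- g_cm
    if (length(idx) > 1) {
      d <- diff(g_cm) / 100                     # Morgans
      truth$r_next[idx[-length(idx)]] <- (1 - exp(-2 * d)) / 2
    }
    for (ln in seq_len(cfg$n_lines)) {
      h1 <- rep(0L, length(idx)); h2 <- rep(1L, length(idx))   # F1
      for (gen in seq_len(cfg$generations - 1L)) {
        g1 <- meiosis_gamete(h1, h2, g_cm, len_cm, rng)
        g2 <- meiosis_gamete(h1, h2, g_cm, len_cm, rng)
        h1 <- g1; h2 <- g2
      }
      calls[ln, idx] <- ifelse(h1 == h2, ifelse(h1 == 0L, "A", "B"), "H")
    }
  }

  # top up residual heterozygosity to the configured target in expectation
  nat_het <- mean(calls == "H")
  extra <- max(0, cfg$het_rate - nat_het)
  if (extra > 0) {
    flip <- rng$runif(length(calls)) < extra
    calls[flip & calls != "H"] <- "H"
  }
  miss <- rng$runif(length(calls)) < cfg$missing_rate
  calls[miss] <- NA_character_

  list(calls = calls, truth = truth, config = cfg)
}
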