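#' Per-marker allele frequency statistics
#'
#' Inbred lines are counted as single alleles: heterozygous and missing
#' calls are excluded, and `p` is the frequency of the `B` allele among
#' the remaining calls.
#'
#' @param calls character vector of calls at one marker (codes A/B/H/NA).
#' @return list with `p`, `n` (non-missing homozygous calls), `maf`; all
#'   `NA` when fewer than 2 usable calls remain.
#' @export
allele_freq <- function(calls) {
  use <- calls %in% c("A", "B")
  n <- sum(use)
  if (n < 2) return(list(p = NA_real_, n = n, maf = NA_real_))
  p <- sum(calls[use] == "B") / n
  list(p = p, n = n, maf = min(p, 1 - p))
}

#' Polymorphic information content of a biallelic locus
#'
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`, maximal (0.375) at `p = 0.5`.
#'
#' @param p allele frequency in `[0, 1]`.
#' @export
pic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Per-site nucleotide diversity
#'
#' Expected pairwise difference at one biallelic site with small-sample
#' correction: `pi = n/(n-1) * 2 p (1 - p)`.
#'
#' @param p allele frequency.
#' @param n number of sampled alleles (>= 2).
#' @export
pi_site <- function(p, n) {
  stopifnot(all(n >= 2))
  n / (n - 1) * 2 * p * (1 - p)
}

#' Marker diversity table, globally and within populations
#'
#' Computes sample size, MAF, PIC and per-site nucleotide diversity for
#' every marker in each requested scope ("global" plus each population
#' label).
#'
#' @param calls genotype matrix (lines x markers).
#' @param labels optional data.frame with `line`, `pool` columns; when
#'   given, per-pool scopes are added.
#' @return data.frame with `marker`, `scope`, `n`, `maf`, `pic`, `pi`.
#' @export
marker_diversity <- function(calls, labels = NULL) {
  scopes <- list(global = rownames(calls))
  if (!is.null(labels)) {
    for (pool in unique(labels$pool))
      scopes[[pool]] <- labels$line[labels$pool == pool]
  }
  out <- lapply(names(scopes), function(sc) {
    sub <- calls[rownames(calls) %in% scopes[[sc]], , drop = FALSE]
    stats_list <- apply(sub, 2, allele_freq)
    p <- vapply(stats_list, `[[`, numeric(1), "p")
    n <- vapply(stats_list, `[[`, numeric(1), "n")
    data.frame(marker = colnames(sub), scope = sc, n = n,
               maf = vapply(stats_list, `[[`, numeric(1), "maf"),
               pic = ifelse(is.na(p), NA, pic(p)),
               pi = ifelse(is.na(p), NA, pi_site(p, pmax(n, 2))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Folded site-frequency spectrum over markers
#'
#' Histogram of minor-allele frequencies in equal bins on `[0, 0.5]`.
#' Monomorphic markers (MAF 0) land in the first bin; `NA` MAF values
#' are dropped.
#'
#' @param maf numeric vector of minor-allele frequencies.
#' @param bins number of equal bins.
#' @return named integer vector of bin counts; bin edges in
#'   `attr(, "breaks")`.
#' @export
folded_sfs <- function(maf, bins = 10) {
  maf <- maf[!is.na(maf)]
  breaks <- seq(0, 0.5, length.out = bins + 1)
  idx <- pmin(findInterval(maf, breaks, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  names(counts) <- sprintf("[%.2f,%.2f%s", utils::head(breaks, -1),
                           breaks[-1],
                           c(rep(")", bins - 1), "]"))
  attr(counts, "breaks") <- breaks
  counts
}

#' Wright-Fisher neutral folded-SFS expectation
#'
#' Monte-Carlo expectation of the folded SFS for `n_markers` unlinked
#' segregating sites in a sample of `n` haplotypes under the standard
#' neutral model: each site's derived count `i` in `1..n-1` is drawn
#' with probability proportional to `1/i`, folded to `min(i, n-i)/n`,
#' and binned as [folded_sfs()]. Repeated `reps` times to give the mean
#' and a 2.5/97.5-percentile envelope per bin.
#'
#' @param n sampled haplotypes (>= 2).
#' @param n_markers segregating sites per repetition.
#' @param reps Monte-Carlo repetitions (default 5000).
#' @param bins histogram bins as in [folded_sfs()].
#' @param seed RNG seed.
#' @return list with `mean`, `lo`, `hi` (per-bin), `breaks`,
#'   `unfolded_prop` (mean proportion of each derived count class
#'   `1..n-1` across all draws), `n`, `n_markers`, `reps`.
#' @export
neutral_sfs_expectation <- function(n, n_markers, reps = 5000, bins = 10,
                                    seed = 1) {
  stopifnot(n >= 2, n_markers >= 1, reps >= 1)
  rng <- local_rng(seed)
  classes <- seq_len(n - 1)
  prob <- (1 / classes) / sum(1 / classes)
  maf_of_class <- pmin(classes, n - classes) / n
  breaks <- seq(0, 0.5, length.out = bins + 1)
  bin_of_class <- pmin(findInterval(maf_of_class, breaks,
                                    rightmost.closed = TRUE), bins)
  binned <- matrix(0L, nrow = reps, ncol = bins)
  unfolded_tot <- numeric(n - 1)
  for (r in seq_len(reps)) {
    draw <- rng$sample(n - 1, n_markers, replace = TRUE, prob = prob)
    cls <- tabulate(draw, nbins = n - 1)
    unfolded_tot <- unfolded_tot + cls
    binned[r, ] <- vapply(seq_len(bins), function(b)
      sum(cls[bin_of_class == b]), numeric(1))
  }
  qs <- apply(binned, 2, stats::quantile, probs = c(0.025, 0.975))
  out <- list(mean = colMeans(binned), lo = qs[1, ], hi = qs[2, ],
              breaks = breaks,
              unfolded_prop = unfolded_tot / (reps * n_markers),
              theory_prop = prob, n = n, n_markers = n_markers,
              reps = reps, seed = seed)
  class(out) <- "neutral_sfs"
  out
}

#' Compare an observed folded SFS with the neutral expectation
#'
#' Per-bin deviation `(observed - mean) / halfwidth`, where halfwidth is
#' half the 2.5-97.5 percentile envelope; the spectrum is flagged
#' `consistent` when every bin lies inside the envelope. Observed counts
#' should cover the same number of polymorphic markers the expectation
#' was simulated for.
#'
#' @param observed integer vector of bin counts from [folded_sfs()]
#'   (same binning as the expectation).
#' @param expectation a [neutral_sfs_expectation()] result.
#' @return list with `table` (per-bin observed, expected, lo, hi,
#'   deviation) and `consistent`.
#' @export
neutrality_comparison <- function(observed, expectation) {
  if (length(observed) != length(expectation$mean))
    stop("bin count mismatch between observed SFS and expectation")
  half <- pmax((expectation$hi - expectation$lo) / 2, 1e-9)
  dev <- (as.numeric(observed) - expectation$mean) / half
  inside <- observed >= expectation$lo & observed <= expectation$hi
  list(table = data.frame(bin = seq_along(observed),
                          observed = as.numeric(observed),
                          expected = expectation$mean,
                          lo = expectation$lo, hi = expectation$hi,
                          deviation = dev),
       consistent = all(inside))
}
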