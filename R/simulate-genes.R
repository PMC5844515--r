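#' Simulate gene models over a synthetic genome
#'
#' Places gene intervals with local density proportional to the meiotic
#' recombination intensity (plus a floor), emulating the gene-rich
#' recombining arms and gene-poor pericentromeric heterochromatin of
#' plant chromosomes.
#'
#' @param genome a [genome_spec()].
#' @param genes_per_mb genome-wide average gene density.
#' @param mean_len_bp mean gene length (exponential).
#' @param floor relative density inside zero/low-intensity regions.
#' @param seed RNG seed.
#' @return data.frame in the [read_gff3()] layout (`gene`, `chrom`,
#'   `start` 0-based, `end` exclusive, `strand`).
#' @export
simulate_gene_models <- function(genome, genes_per_mb = 20,
                                 mean_len_bp = 3000, floor = 0.1,
                                 seed = 1) {
  rng <- local_rng(seed)
  out <- lapply(names(genome$chrom_lengths), function(ch) {
    L <- genome$chrom_lengths[[ch]]
    n <- round(genes_per_mb * L / 1e6)
    grid <- seq(1, L - mean_len_bp, length.out = 20000)
    seg <- genome$intensity[genome$intensity$chrom == ch, , drop = FALSE]
    idx <- findInterval(grid, c(seg$start_bp[1], seg$end_bp))
    idx <- pmin(pmax(idx, 1), nrow(seg))
    w <- seg$cm_per_mb[idx]
    w <- pmax(w, floor * max(w))
    starts <- sort(round(grid[rng$sample(length(grid), n, replace = TRUE,
                                         prob = w)]))
    lens <- pmax(200, round(-mean_len_bp * log(rng$runif(n))))
    data.frame(gene = sprintf("%s_G%05d", ch, seq_len(n)), chrom = ch,
               start = starts, end = pmin(starts + lens, L),
               strand = ifelse(rng$runif(n) < 0.5, "+", "-"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
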