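#' Simulate chromosome sequences and marker flanking sequences
#'
#' Generates random chromosome sequences for a genome spec and extracts
#' each marker's flanking context (`flank_len` bp either side of the SNP
#' position, `2 * flank_len + 1` bp total) as the query set for physical
#' anchoring. Optionally a subset of markers is additionally copied, with
#' small sequence divergence, to a second genomic location to create
#' paralogous multi-hit cases.
#'
#' @param genome a [genome_spec()]. Chromosome lengths should be modest
#'   (sub-Mb) for sequence work; marker positions must be farther than
#'   `flank_len` from the chromosome ends.
#' @param flank_len flanking length either side of the marker (>= 10).
#' @param n_paralogs number of markers to duplicate elsewhere.
#' @param paralog_divergence per-base substitution probability applied to
#'   the duplicated copy.
#' @param seed RNG seed.
#' @return list with `chromosomes` (named `Biostrings::DNAStringSet`),
#'   `flanks` (named `DNAStringSet`, one 121-bp record per marker at the
#'   default flank), and `paralogs` (data.frame marker, chrom, pos_bp of
#'   the second copy; empty when `n_paralogs = 0`).
#' @export
simulate_marker_sequences <- function(genome, flank_len = 60,
                                      n_paralogs = 0,
                                      paralog_divergence = 0.02,
                                      seed = 1) {
  stopifnot(inherits(genome, "genome_spec"), flank_len >= 10,
            n_paralogs >= 0)
  mk <- genome$markers
  ctx <- 2 * flank_len + 1
  for (ch in unique(mk$chrom)) {
    p <- mk$pos_bp[mk$chrom == ch]
    L <- genome$chrom_lengths[[ch]]
    if (any(p - flank_len < 1) || any(p + flank_len > L))
      stop("marker closer than flank_len to a chromosome end on ", ch)
    if (any(diff(p) < ctx))
      stop("overlapping marker contexts on ", ch)
  }
  rng <- local_rng(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(genome$chrom_lengths, function(L)
    paste(bases[rng$sample(4, L, replace = TRUE)], collapse = ""))

  flanks <- character(nrow(mk))
  for (i in seq_len(nrow(mk))) {
    flanks[i] <- substr(seqs[[mk$chrom[i]]],
                        mk$pos_bp[i] - flank_len, mk$pos_bp[i] + flank_len)
  }
  names(flanks) <- mk$marker

  paralogs <- data.frame(marker = character(), chrom = character(),
                         pos_bp = integer())
  if (n_paralogs > 0) {
    if (n_paralogs > nrow(mk)) stop("n_paralogs exceeds marker count")
    chosen <- sort(rng$sample(nrow(mk), n_paralogs))
    for (i in chosen) {
      copy <- mutate_seq(flanks[i], paralog_divergence, rng)
      # place the copy on a random chromosome, clear of marker contexts
      for (try in 1:100) {
        ch <- unique(mk$chrom)[rng$sample(length(unique(mk$chrom)), 1)]
        L <- genome$chrom_lengths[[ch]]
        pos <- round(rng$runif(1, flank_len + 1, L - flank_len - 1))
        near <- mk$pos_bp[mk$chrom == ch]
        near <- c(near, paralogs$pos_bp[paralogs$chrom == ch])
        if (all(abs(near - pos) > ctx)) break
      }
      substr(seqs[[ch]], pos - flank_len, pos + flank_len) <- copy
      paralogs <- rbind(paralogs,
                        data.frame(marker = mk$marker[i], chrom = ch,
                                   pos_bp = pos))
    }
  }

  list(chromosomes = Biostrings::DNAStringSet(unlist(seqs)),
       flanks = Biostrings::DNAStringSet(flanks),
       paralogs = paralogs)
}

mutate_seq <- function(s, rate, rng) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- which(rng$runif(length(v)) < rate)
  for (i in hit) {
    v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[rng$sample(3, 1)]
  }
  paste(v, collapse = "")
}
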