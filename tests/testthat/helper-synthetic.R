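# Shared fixture builders. Everything is generated in code at test time.

# A tiny genome: `n_chrom` chromosomes of `len` bp with uniform intensity
# `rate` cM/Mb and `m` evenly spaced markers per chromosome.
tiny_genome <- function(n_chrom = 1, m = 4, len = 10e6, rate = 2) {
  lens <- stats::setNames(rep(len, n_chrom), sprintf("chr%d", seq_len(n_chrom)))
  markers <- do.call(rbind, lapply(names(lens), function(ch)
    data.frame(marker = sprintf("%s_m%d", ch, seq_len(m)), chrom = ch,
               pos_bp = round(seq(len / (m + 1), len * m / (m + 1),
                                  length.out = m)))))
  genome_spec(lens, markers, base_rate = rate)
}

# Genotype matrix from a character vector per line (strings of A/B/H/-)
calls_from_strings <- function(..., markers = NULL) {
  rows <- list(...)
  mat <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  mat[mat == "-"] <- NA_character_
  rownames(mat) <- sprintf("L%02d", seq_len(nrow(mat)))
  colnames(mat) <- if (is.null(markers))
    sprintf("m%d", seq_len(ncol(mat))) else markers
  mat
}

# Truth genetic map (data.frame in genetic_map layout) from a genome spec
truth_map_of <- function(genome) {
  mk <- genome$markers
  cm <- numeric(nrow(mk))
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    cm[idx] <- genetic_pos(genome, ch, mk$pos_bp[idx])
  }
  out <- data.frame(linkage_group = mk$chrom, marker = mk$marker, cm = cm,
                    chromosome = mk$chrom, stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

# Synthetic singleton placements at the generating truth positions
truth_placements_of <- function(genome, flank = 60) {
  mk <- genome$markers
  data.frame(marker = mk$marker, status = "singleton", chrom = mk$chrom,
             pos_bp = mk$pos_bp, sstart = mk$pos_bp - flank,
             send = mk$pos_bp + flank, best_evalue = 1e-60,
             next_evalue = NA_real_, stringsAsFactors = FALSE)
}

# Exhaustive SARF minimum over all orders of a small group (oracle)
brute_force_order <- function(group, rf) {
  perms <- recombean:::perms_of(length(group))
  sarf_of <- function(ids) {
    idx <- match(ids, rf$markers)
    sum(rf$r[cbind(idx[-length(idx)], idx[-1])])
  }
  scores <- apply(perms, 1, function(p) sarf_of(group[p]))
  list(order = group[perms[which.min(scores), ]], sarf = min(scores))
}

# Brute-force two-sided Fisher p by enumeration with choose() (oracle,
# independent of dhyper)
fisher_oracle <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; r2 <- n21 + n22; c1 <- n11 + n21
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- prob[ks == n11]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
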