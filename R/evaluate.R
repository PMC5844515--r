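#' Score an estimated marker order against the generating truth
#'
#' Two metrics over truth-adjacent marker pairs, after orienting each
#' estimated group to the truth: `adjacency_kept`, the fraction still
#' adjacent in the estimate, and `relative_order`, the fraction whose
#' relative order is preserved (an adjacent swap costs one pair under the
#' second metric but breaks two adjacencies under the first).
#'
#' @param ordered_groups list of ordered marker id vectors (one per
#'   linkage group).
#' @param genome the generating [genome_spec()].
#' @return list with `adjacency_kept`, `relative_order`, `n_pairs`.
#' @export
order_accuracy <- function(ordered_groups, genome) {
  tot <- 0L; kept <- 0L; ordok <- 0L
  for (est in ordered_groups) {
    ch <- genome$markers$chrom[match(est[1], genome$markers$marker)]
    tr <- genome$markers$marker[genome$markers$chrom == ch]
    tr <- tr[tr %in% est]
    if (length(tr) < 2) next
    if (stats::cor(match(est, tr), seq_along(est),
                   use = "complete.obs") < 0) est <- rev(est)
    adj_e <- c(paste(est[-length(est)], est[-1]),
               paste(est[-1], est[-length(est)]))
    kept <- kept + sum(paste(tr[-length(tr)], tr[-1]) %in% adj_e)
    pos <- match(tr, est)
    ordok <- ordok + sum(pos[-1] > pos[-length(pos)])
    tot <- tot + length(tr) - 1L
  }
  list(adjacency_kept = kept / tot, relative_order = ordok / tot,
       n_pairs = tot)
}

#' Jaccard overlap between detected and truth pCENR intervals
#'
#' @param detected data.frame from [detect_pcenr()] (primary rows used).
#' @param truth data.frame with `chrom`, `start_bp`, `end_bp`.
#' @return data.frame with per-chromosome `jaccard` and its mean as the
#'   `"mean"` attribute; chromosomes with a truth interval but no call
#'   score 0.
#' @export
pcenr_jaccard <- function(detected, truth) {
  det <- detected[detected$primary, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    ch <- truth$chrom[i]
    d <- det[det$chrom == ch, , drop = FALSE]
    j <- 0
    if (nrow(d)) {
      inter <- max(0, min(d$end_bp[1], truth$end_bp[i]) -
                     max(d$start_bp[1], truth$start_bp[i]))
      uni <- max(d$end_bp[1], truth$end_bp[i]) -
        min(d$start_bp[1], truth$start_bp[i])
      j <- inter / uni
    }
    data.frame(chrom = ch, jaccard = j)
  }))
  attr(out, "mean") <- mean(out$jaccard)
  out
}
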