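#' Sliding-window skeletons over chromosomes
#'
#' Windows of `size` bp every `step` bp, starting at 0 (0-based
#' half-open). Chromosomes shorter than `size` yield a single truncated,
#' flagged window.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param size window size in bp (default 1 Mb).
#' @param step walk speed in bp (default 200 kb; must not exceed
#'   `size`).
#' @return data.frame with `chrom`, `start`, `end`, `truncated`.
#' @export
make_windows <- function(chrom_lengths, size = 1e6, step = 2e5) {
  stopifnot(size >= step, step > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < size)
      return(data.frame(chrom = ch, start = 0, end = L, truncated = TRUE))
    starts <- seq(0, L - size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + size,
               truncated = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate windows with gene density, recombination rate and mean LD
#'
#' Gene count is the number of gene intervals sharing at least one base
#' with the window (half-open intersection; containment mode by flag);
#' recombination rate is the Marey-fit genetic span of the window divided
#' by its width (cM/bp); mean r-squared (percent) is averaged over pairs
#' whose two markers both lie inside the window.
#'
#' @param windows data.frame from [make_windows()].
#' @param genes data.frame from [read_gff3()].
#' @param fits named list of `marey_fit` objects (per chromosome).
#' @param pairs optional [pairwise_ld()] table computed with
#'   `placements`, for the mean r-squared column.
#' @param placements optional [classify_hits()] table giving marker bp
#'   positions (required with `pairs`).
#' @param containment count only genes fully inside the window.
#' @return the windows table with `n_genes`, `rate_cm_bp`, `mean_r2_pct`,
#'   `n_pairs` columns.
#' @export
annotate_windows <- function(windows, genes, fits = NULL, pairs = NULL,
                             placements = NULL, containment = FALSE) {
  windows$n_genes <- 0L
  windows$rate_cm_bp <- NA_real_
  windows$mean_r2_pct <- NA_real_
  windows$n_pairs <- 0L

  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    w <- windows[wi, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g)) {
      ir_w <- IRanges::IRanges(start = w$start + 1L, end = w$end)
      ir_g <- IRanges::IRanges(start = g$start + 1L, end = g$end)
      if (containment) {
        ov <- IRanges::findOverlaps(ir_g, ir_w, type = "within")
        windows$n_genes[wi] <- tabulate(S4Vectors::subjectHits(ov),
                                        nbins = length(ir_w))
      } else {
        windows$n_genes[wi] <- IRanges::countOverlaps(ir_w, ir_g)
      }
    }
    if (!is.null(fits) && !is.null(fits[[ch]])) {
      cm_s <- marey_predict(fits[[ch]], w$start)
      cm_e <- marey_predict(fits[[ch]], w$end)
      windows$rate_cm_bp[wi] <- (cm_e - cm_s) / (w$end - w$start)
    }
    if (!is.null(pairs) && !is.null(placements)) {
      pl <- placements[!is.na(placements$chrom) & placements$chrom == ch, ]
      bp <- stats::setNames(pl$pos_bp, pl$marker)
      pp <- pairs[pairs$m1 %in% pl$marker & pairs$m2 %in% pl$marker &
                    !is.na(pairs$r2), , drop = FALSE]
      if (nrow(pp)) {
        b1 <- bp[pp$m1]; b2 <- bp[pp$m2]
        for (k in seq_along(wi)) {
          inside <- b1 >= w$start[k] & b1 < w$end[k] &
            b2 >= w$start[k] & b2 < w$end[k]
          if (any(inside)) {
            windows$mean_r2_pct[wi[k]] <- 100 * mean(pp$r2[inside])
            windows$n_pairs[wi[k]] <- sum(inside)
          }
        }
      }
    }
  }
  windows
}

#' Correlation between two window statistics
#'
#' Pearson correlation with a t-approximation p-value, plus the Spearman
#' rank alternative. Overlapping windows are statistically dependent;
#' the p-values carry that caveat in the `note` field rather than a
#' correction, reproducing the usual sliding-window practice.
#'
#' @param x,y paired numeric vectors; pairs with missing values are
#'   dropped.
#' @return list with `n`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `note`; statistics are `NA` when fewer than 3 pairs
#'   remain or either input has zero variance.
#' @export
correlate_windows <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(n = length(x), pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                note = "undefined: fewer than 3 pairs or zero variance"))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(n = length(x),
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       note = "overlapping windows are dependent; p-values uncorrected")
}
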