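#' Filter markers on MAF and call rate
#'
#' A marker is retained when its minor allele frequency exceeds
#' `maf_min` (strictly) and its fraction of successful calls (non-missing
#' cells, heterozygous calls count as calls) is at least
#' `call_rate_min`.
#'
#' @param calls genotype matrix (lines x markers).
#' @param maf_min strict lower MAF bound (default 0.05).
#' @param call_rate_min minimum call rate (default 0.80, inclusive).
#' @return character vector of retained marker ids.
#' @export
filter_markers <- function(calls, maf_min = 0.05, call_rate_min = 0.80) {
  call_rate <- colMeans(!is.na(calls))
  maf <- apply(calls, 2, function(x) allele_freq(x)$maf)
  keep <- !is.na(maf) & maf > maf_min & call_rate >= call_rate_min
  colnames(calls)[keep]
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: with margins fixed, the p-value is the sum
#' of hypergeometric probabilities of all tables at most as probable as
#' the observed one. Any zero margin gives p = 1.
#'
#' @param n11,n12,n21,n22 non-negative integer cell counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(n11, n12, n21, n22) {
  stopifnot(n11 >= 0, n12 >= 0, n21 >= 0, n22 >= 0)
  r1 <- n11 + n12; c1 <- n11 + n21; n <- n11 + n12 + n21 + n22
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- stats::dhyper(n11, c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pairwise linkage disequilibrium table
#'
#' Inbred genotypes are treated as haplotypes (A/B calls, heterozygous
#' and missing excluded pairwise). For each marker pair with at least
#' `min_lines` informative lines and both markers polymorphic in scope,
#' computes haplotype counts, `D = p_AB - p_A p_B`, `D' = |D| / D_max`,
#' `r^2 = D^2 / (p_A q_A p_B q_B)`, and (optionally) the two-sided
#' Fisher exact p. Genetic distance is attached for same-group pairs
#' from `map`, physical distance for same-chromosome pairs from
#' `placements`.
#'
#' @param calls genotype matrix.
#' @param lines optional subset of line ids defining the scope.
#' @param scope label stored in the output's `scope` column.
#' @param map optional `genetic_map` for cM distances.
#' @param placements optional [classify_hits()] table for bp distances.
#' @param with_p compute Fisher exact p-values (default TRUE).
#' @param min_lines minimum informative lines per pair.
#' @return data.frame with one row per retained pair: `m1`, `m2`,
#'   `scope`, `n`, `n11`..`n22` (AB haplotype counts), `D`, `Dprime`,
#'   `r2`, `p`, `dist_cm`, `dist_bp`, `same_group`, `same_chrom`.
#' @export
pairwise_ld <- function(calls, lines = NULL, scope = "global", map = NULL,
                        placements = NULL, with_p = TRUE, min_lines = 4) {
  if (!is.null(lines)) calls <- calls[rownames(calls) %in% lines, , drop = FALSE]
  m <- ncol(calls)
  if (m < 2) stop("need at least two markers")
  A <- (calls == "A"); A[is.na(A)] <- FALSE
  B <- (calls == "B"); B[is.na(B)] <- FALSE
  storage.mode(A) <- "numeric"; storage.mode(B) <- "numeric"
  nAA <- crossprod(A); nAB <- crossprod(A, B)
  nBA <- crossprod(B, A); nBB <- crossprod(B)

  pair_idx <- which(upper.tri(nAA), arr.ind = TRUE)
  i <- pair_idx[, 1]; j <- pair_idx[, 2]
  n11 <- nAA[pair_idx]; n12 <- nAB[pair_idx]
  n21 <- nBA[pair_idx]; n22 <- nBB[pair_idx]
  n <- n11 + n12 + n21 + n22

  pA <- (n11 + n12) / n                   # freq of allele A at marker 1
  pB <- (n11 + n21) / n                   # freq of allele A at marker 2
  keep <- n >= min_lines & pA > 0 & pA < 1 & pB > 0 & pB < 1
  i <- i[keep]; j <- j[keep]
  n11 <- n11[keep]; n12 <- n12[keep]; n21 <- n21[keep]; n22 <- n22[keep]
  n <- n[keep]; pA <- pA[keep]; pB <- pB[keep]

  D <- n11 / n - pA * pB
  qA <- 1 - pA; qB <- 1 - pB
  dmax <- ifelse(D >= 0, pmin(pA * qB, qA * pB), pmin(pA * pB, qA * qB))
  dprime <- ifelse(dmax > 0, abs(D) / dmax, 0)
  r2 <- ifelse(pA * qA * pB * qB > 0, D^2 / (pA * qA * pB * qB), NA)

  p <- rep(NA_real_, length(n))
  if (with_p && length(n))
    p <- vapply(seq_along(n), function(k)
      fisher_exact_2x2(n11[k], n12[k], n21[k], n22[k]), numeric(1))

  out <- data.frame(m1 = colnames(calls)[i], m2 = colnames(calls)[j],
                    scope = scope, n = n, n11 = n11, n12 = n12,
                    n21 = n21, n22 = n22, D = D, Dprime = dprime,
                    r2 = r2, p = p,
                    dist_cm = NA_real_, dist_bp = NA_real_,
                    same_group = NA, same_chrom = NA,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    pos <- stats::setNames(map$cm, map$marker)
    grp <- stats::setNames(map$linkage_group, map$marker)
    g1 <- grp[out$m1]; g2 <- grp[out$m2]
    out$same_group <- !is.na(g1) & !is.na(g2) & g1 == g2
    sg <- which(out$same_group)
    out$dist_cm[sg] <- abs(pos[out$m1[sg]] - pos[out$m2[sg]])
  }
  if (!is.null(placements)) {
    pl <- placements[!is.na(placements$chrom), , drop = FALSE]
    chr <- stats::setNames(pl$chrom, pl$marker)
    bp <- stats::setNames(pl$pos_bp, pl$marker)
    c1 <- chr[out$m1]; c2 <- chr[out$m2]
    out$same_chrom <- !is.na(c1) & !is.na(c2) & c1 == c2
    sc <- which(out$same_chrom)
    out$dist_bp[sc] <- abs(bp[out$m1[sc]] - bp[out$m2[sc]])
  }
  rownames(out) <- NULL
  out
}

#' Fit an LD decay curve and the distance to an r-squared threshold
#'
#' Restricts to same-group (or same-chromosome, for bp distances) pairs
#' with `p < p_max` and fits two curves to r-squared versus distance: a
#' second-degree polynomial (the regression model the decay distance is
#' read from) and an exponential tendency line `a exp(-b d) + c`,
#' reported when its F-test against the constant model is significant
#' at 0.05. The decay distance is the smallest distance at which the
#' fitted polynomial crosses `threshold` within the observed range
#' (`NA` = no crossing). The significance screen keeps only pairs whose
#' r-squared is individually distinguishable from zero, which floors
#' the r-squared of retained distant pairs; an exponential's asymptote
#' can therefore sit above the threshold even when LD has fully
#' decayed, and its crossing (when one exists) is reported separately
#' as `decay_distance_exp`. Binned mean r-squared values are attached
#' for plotting.
#'
#' @param pairs a [pairwise_ld()] table.
#' @param distance `"cm"` or `"bp"`.
#' @param p_max pair-inclusion p-value screen (strict, default 0.001).
#' @param threshold r-squared decay threshold (default 0.1).
#' @param min_pairs minimum qualifying pairs.
#' @param n_bins bins for the binned means.
#' @return list of class `ld_decay`: `coef` (polynomial), `exp_coef`
#'   (`NULL` unless converged), `exp_significant`, `decay_distance`
#'   (polynomial crossing), `decay_distance_exp`, `threshold`,
#'   `n_pairs`, `curve` (fitted grids), `bins`, and
#'   `binned_decay_distance` (first bin midpoint whose mean falls below
#'   the threshold).
#' @export
ld_decay <- function(pairs, distance = c("cm", "bp"), p_max = 0.001,
                     threshold = 0.1, min_pairs = 10, n_bins = 15) {
  distance <- match.arg(distance)
  d <- if (distance == "cm") pairs$dist_cm else pairs$dist_bp
  use <- !is.na(d) & !is.na(pairs$r2)
  if (p_max < 1) use <- use & !is.na(pairs$p) & pairs$p < p_max
  d <- d[use]; r2 <- pairs$r2[use]
  if (length(d) < min_pairs)
    stop("too few qualifying pairs (", length(d), " < ", min_pairs, ")")

  poly_fit <- stats::lm(r2 ~ d + I(d^2))
  exp_fit <- tryCatch(
    minpack.lm::nlsLM(r2 ~ a * exp(-b * d) + c,
                      start = list(a = max(r2) - min(r2) + 1e-3,
                                   b = 1 / max(stats::median(d), 1e-6),
                                   c = min(r2)),
                      lower = c(a = 0, b = 1e-9, c = -0.5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  exp_p <- NA_real_
  exp_coef <- NULL
  if (!is.null(exp_fit)) {
    exp_coef <- stats::coef(exp_fit)
    rss0 <- sum((r2 - mean(r2))^2)
    rss1 <- sum(stats::residuals(exp_fit)^2)
    df2 <- length(d) - 3
    fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
    exp_p <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  }
  pc <- stats::coef(poly_fit)
  grid <- seq(min(d), max(d), length.out = 512)
  poly_grid <- pc[[1]] + pc[[2]] * grid + pc[[3]] * grid^2
  cross <- which(poly_grid <= threshold)
  decay_distance <- if (length(cross)) grid[cross[1]] else NA_real_
  exp_grid <- decay_distance_exp <- NULL
  if (!is.null(exp_coef)) {
    exp_grid <- exp_coef[["a"]] * exp(-exp_coef[["b"]] * grid) +
      exp_coef[["c"]]
    ce <- which(exp_grid <= threshold)
    decay_distance_exp <- if (length(ce)) grid[ce[1]] else NA_real_
  }

  brk <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- pmin(findInterval(d, brk, rightmost.closed = TRUE), n_bins)
  bins <- data.frame(mid = (brk[-1] + brk[-length(brk)]) / 2,
                     mean_r2 = vapply(seq_len(n_bins), function(b)
                       if (any(bin == b)) mean(r2[bin == b]) else NA_real_,
                       numeric(1)),
                     n = tabulate(bin, n_bins))
  below <- which(!is.na(bins$mean_r2) & bins$mean_r2 <= threshold)
  structure(list(coef = pc, exp_coef = exp_coef, exp_p = exp_p,
                 exp_significant = is.finite(exp_p) && exp_p < 0.05,
                 decay_distance = decay_distance,
                 decay_distance_exp = decay_distance_exp,
                 threshold = threshold,
                 n_pairs = length(d), distance = distance,
                 curve = data.frame(d = grid, r2_poly = poly_grid,
                                    r2_exp = if (is.null(exp_grid)) NA_real_
                                    else exp_grid),
                 bins = bins,
                 binned_decay_distance = if (length(below))
                   bins$mid[below[1]] else NA_real_),
            class = "ld_decay")
}

#' Triangular LD matrix for one linkage group
#'
#' Square matrix over the group's markers in map order with r-squared in
#' the upper triangle, p-values in the lower triangle and 1 on the
#' diagonal.
#'
#' @param pairs a [pairwise_ld()] table (computed with p-values).
#' @param markers ordered marker ids (map order).
#' @return numeric matrix.
#' @export
ld_matrix <- function(pairs, markers) {
  m <- length(markers)
  out <- matrix(NA_real_, m, m, dimnames = list(markers, markers))
  diag(out) <- 1
  sub <- pairs[pairs$m1 %in% markers & pairs$m2 %in% markers, , drop = FALSE]
  i <- match(sub$m1, markers); j <- match(sub$m2, markers)
  lo <- pmin(i, j); hi <- pmax(i, j)
  out[cbind(lo, hi)] <- sub$r2       # upper triangle: r2
  out[cbind(hi, lo)] <- sub$p        # lower triangle: p
  out
}
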