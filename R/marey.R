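#' Build Marey curves from a genetic map and physical placements
#'
#' Joins map and placement tables on marker id (singleton placements
#' only), one curve per labeled chromosome. Each chromosome's genetic
#' coordinates are oriented so cM correlates positively with bp
#' (reversed otherwise), and points breaking monotonicity beyond
#' `monotone_tol` against an immediate neighbor are flagged - not
#' dropped - as discordant.
#'
#' @param map a `genetic_map` with chromosome labels (see
#'   [place_anchors()]).
#' @param placements data.frame from [classify_hits()].
#' @param monotone_tol cM tolerance before a neighbor violation is
#'   flagged.
#' @return named list of `marey_curve` objects, each a list with
#'   `chrom`, `points` (data.frame `marker`, `bp`, `cm`, `flagged`,
#'   sorted by bp) and `fittable` (at least 3 shared markers).
#' @export
build_marey <- function(map, placements, monotone_tol = 1e-6) {
  singles <- placements[placements$status == "singleton", , drop = FALSE]
  joined <- merge(as.data.frame(map), singles[, c("marker", "chrom", "pos_bp")],
                  by = "marker")
  joined <- joined[!is.na(joined$chromosome) &
                     joined$chromosome == joined$chrom, , drop = FALSE]
  curves <- lapply(split(joined, joined$chromosome), function(d) {
    d <- d[order(d$pos_bp), , drop = FALSE]
    cm <- d$cm
    if (nrow(d) >= 2 &&
        !is.na(stats::cor(d$pos_bp, cm)) && stats::cor(d$pos_bp, cm) < 0)
      cm <- max(cm) - cm
    cm <- cm - min(cm)                  # zero-base the oriented coordinates
    n <- nrow(d)
    flagged <- rep(FALSE, n)
    if (n >= 2) {
      back <- c(FALSE, cm[-1] < cm[-n] - monotone_tol)
      fwd <- c(cm[-n] > cm[-1] + monotone_tol, FALSE)
      flagged <- back | fwd
    }
    structure(list(chrom = d$chromosome[1],
                   points = data.frame(marker = d$marker, bp = d$pos_bp,
                                       cm = cm, flagged = flagged,
                                       stringsAsFactors = FALSE),
                   fittable = n >= 3),
              class = "marey_curve")
  })
  curves
}

#' Fit a polynomial Marey curve with isotonic adjustment
#'
#' Least-squares polynomial of the configured degree on the (bp, cM)
#' points (duplicate bp positions are averaged first), followed by an
#' isotonic projection of the fitted values so the curve - and hence the
#' derivative-based recombination rate - is non-decreasing.
#'
#' @param curve a `marey_curve` from [build_marey()].
#' @param degree polynomial degree (default 7). A cubic can draw a single
#'   sigmoid but its derivative (a parabola) cannot hold a long
#'   near-zero plateau between two steep arms; degree 7 expresses the
#'   plateau-and-arms shape well at typical marker densities.
#' @return object of class `marey_fit`: list with `chrom`, `coef`,
#'   `degree`, `points` (with `fitted` and `adjusted` columns), and the
#'   observed bp `range`.
#' @export
fit_marey <- function(curve, degree = 7) {
  if (!curve$fittable) stop("curve on ", curve$chrom, " is unfittable")
  pts <- curve$points
  if (anyDuplicated(pts$bp)) {
    agg <- stats::aggregate(cm ~ bp, data = pts, FUN = mean)
    pts <- data.frame(marker = NA_character_, bp = agg$bp, cm = agg$cm)
  }
  if (nrow(pts) < degree + 2)
    stop("need at least degree + 2 points on ", curve$chrom)
  fit <- stats::lm(cm ~ poly(bp, degree, raw = TRUE), data = pts)
  fitted <- stats::fitted(fit)
  adjusted <- stats::isoreg(pts$bp, fitted)$yf
  structure(list(chrom = curve$chrom, coef = stats::coef(fit),
                 degree = degree,
                 points = data.frame(bp = pts$bp, cm = pts$cm,
                                     fitted = fitted, adjusted = adjusted),
                 range = range(pts$bp)),
            class = "marey_fit")
}

poly_eval <- function(coef, x) {
  out <- rep(coef[1], length(x))
  for (k in seq_len(length(coef) - 1)) out <- out + coef[k + 1] * x^k
  unname(out)
}

#' Predict isotonic-adjusted genetic positions from a Marey fit
#'
#' Evaluates the fitted polynomial on the query positions (clamped to the
#' observed bp range to avoid extrapolation) and projects the values to
#' the nearest non-decreasing sequence.
#'
#' @param fit a `marey_fit`.
#' @param bp physical positions.
#' @return predicted cM, non-decreasing in bp.
#' @export
marey_predict <- function(fit, bp) {
  bp_cl <- pmin(pmax(bp, fit$range[1]), fit$range[2])
  ord <- order(bp_cl)
  vals <- poly_eval(fit$coef, bp_cl[ord])
  adj <- stats::isoreg(seq_along(vals), vals)$yf
  out <- numeric(length(bp))
  out[ord] <- adj
  out
}

#' Local recombination rate from a Marey fit
#'
#' The derivative of the adjusted fit, evaluated by finite differences on
#' a fine grid over the observed bp range.
#'
#' @param fit a `marey_fit`.
#' @param bp positions at which to report the rate (cM/Mb); default a
#'   512-step grid.
#' @param grid_n grid resolution.
#' @return data.frame with `bp` (interval midpoints when `bp` is NULL)
#'   and `rate_cm_mb`.
#' @export
local_rate <- function(fit, bp = NULL, grid_n = 512) {
  grid <- seq(fit$range[1], fit$range[2], length.out = grid_n + 1)
  vals <- marey_predict(fit, grid)
  rate <- diff(vals) / diff(grid) * 1e6
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  if (is.null(bp)) return(data.frame(bp = mids, rate_cm_mb = rate))
  idx <- pmin(pmax(findInterval(bp, grid, all.inside = TRUE), 1),
              length(rate))
  data.frame(bp = bp, rate_cm_mb = rate[idx])
}

#' Detect pericentromeric low-recombination plateaus
#'
#' Two-level (hysteresis) scan of the local rate profile: a plateau
#' exists wherever the rate falls below the core floor (`rate_floor`,
#' by default 10% of the supplied genome-wide mean - "almost no
#' recombination"), and each core is then extended outward to where the
#' rate rises through the edge level (`edge_frac` of the genome mean).
#' The polynomial fit necessarily rounds the shoulders of a plateau, so
#' the mid-level crossing localizes the true boundary far better than
#' the core floor itself. Overlapping extended intervals merge; the
#' largest is the primary pCENR call, others are secondary.
#'
#' @param fit a `marey_fit`.
#' @param genome_mean_rate genome-wide mean recombination rate (cM/Mb)
#'   used to derive the default floor and the edge level.
#' @param rate_floor explicit core floor in cM/Mb (overrides the
#'   default).
#' @param edge_frac edge-localization level as a fraction of
#'   `genome_mean_rate` (ignored when that is not supplied).
#' @param grid_n grid resolution for the rate profile.
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `primary`;
#'   zero rows when no plateau exists.
#' @export
detect_pcenr <- function(fit, genome_mean_rate = NULL, rate_floor = NULL,
                         edge_frac = 0.5, grid_n = 512) {
  if (is.null(rate_floor)) {
    if (is.null(genome_mean_rate))
      stop("supply rate_floor or genome_mean_rate")
    rate_floor <- 0.1 * genome_mean_rate
  }
  edge_level <- if (is.null(genome_mean_rate)) rate_floor else
    max(rate_floor, edge_frac * genome_mean_rate)
  prof <- local_rate(fit, grid_n = grid_n)
  below <- prof$rate_cm_mb < rate_floor
  if (!any(below))
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), primary = logical()))
  soft <- prof$rate_cm_mb < edge_level
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  keep <- which(r$values)
  n <- nrow(prof)
  iv_idx <- lapply(keep, function(k) {
    lo <- starts[k]; hi <- ends[k]
    while (lo > 1 && soft[lo - 1]) lo <- lo - 1
    while (hi < n && soft[hi + 1]) hi <- hi + 1
    c(lo, hi)
  })
  # merge overlapping extended cores
  iv_idx <- iv_idx[order(vapply(iv_idx, `[`, numeric(1), 1))]
  merged <- list()
  for (iv in iv_idx) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && iv[1] <= last[2] + 1)
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[2]))
    else merged[[length(merged) + 1]] <- iv
  }
  step <- diff(prof$bp[1:2])
  iv <- data.frame(chrom = fit$chrom,
                   start_bp = vapply(merged, function(m)
                     prof$bp[m[1]], numeric(1)) - step / 2,
                   end_bp = vapply(merged, function(m)
                     prof$bp[m[2]], numeric(1)) + step / 2)
  iv$primary <- seq_len(nrow(iv)) == which.max(iv$end_bp - iv$start_bp)
  iv[order(-iv$primary, iv$start_bp), ]
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Genetic/physical landscape summary
#'
#' Computes the per-chromosome and genome-wide genetic-to-physical
#' summary statistics: the G/P ratio in cM/Mb (2 decimals, half-up), bp
#' per cM, the genome ratio from summed totals (never the mean of
#' per-chromosome ratios - the two differ and both are reported), the
#' mean and population SD of the per-chromosome ratios, average group
#' length, average inter-marker spacing, and the Pearson correlation of
#' group genetic length with chromosome physical length.
#'
#' @param tbl data.frame with one row per chromosome: `chromosome`,
#'   `cm` (group genetic length), `bp` (chromosome physical length) and
#'   optionally `n_markers`, `cm_initial`, `n_markers_initial`.
#' @param totals optional list overriding the summed totals (e.g. the
#'   printed totals row of a published table) with any of `cm`, `bp`,
#'   `n_markers`, `cm_initial`, `n_markers_initial`.
#' @return list of class `landscape_summary`.
#' @export
landscape_summary <- function(tbl, totals = NULL) {
  stopifnot(all(c("chromosome", "cm", "bp") %in% names(tbl)))
  per <- data.frame(chromosome = tbl$chromosome, cm = tbl$cm, bp = tbl$bp)
  per$ratio_cm_mb <- round_half_up(per$cm / (per$bp / 1e6), 2)
  per$bp_per_cm <- round_half_up(per$bp / per$cm, 0)
  tot <- list(cm = sum(tbl$cm), bp = sum(tbl$bp),
              n_markers = if ("n_markers" %in% names(tbl))
                sum(tbl$n_markers) else NA,
              cm_initial = if ("cm_initial" %in% names(tbl))
                sum(tbl$cm_initial) else NA,
              n_markers_initial = if ("n_markers_initial" %in% names(tbl))
                sum(tbl$n_markers_initial) else NA)
  if (!is.null(totals)) tot[names(totals)] <- totals
  n_chr <- nrow(per)
  ratios <- per$ratio_cm_mb
  out <- list(
    per_chromosome = per,
    genome_ratio_cm_mb = round_half_up(tot$cm / (tot$bp / 1e6), 2),
    ratio_mean = round_half_up(mean(ratios), 2),
    ratio_sd = round_half_up(sqrt(mean((ratios - mean(ratios))^2)), 2),
    avg_group_cm = round_half_up(tot$cm / n_chr, 1),
    bp_per_cm = round_half_up(tot$bp / tot$cm, 0),
    avg_marker_spacing_cm = if (!is.na(tot$n_markers))
      round_half_up(tot$cm / tot$n_markers, 2) else NA,
    bp_per_cm_initial = if (!is.na(tot$cm_initial))
      round_half_up(tot$bp / tot$cm_initial, 0) else NA,
    avg_marker_spacing_cm_initial =
      if (!is.na(tot$cm_initial) && !is.na(tot$n_markers_initial))
        round_half_up(tot$cm_initial / tot$n_markers_initial, 1) else NA,
    cor_cm_bp = if (n_chr >= 3) stats::cor(per$cm, per$bp) else NA,
    totals = tot
  )
  class(out) <- "landscape_summary"
  out
}

#' @export
print.landscape_summary <- function(x, ...) {
  print(x$per_chromosome)
  cat(sprintf("genome G/P ratio: %.2f cM/Mb; per-chromosome mean %.2f +/- %.2f\n",
              x$genome_ratio_cm_mb, x$ratio_mean, x$ratio_sd))
  invisible(x)
}

#' Published reference map summary for common bean
#'
#' The per-linkage-group summary of the BAT93 x Jalo EEP558 SNP + legacy
#' marker reference map on the G19833 v1.0 assembly: marker counts and
#' map lengths for the initial (all-marker) and refined (high-LOD) maps,
#' chromosome physical lengths, and the published genetic/physical
#' ratios. The published totals row (which does not equal the column
#' sums for the refined distances and initial marker counts - the table
#' is reproduced as printed) is attached as the `"totals"` attribute.
#'
#' @return data.frame with one row per chromosome Pv1-Pv11.
#' @export
bean_reference_map <- function() {
  df <- data.frame(
    chromosome = sprintf("Pv%d", 1:11),
    n_markers_initial = c(104L, 145L, 119L, 37L, 62L, 101L, 82L, 93L, 90L,
                          43L, 89L),
    cm_initial = c(230.1, 374.5, 191.1, 105.1, 103.9, 171.4, 104.9, 160.9,
                   72.3, 158.6, 89.7),
    n_markers = c(88L, 104L, 84L, 30L, 49L, 85L, 99L, 91L, 83L, 32L, 67L),
    cm = c(147.0, 140.6, 114.4, 84.7, 82.8, 83.7, 108.3, 99.2, 46.5, 72.2,
           67.5),
    bp = c(52159049, 49012014, 52266928, 45799695, 40676787, 31960678,
           51729989, 59650056, 37463265, 43227687, 50184061),
    ratio_cm_mb = c(2.82, 2.87, 2.19, 1.85, 2.04, 2.62, 2.09, 1.66, 1.24,
                    1.67, 1.35),
    stringsAsFactors = FALSE
  )
  attr(df, "totals") <- list(n_markers_initial = 981L, cm_initial = 1762.5,
                             n_markers = 812L, cm = 1097.5, bp = 514130209)
  df
}
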