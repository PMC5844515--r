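#' Kosambi map function
#'
#' Converts a meiotic recombination fraction to a map distance allowing
#' partial crossover interference: `d = 25 * ln((1 + 2r) / (1 - 2r))` cM.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param max_cm distance assigned (with a warning) when `r >= 0.5`.
#' @return distance in cM.
#' @seealso [kosambi_r()] for the inverse.
#' @export
kosambi_cm <- function(r, max_cm = 50) {
  stopifnot(all(r >= 0, na.rm = TRUE))
  out <- 25 * log((1 + 2 * r) / (1 - 2 * r))
  if (any(r >= 0.5, na.rm = TRUE)) {
    warning("r >= 0.5 capped at ", max_cm, " cM")
    out[r >= 0.5] <- max_cm
  }
  out
}

#' Inverse Kosambi map function
#' @param d distance(s) in cM.
#' @return recombination fraction `r = tanh(d / 50) / 2`.
#' @export
kosambi_r <- function(d) {
  stopifnot(all(d >= 0, na.rm = TRUE))
  tanh(d / 50) / 2
}

#' Haldane-Waddington correction for selfing RILs
#'
#' In a fully inbred selfing RIL population the observed recombinant-line
#' fraction `R` relates to the per-meiosis fraction `r` by
#' `R = 2r / (1 + 2r)`; the inverse `r = R / (2(1 - R))` (capped at 0.5)
#' recovers the meiotic fraction before map-distance conversion.
#'
#' @param R observed recombinant fraction(s).
#' @return meiotic recombination fraction(s).
#' @export
hw_correct <- function(R) {
  stopifnot(all(R >= 0 & R <= 1, na.rm = TRUE))
  pmin(R / (2 * (1 - R)), 0.5)
}

#' Forward Haldane-Waddington transform (`r` to expected RIL `R`)
#' @param r meiotic recombination fraction(s).
#' @export
hw_ril <- function(r) 2 * r / (1 + 2 * r)

lod_from_counts <- function(n, n_rec) {
  R <- n_rec / n
  lod <- ifelse(R == 0, n * log10(2),
                ifelse(R == 1, n_rec * log10(2),
                       n_rec * log10(pmax(R, .Machine$double.xmin) / 0.5) +
                         (n - n_rec) * log10((1 - R) / 0.5)))
  lod
}

#' Two-point recombination estimate for one marker pair
#'
#' A line is informative when both calls are in `{A, B}` (heterozygous and
#' missing calls are excluded pairwise) and recombinant when the two calls
#' differ. The observed RIL fraction is corrected to the meiotic scale via
#' [hw_correct()], and the LOD score is
#' `n_R log10(R/0.5) + (n - n_R) log10((1-R)/0.5)`.
#'
#' @param calls genotype matrix (lines x markers).
#' @param m1,m2 marker ids or column indices.
#' @return list of class `two_point` with `n`, `n_rec`, `R`, `r`, `lod`,
#'   or an uninformative sentinel (`n < 2`, all statistics `NA`).
#' @export
estimate_rf <- function(calls, m1, m2) {
  c1 <- calls[, m1]; c2 <- calls[, m2]
  ok <- c1 %in% c("A", "B") & c2 %in% c("A", "B")
  n <- sum(ok)
  if (n < 2) {
    return(structure(list(m1 = m1, m2 = m2, n = n, n_rec = NA_integer_,
                          R = NA_real_, r = NA_real_, lod = NA_real_,
                          informative = FALSE),
                     class = "two_point"))
  }
  n_rec <- sum(c1[ok] != c2[ok])
  R <- n_rec / n
  structure(list(m1 = m1, m2 = m2, n = n, n_rec = n_rec, R = R,
                 r = hw_correct(R), lod = lod_from_counts(n, n_rec),
                 informative = TRUE),
            class = "two_point")
}

#' All-pairs two-point matrices
#'
#' Vectorized computation of informative counts, recombinant counts,
#' observed fraction, HW-corrected fraction and LOD for every marker pair.
#'
#' @param calls genotype matrix.
#' @return list of symmetric matrices `n`, `n_rec`, `R`, `r`, `lod`
#'   (class `rf_matrices`); pairs with fewer than 2 informative lines have
#'   `NA` statistics.
#' @export
rf_matrices <- function(calls) {
  A <- (calls == "A"); A[is.na(A)] <- FALSE
  B <- (calls == "B"); B[is.na(B)] <- FALSE
  storage.mode(A) <- "numeric"; storage.mode(B) <- "numeric"
  n_AA <- crossprod(A); n_BB <- crossprod(B)
  n_AB <- crossprod(A, B); n_BA <- crossprod(B, A)
  n <- n_AA + n_BB + n_AB + n_BA
  n_rec <- n_AB + n_BA
  R <- n_rec / n
  bad <- n < 2
  R[bad] <- NA
  lod <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
  ok <- which(!bad)
  lod[ok] <- lod_from_counts(n[ok], n_rec[ok])
  structure(list(n = n, n_rec = n_rec, R = R, r = hw_correct(R), lod = lod,
                 markers = colnames(calls)),
            class = "rf_matrices")
}

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure over marker pairs with
#' `LOD >= lod_min` and HW-corrected `r <= r_max`. Groups are numbered by
#' their smallest member column index, so the partition is deterministic
#' and invariant to marker order in the input.
#'
#' @param rf an [rf_matrices()] result.
#' @param lod_min minimum LOD to link two markers (default 6, the grouping
#'   threshold used for the reference bean map).
#' @param r_max maximum corrected recombination fraction for a link.
#' @return list of character vectors of marker ids, one per group.
#' @export
group_markers <- function(rf, lod_min = 6, r_max = 0.4) {
  m <- length(rf$markers)
  if (m == 0) return(list())
  adj <- !is.na(rf$lod) & rf$lod >= lod_min & !is.na(rf$r) & rf$r <= r_max
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(m), comp)
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  names(groups) <- NULL
  lapply(groups, function(i) rf$markers[i])
}

sarf <- function(order_idx, rmat) {
  sum(rmat[cbind(order_idx[-length(order_idx)], order_idx[-1])])
}

two_opt <- function(ord, rmat) {
  n <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        if (sarf(cand, rmat) < sarf(ord, rmat) - 1e-12) {
          ord <- cand
          improved <- TRUE
        }
      }
    }
  }
  ord
}

# all permutations of 1..n as a matrix (n! rows); n is tiny (<= 5)
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

# Total crossover breakpoints implied by an order: per line, the number of
# A<->B transitions between consecutive informative calls. `left`/`right`
# carry the flanking states so a window can be scored in isolation.
segment_breaks <- function(calls01, cols, left, right) {
  prev <- left
  total <- 0
  for (cc in cols) {
    cur <- calls01[, cc]
    both <- !is.na(cur) & !is.na(prev)
    total <- total + sum(cur[both] != prev[both])
    obs <- !is.na(cur)
    prev[obs] <- cur[obs]
  }
  both <- !is.na(prev) & !is.na(right)
  total + sum(prev[both] != right[both])
}

# Sliding-window exhaustive "ripple" polish minimizing total breakpoints
# (multipoint double-recombinant parsimony). Strict improvements only, so
# the result is deterministic.
ripple_count <- function(ord, calls01, window = 4) {
  m <- length(ord)
  if (m < 3) return(ord)
  window <- min(window, m)
  perms <- perms_of(window)
  n <- nrow(calls01)
  max_moves <- 10L * m
  for (move in seq_len(max_moves)) {
    # forward carry (state after col j) and backward carry (state from col j)
    ls <- matrix(NA_real_, n, m + 1)
    for (j in seq_len(m)) {
      cur <- calls01[, ord[j]]
      ls[, j + 1] <- ifelse(is.na(cur), ls[, j], cur)
    }
    rs <- matrix(NA_real_, n, m + 1)
    for (j in rev(seq_len(m))) {
      cur <- calls01[, ord[j]]
      rs[, j] <- ifelse(is.na(cur), rs[, j + 1], cur)
    }
    improved <- FALSE
    for (i in seq_len(m - window + 1)) {
      seg <- ord[i:(i + window - 1)]
      left <- ls[, i]
      right <- rs[, i + window]
      scores <- apply(perms, 1, function(p)
        segment_breaks(calls01, seg[p], left, right))
      if (min(scores) < scores[1]) {   # first permutation is the identity
        best <- which.min(scores)
        ord[i:(i + window - 1)] <- seg[perms[best, ]]
        improved <- TRUE
        break                          # recompute carries, then continue
      }
    }
    if (!improved) break
  }
  ord
}

#' Order the markers of a linkage group
#'
#' Minimizes the sum of adjacent recombination fractions (SARF): a greedy
#' path is grown from the tightest pair by appending the nearest unplaced
#' marker at either end, then refined by 2-opt segment reversals to a
#' local optimum. When the genotype matrix is supplied, a sliding-window
#' ripple polish then minimizes the total implied crossover count
#' (multipoint double-recombinant parsimony), which resolves local swaps
#' that two-point statistics cannot distinguish. Ties break toward the
#' lower marker index, and the output orientation is canonicalized
#' (first marker index < last), so the result is deterministic.
#'
#' @param group character vector of marker ids.
#' @param rf an [rf_matrices()] result covering them.
#' @param calls optional genotype matrix enabling the ripple polish.
#' @param ripple_window window size for the exhaustive ripple.
#' @return ordered character vector.
#' @export
order_markers <- function(group, rf, calls = NULL, ripple_window = 4) {
  if (length(group) < 2) return(group)
  idx <- match(group, rf$markers)
  if (anyNA(idx)) stop("group marker absent from rf table")
  rmat <- rf$r[idx, idx, drop = FALSE]
  if (anyNA(rmat[upper.tri(rmat)])) {
    rmat[is.na(rmat)] <- 0.5          # uninformative pairs: maximally loose
  }
  n <- length(idx)
  if (all(!is.finite(rmat[upper.tri(rmat)])))
    stop("disconnected group: no informative pairs")
  diag(rmat) <- Inf
  # greedy seed: tightest pair (ties by lowest flat index)
  best <- which(rmat == min(rmat))[1]
  path <- c((best - 1) %% n + 1, (best - 1) %/% n + 1)
  left <- setdiff(seq_len(n), path)
  while (length(left)) {
    d_head <- rmat[path[1], left]
    d_tail <- rmat[path[length(path)], left]
    if (min(d_head) < min(d_tail) ||
        (min(d_head) == min(d_tail) &&
         left[which.min(d_head)] <= left[which.min(d_tail)])) {
      path <- c(left[which.min(d_head)], path)
    } else {
      path <- c(path, left[which.min(d_tail)])
    }
    left <- setdiff(seq_len(n), path)
  }
  diag(rmat) <- 0
  path <- two_opt(path, rmat)
  if (!is.null(calls)) {
    calls01 <- matrix(NA_real_, nrow(calls), length(group))
    sub <- calls[, group, drop = FALSE]
    calls01[sub == "A"] <- 0
    calls01[sub == "B"] <- 1
    path <- ripple_count(path, calls01, window = ripple_window)
  }
  if (path[1] > path[length(path)]) path <- rev(path)
  group[path]
}

#' Assemble a genetic map from ordered groups
#'
#' Cumulative cM positions are the running sum of Kosambi distances over
#' adjacent HW-corrected recombination fractions.
#'
#' @param ordered_groups list of ordered marker id vectors.
#' @param rf an [rf_matrices()] result.
#' @param max_cm cap passed to [kosambi_cm()] for unlinked adjacencies.
#' @return data.frame of class `genetic_map` with columns
#'   `linkage_group`, `marker`, `cm`, `chromosome` (NA until anchored).
#' @export
assemble_map <- function(ordered_groups, rf, max_cm = 50) {
  rows <- lapply(seq_along(ordered_groups), function(gi) {
    g <- ordered_groups[[gi]]
    if (length(g) == 1) {
      pos <- 0
    } else {
      idx <- match(g, rf$markers)
      radj <- rf$r[cbind(idx[-length(idx)], idx[-1])]
      radj[is.na(radj)] <- 0.5
      pos <- c(0, cumsum(suppressWarnings(kosambi_cm(radj, max_cm))))
    }
    data.frame(linkage_group = sprintf("LG-%d", gi), marker = g, cm = pos,
               chromosome = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Label linkage groups from anchor markers
#'
#' Each anchor marker carries a known chromosome; a group is labeled with
#' the majority label of its anchors. Groups whose anchors disagree with
#' no majority stay unlabeled (`LG-n`), and all conflicts are reported in
#' the `conflicts` attribute. Two groups claiming the same chromosome
#' trigger a warning.
#'
#' @param map a `genetic_map`.
#' @param anchors data.frame with columns `marker`, `chromosome`.
#' @return the map with `chromosome` filled per group.
#' @export
place_anchors <- function(map, anchors) {
  stopifnot(all(c("marker", "chromosome") %in% names(anchors)))
  conflicts <- list()
  labels <- character(0)
  for (g in unique(map$linkage_group)) {
    mk <- map$marker[map$linkage_group == g]
    lab <- anchors$chromosome[anchors$marker %in% mk]
    if (!length(lab)) next
    tab <- sort(table(lab), decreasing = TRUE)
    if (length(tab) > 1) {
      conflicts[[g]] <- tab
      if (tab[1] == tab[2]) next      # no majority: leave unlabeled
    }
    map$chromosome[map$linkage_group == g] <- names(tab)[1]
    labels <- c(labels, names(tab)[1])
  }
  if (anyDuplicated(labels))
    warning("multiple groups claim chromosome(s): ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  attr(map, "conflicts") <- conflicts
  map
}

#' Map summary statistics
#'
#' Per-group marker counts and lengths, total and average group length,
#' average inter-marker distance (total length / total marker count), and
#' a chi-square test of marker counts against a uniform expectation
#' across groups.
#'
#' @param map a `genetic_map`.
#' @return list with `per_group` data.frame, `total_cm`,
#'   `avg_group_cm`, `avg_marker_spacing_cm`, and `chisq`
#'   (statistic, df, p.value).
#' @export
map_summary <- function(map) {
  per_group <- do.call(rbind, lapply(split(map, map$linkage_group), function(d)
    data.frame(linkage_group = d$linkage_group[1],
               chromosome = d$chromosome[1],
               n_markers = nrow(d), length_cm = max(d$cm) - min(d$cm),
               stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  total <- sum(per_group$length_cm)
  cs <- stats::chisq.test(per_group$n_markers)
  list(per_group = per_group,
       total_cm = total,
       avg_group_cm = total / nrow(per_group),
       avg_marker_spacing_cm = total / sum(per_group$n_markers),
       chisq = list(statistic = unname(cs$statistic),
                    df = unname(cs$parameter),
                    p.value = cs$p.value))
}
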