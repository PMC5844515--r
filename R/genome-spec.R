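#' Genome specification for simulation
#'
#' A `genome_spec` describes the synthetic genome every simulator draws from:
#' chromosome lengths, marker positions, and a piecewise-constant meiotic
#' recombination intensity profile (cM/Mb) that defines the crossover
#' landscape, optionally with pericentromeric (pCENR) intervals where the
#' intensity is suppressed.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param markers data.frame with columns `marker`, `chrom`, `pos_bp`
#'   (1-based). Positions must be strictly increasing within a chromosome.
#' @param intensity data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (0-based half-open) and `cm_per_mb` (>= 0) tiling each chromosome.
#'   If `NULL`, a uniform profile of `base_rate` cM/Mb is used.
#' @param pcenr optional data.frame with columns `chrom`, `start_bp`,
#'   `end_bp` marking the pericentromeric truth intervals.
#' @param base_rate uniform intensity (cM/Mb) used when `intensity` is NULL.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths, markers, intensity = NULL,
                        pcenr = NULL, base_rate = 2) {
  stopifnot(is.numeric(chrom_lengths), all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)))
  markers <- as.data.frame(markers)
  stopifnot(all(c("marker", "chrom", "pos_bp") %in% names(markers)))
  if (nrow(markers) == 0L) stop("genome_spec requires at least one marker")
  if (anyDuplicated(markers$marker))
    stop("marker ids must be unique")
  if (!all(markers$chrom %in% names(chrom_lengths)))
    stop("marker chromosome not in chrom_lengths")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos_bp[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within ", ch)
    if (any(p < 1) || any(p > chrom_lengths[[ch]]))
      stop("marker position outside [1, length] on ", ch)
  }
  if (is.null(intensity)) {
    intensity <- data.frame(
      chrom    = names(chrom_lengths),
      start_bp = 0,
      end_bp   = unname(chrom_lengths),
      cm_per_mb = base_rate
    )
  }
  intensity <- as.data.frame(intensity)
  stopifnot(all(c("chrom", "start_bp", "end_bp", "cm_per_mb") %in%
                  names(intensity)),
            all(intensity$cm_per_mb >= 0))
  structure(
    list(chrom_lengths = chrom_lengths, markers = markers,
         intensity = intensity, pcenr = pcenr),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosomes, %d markers, %.1f Mb total\n",
              length(x$chrom_lengths), nrow(x$markers),
              sum(x$chrom_lengths) / 1e6))
  invisible(x)
}

#' Cumulative genetic position along a chromosome
#'
#' Integrates the piecewise-constant intensity profile from the chromosome
#' start to each `bp`, returning positions in cM.
#'
#' @param spec a [genome_spec()].
#' @param chrom chromosome id.
#' @param bp numeric vector of physical positions.
#' @return numeric vector of genetic positions (cM).
#' @export
genetic_pos <- function(spec, chrom, bp) {
  seg <- spec$intensity[spec$intensity$chrom == chrom, , drop = FALSE]
  seg <- seg[order(seg$start_bp), , drop = FALSE]
  vapply(bp, function(p) {
    ov <- pmax(0, pmin(p, seg$end_bp) - seg$start_bp)
    sum(ov * seg$cm_per_mb) / 1e6
  }, numeric(1))
}

#' Genetic length of a chromosome in cM
#' @inheritParams genetic_pos
#' @export
chrom_genetic_length <- function(spec, chrom) {
  genetic_pos(spec, chrom, spec$chrom_lengths[[chrom]])
}

#' Construct a bean-like synthetic genome
#'
#' Builds an 11-chromosome genome emulating the common bean karyotype:
#' chromosome lengths spanning roughly 32-60 Mb, one pericentromeric
#' interval per chromosome with strongly suppressed recombination
#' (intensity `pcenr_factor` times the arm rate), one telocentric
#' chromosome (the 9th, mirroring Pv9) whose plateau sits at the
#' chromosome start, and gene-based markers placed preferentially in the
#' recombining arms (probability proportional to local intensity plus a
#' small floor so the plateau retains sparse coverage).
#'
#' @param n_chrom number of chromosomes.
#' @param n_markers total marker count distributed over chromosomes
#'   proportionally to physical length.
#' @param arm_rate recombination intensity on chromosome arms (cM/Mb); the
#'   default gives a genome-wide average near the 2.1 cM/Mb of the bean
#'   reference map.
#' @param pcenr_factor multiplicative suppression inside the plateau.
#' @param pcenr_frac fraction of each chromosome covered by the plateau.
#' @param marker_floor extra placement weight inside the plateau, added to
#'   the genetic-evenness weight (0 = markers even on the genetic scale).
#' @param seed RNG seed (required; output is deterministic given it).
#' @return a [genome_spec()].
#' @export
bean_genome_spec <- function(n_chrom = 11, n_markers = 768,
                             arm_rate = 3.4, pcenr_factor = 0.05,
                             pcenr_frac = 0.4, marker_floor = 0,
                             seed = 1) {
  stopifnot(n_chrom >= 1, n_markers >= n_chrom)
  rng <- local_rng(seed)
  lens <- round(seq(60e6, 32e6, length.out = n_chrom) +
                  rng$runif(n_chrom, -1e6, 1e6))
  names(lens) <- sprintf("Chr%02d", seq_len(n_chrom))

  pcenr <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    L <- lens[i]
    w <- pcenr_frac * L
    if (i == 9 && n_chrom >= 9) {        # telocentric: plateau at the start
      s <- 0
    } else {
      s <- rng$runif(1, 0.2 * L, 0.8 * L - w)
    }
    data.frame(chrom = names(lens)[i], start_bp = round(s),
               end_bp = round(s + w))
  }))

  intensity <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    L <- lens[i]; pc <- pcenr[i, ]
    brk <- sort(unique(c(0, pc$start_bp, pc$end_bp, L)))
    data.frame(chrom = names(lens)[i],
               start_bp = brk[-length(brk)], end_bp = brk[-1],
               cm_per_mb = ifelse(brk[-length(brk)] >= pc$start_bp &
                                    brk[-1] <= pc$end_bp,
                                  arm_rate * pcenr_factor, arm_rate))
  }))

  # markers: gene-based SNP panels sit in the gene-dense recombining arms
  # and are close to evenly spaced on the genetic scale; positions are
  # jittered quantiles of the intensity-weighted (plus floor) measure
  per_chrom <- round(n_markers * lens / sum(lens))
  per_chrom[n_chrom] <- n_markers - sum(per_chrom[-n_chrom])
  markers <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    L <- lens[i]; pc <- pcenr[i, ]
    m <- per_chrom[i]
    grid <- seq(1, L, length.out = 20000)
    w <- ifelse(grid >= pc$start_bp & grid <= pc$end_bp,
                marker_floor + pcenr_factor, 1)
    cw <- cumsum(w) / sum(w)
    targets <- (seq_len(m) - 0.5 + rng$runif(m, -0.35, 0.35)) / m
    pos <- sort(unique(round(grid[findInterval(targets, cw) + 1L])))
    while (length(pos) < m) {
      extra <- round(rng$runif(m - length(pos), 1, L))
      pos <- sort(unique(c(pos, extra)))
    }
    data.frame(marker = sprintf("%s_M%03d", names(lens)[i], seq_along(pos)),
               chrom = names(lens)[i], pos_bp = pos)
  }))
  genome_spec(lens, markers, intensity = intensity, pcenr = pcenr)
}

# Self-contained RNG stream so simulators do not disturb the global
# .Random.seed and are reproducible from their own seed argument.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      assign("state", get(".Random.seed", globalenv()), envir = env)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (exists("state", env, inherits = FALSE))
      assign(".Random.seed", get("state", env), envir = globalenv())
    else set.seed(as.integer(seed) %% .Machine$integer.max)
    expr_fun()
  }
  list(
    runif  = function(n, min = 0, max = 1) run(function() runif(n, min, max)),
    rbinom = function(n, size, prob) run(function() rbinom(n, size, prob)),
    rpois  = function(n, lambda) run(function() rpois(n, lambda)),
    rbeta  = function(n, a, b) run(function() rbeta(n, a, b)),
    sample = function(x, size, replace = FALSE, prob = NULL)
      run(function() sample.int(x, size, replace = replace, prob = prob)),
    run    = run
  )
}
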