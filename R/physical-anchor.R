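#' Classify marker placements from alignment hits
#'
#' Applies the best-hit placement rule: a marker is `unplaced` when its
#' best (lowest) E-value exceeds `e_threshold`; `singleton` when the best
#' hit qualifies and either no second hit exists or the next-best E-value
#' is at least `separation` times the best (E-values are compared on the
#' multiplicative scale, i.e. a 1e10 separation factor); `multiple`
#' otherwise. The physical position is the midpoint of the best hit's
#' subject interval. Hits are sorted internally (E-value ascending, bit
#' score descending, then chromosome and position), so input order is
#' irrelevant.
#'
#' @param hits data.frame of hits as from [read_blast_tab()] or
#'   [naive_search()] (columns `query`, `chrom`, `sstart`, `send`,
#'   `evalue`, `bitscore`).
#' @param markers optional character vector of all tested marker ids;
#'   markers without any hit are reported as `unplaced`.
#' @param e_threshold maximum qualifying E-value (default `1e-30`).
#' @param separation multiplicative E-value separation between best and
#'   next-best hit required for a singleton call (default `1e10`).
#' @return data.frame with one row per marker: `marker`, `status`,
#'   `chrom`, `pos_bp` (midpoint), `sstart`, `send`, `best_evalue`,
#'   `next_evalue`.
#' @export
classify_hits <- function(hits, markers = NULL, e_threshold = 1e-30,
                          separation = 1e10) {
  if (is.null(markers)) markers <- unique(hits$query)
  out <- lapply(markers, function(q) {
    h <- hits[hits$query == q, , drop = FALSE]
    if (nrow(h) == 0) {
      return(data.frame(marker = q, status = "unplaced",
                        chrom = NA_character_, pos_bp = NA_real_,
                        sstart = NA_integer_, send = NA_integer_,
                        best_evalue = NA_real_, next_evalue = NA_real_,
                        stringsAsFactors = FALSE))
    }
    h <- h[order(h$evalue, -h$bitscore, h$chrom, h$sstart), , drop = FALSE]
    best <- h[1, ]
    next_e <- if (nrow(h) > 1) h$evalue[2] else NA_real_
    status <- if (best$evalue > e_threshold) {
      "unplaced"
    } else if (is.na(next_e)) {
      "singleton"
    } else if (best$evalue == 0 && next_e == 0) {
      "multiple"
    } else if (best$evalue == 0 || next_e / best$evalue >= separation) {
      "singleton"
    } else {
      "multiple"
    }
    data.frame(marker = q, status = status,
               chrom = if (status == "unplaced") NA_character_ else best$chrom,
               pos_bp = if (status == "unplaced") NA_real_ else
                 (best$sstart + best$send) / 2,
               sstart = if (status == "unplaced") NA_integer_ else best$sstart,
               send = if (status == "unplaced") NA_integer_ else best$send,
               best_evalue = best$evalue, next_evalue = next_e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Placement bookkeeping summary
#'
#' Counts singleton / multiple / unplaced placements and the marker
#' success rate of the genotyping assay. Accepts either a decisions
#' data.frame from [classify_hits()] or explicit printed counts.
#'
#' @param decisions data.frame from [classify_hits()], or `NULL` when
#'   explicit counts are given.
#' @param n_tested total markers tested (derived from `decisions` when
#'   omitted).
#' @param n_multiple,n_unplaced explicit counts (derived from `decisions`
#'   when omitted).
#' @param n_het,n_low_signal markers excluded upstream for heterozygosity
#'   or low assay signal; they reduce the assay success rate but are not
#'   part of the placement classification.
#' @return list with `n_tested`, `n_singleton`, `n_multiple`,
#'   `n_unplaced`, `singleton_pct` (1 decimal), and `success_pct`
#'   (`(n_tested - n_het - n_low_signal) / n_tested`, 1 decimal).
#' @export
placement_summary <- function(decisions = NULL, n_tested = NULL,
                              n_multiple = NULL, n_unplaced = 0,
                              n_het = 0, n_low_signal = 0) {
  if (!is.null(decisions)) {
    n_tested <- nrow(decisions)
    n_multiple <- sum(decisions$status == "multiple")
    n_unplaced <- sum(decisions$status == "unplaced")
  }
  stopifnot(!is.null(n_tested), !is.null(n_multiple))
  n_singleton <- n_tested - n_multiple - n_unplaced
  round1 <- function(x) floor(x * 10 + 0.5) / 10
  list(n_tested = n_tested, n_singleton = n_singleton,
       n_multiple = n_multiple, n_unplaced = n_unplaced,
       singleton_pct = if (n_tested > 0) round1(100 * n_singleton / n_tested) else NA,
       success_pct = if (n_tested > 0)
         round1(100 * (n_tested - n_het - n_low_signal) / n_tested) else NA)
}

karlin_altschul_evalue <- function(score, qlen, dblen,
                                   lambda = 0.625, K = 0.41) {
  K * qlen * dblen * exp(-lambda * score)
}

# Seed-and-extend ungapped search of one query against one subject strand.
# Non-overlapping exact words of length `word` guarantee a seed whenever
# the query matches with fewer than floor(len/word) substitutions.
search_one_strand <- function(query, subject, word, min_score) {
  qlen <- nchar(query)
  offsets <- seq(1, qlen - word + 1, by = word)
  starts <- integer(0)
  subj <- Biostrings::DNAString(subject)
  for (o in offsets) {
    w <- substr(query, o, o + word - 1)
    m <- Biostrings::matchPattern(w, subj)
    if (length(m)) starts <- c(starts, Biostrings::start(m) - o + 1L)
  }
  starts <- unique(starts)
  starts <- starts[starts >= 1 & starts + qlen - 1 <= nchar(subject)]
  if (!length(starts)) return(NULL)
  qv <- strsplit(query, "")[[1]]
  res <- lapply(starts, function(s) {
    sv <- strsplit(substr(subject, s, s + qlen - 1), "")[[1]]
    matches <- sum(qv == sv)
    score <- 2 * matches - 3 * (qlen - matches)   # blastn +2/-3 scoring
    if (score < min_score) return(NULL)
    data.frame(sstart = s, send = s + qlen - 1L, score = score,
               pident = 100 * matches / qlen)
  })
  do.call(rbind, res)
}

#' Naive ungapped sequence search with E-values
#'
#' A deliberately simple matcher for synthetic genomes: exact
#' `word`-length seeds, ungapped full-query extension with the blastn
#' default match/mismatch scores (+2/-3), and E-values from the
#' ungapped Karlin-Altschul formula `E = K m n exp(-lambda S)` with the
#' corresponding fixed constants (`lambda = 0.625`, `K = 0.41`). Both
#' strands are searched. For real analyses import tabular hits from a
#' proper aligner instead.
#'
#' @param queries named character vector or `DNAStringSet` of query
#'   sequences (each at least `word` long).
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param word seed word length.
#' @param max_evalue hits above this E-value are dropped.
#' @return data.frame in the layout of [read_blast_tab()].
#' @export
naive_search <- function(queries, genome, word = 11, max_evalue = 10) {
  qs <- as.character(queries)
  names(qs) <- if (!is.null(names(queries))) names(queries) else
    sprintf("query%d", seq_along(qs))
  gs <- as.character(genome)
  names(gs) <- names(genome)
  stopifnot(!is.null(names(gs)), all(nchar(qs) >= word))
  dblen <- sum(nchar(gs))
  out <- list()
  for (qi in seq_along(qs)) {
    qlen <- nchar(qs[qi])
    # min score so that reported hits stay below max_evalue
    min_s <- ceiling((log(0.41 * qlen * dblen) - log(max_evalue)) / 0.625)
    for (ci in seq_along(gs)) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") qs[qi] else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(qs[qi])))
        h <- search_one_strand(q, gs[ci], word, min_s)
        if (is.null(h) || nrow(h) == 0) next
        h$query <- names(qs)[qi]
        h$chrom <- names(gs)[ci]
        h$strand <- strand
        h$length <- qlen
        h$evalue <- karlin_altschul_evalue(h$score, qlen, dblen)
        h$bitscore <- (0.625 * h$score - log(0.41)) / log(2)
        out[[length(out) + 1]] <- h
      }
    }
  }
  if (!length(out))
    return(data.frame(query = character(), chrom = character(),
                      pident = numeric(), length = integer(),
                      sstart = integer(), send = integer(),
                      strand = character(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[res$evalue <= max_evalue, , drop = FALSE]
  rownames(res) <- NULL
  res[, c("query", "chrom", "pident", "length", "sstart", "send",
          "strand", "evalue", "bitscore")]
}

#' Intersect marker placements with gene models
#'
#' A marker overlaps a gene when its best-hit interval and the gene
#' interval share at least one base (0-based half-open intersection). A
#' marker may match several genes and two markers may match the same
#' gene.
#'
#' @param placements data.frame from [classify_hits()] (singleton rows
#'   are used; `sstart`/`send` are 1-based inclusive).
#' @param genes data.frame from [read_gff3()] (`start` 0-based, `end`
#'   exclusive).
#' @param include_multiple also intersect multiple-hit markers at their
#'   best hit (default FALSE: multi-hit markers are dropped, matching the
#'   physical-map treatment).
#' @return data.frame with columns `marker`, `gene`, `chrom`.
#' @export
marker_gene_overlap <- function(placements, genes,
                                include_multiple = FALSE) {
  keep <- placements$status == "singleton" |
    (include_multiple & placements$status == "multiple")
  pl <- placements[keep & !is.na(placements$chrom), , drop = FALSE]
  if (nrow(pl) == 0 || nrow(genes) == 0)
    return(data.frame(marker = character(), gene = character(),
                      chrom = character(), stringsAsFactors = FALSE))
  out <- list()
  for (ch in intersect(unique(pl$chrom), unique(genes$chrom))) {
    p <- pl[pl$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    # convert placements to 0-based half-open and query overlaps
    ir_p <- IRanges::IRanges(start = p$sstart, end = p$send)    # 1-based incl
    ir_g <- IRanges::IRanges(start = g$start + 1L, end = g$end) # to 1-based
    ov <- IRanges::findOverlaps(ir_p, ir_g)
    if (length(ov))
      out[[ch]] <- data.frame(
        marker = p$marker[S4Vectors::queryHits(ov)],
        gene = g$gene[S4Vectors::subjectHits(ov)],
        chrom = ch, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(marker = character(), gene = character(),
                      chrom = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
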