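#' Read a genotype matrix from TSV
#'
#' Expects a header row of marker ids and one row per line (first column
#' the line id). Cells must come from the call alphabet `A`, `B`, `H`
#' plus the missing code.
#'
#' @param path file path.
#' @param missing_code string representing a missing call (default `"-"`).
#' @return character matrix (lines x markers) with `NA` for missing.
#' @export
read_genotypes <- function(path, missing_code = "-") {
  lines <- readLines(path)
  if (length(lines) < 2) stop("genotype file needs a header and >= 1 line")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1]])
  bad <- which(lengths(fields) != ncol)
  if (length(bad))
    stop("ragged row in ", path, " at line ", bad[1],
         " (expected ", ncol, " fields, got ", lengths(fields)[bad[1]], ")")
  markers <- fields[[1]][-1]
  if (anyDuplicated(markers)) stop("duplicate marker ids in header")
  body <- fields[-1]
  calls <- do.call(rbind, lapply(body, function(f) f[-1]))
  rownames(calls) <- vapply(body, `[[`, character(1), 1)
  colnames(calls) <- markers
  calls[calls == missing_code] <- NA_character_
  ok <- is.na(calls) | calls %in% c("A", "B", "H")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid call code '", calls[idx[1], idx[2]], "' at line '",
         rownames(calls)[idx[1]], "', marker '", colnames(calls)[idx[2]], "'")
  }
  calls
}

#' Write a genotype matrix to TSV
#' @param calls character matrix as from [read_genotypes()].
#' @inheritParams read_genotypes
#' @export
write_genotypes <- function(calls, path, missing_code = "-") {
  out <- calls
  out[is.na(out)] <- missing_code
  df <- data.frame(line = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file and returns gene features with coordinates
#' normalized to the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param feature_type feature type(s) to keep (default `"gene"`).
#' @return data.frame with columns `gene`, `chrom`, `start` (0-based),
#'   `end` (exclusive), `strand`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("gene%05d", seq_along(gr))
  out <- data.frame(
    gene = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("gene with start >= end after conversion")
  out
}

#' Write gene models to GFF3
#' @param genes data.frame as returned by [read_gff3()].
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\trecombean\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                     genes$gene), con)
  invisible(path)
}

#' Read alignment hits in 12-column tabular format
#'
#' Parses the standard tabular dialect (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, E-value, bit score). Rows with subject start > end are
#' recorded as minus-strand hits and their interval normalized.
#'
#' @param path tabular file.
#' @return data.frame with columns `query`, `chrom`, `pident`, `length`,
#'   `sstart`, `send` (1-based inclusive, start <= end), `strand`,
#'   `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 12)
    stop("expected 12 tab-separated columns, got ", ncol(raw))
  ev <- suppressWarnings(as.numeric(raw[[11]]))
  if (anyNA(ev)) stop("non-numeric E-value at row ", which(is.na(ev))[1])
  if (any(ev < 0)) stop("negative E-value")
  s1 <- as.integer(raw[[9]]); s2 <- as.integer(raw[[10]])
  data.frame(
    query = raw[[1]], chrom = raw[[2]],
    pident = as.numeric(raw[[3]]), length = as.integer(raw[[4]]),
    sstart = pmin(s1, s2), send = pmax(s1, s2),
    strand = ifelse(s1 <= s2, "+", "-"),
    evalue = ev, bitscore = as.numeric(raw[[12]]),
    stringsAsFactors = FALSE
  )
}

#' Write hits in the 12-column tabular dialect
#' @param hits data.frame as from [read_blast_tab()] (query coordinates are
#'   emitted as 1..length; minus-strand hits get subject start > end).
#' @param path output path.
#' @export
write_blast_tab <- function(hits, path) {
  minus <- hits$strand == "-"
  s1 <- ifelse(minus, hits$send, hits$sstart)
  s2 <- ifelse(minus, hits$sstart, hits$send)
  df <- data.frame(hits$query, hits$chrom, hits$pident, hits$length,
                   0L, 0L, 1L, hits$length, s1, s2,
                   format(hits$evalue, digits = 3),
                   hits$bitscore)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals to BED
#' @param intervals data.frame with `chrom`, `start` (0-based), `end`, and
#'   optionally `name`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, intersect(c("chrom", "start", "end", "name"),
                                names(intervals)), drop = FALSE]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genetic map to TSV
#' @param map a `genetic_map` data.frame (see [assemble_map()]).
#' @param path output path.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genetic map written by [write_map_tsv()]
#' @param path file path.
#' @export
read_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Read FASTA sequences
#' @param path FASTA file (plain text).
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write FASTA sequences
#' @param seqs a `DNAStringSet` or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
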