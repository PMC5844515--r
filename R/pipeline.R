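#' Run the full synthetic analysis pipeline
#'
#' Orchestrates every stage end-to-end on simulated data with a single
#' seed: genome simulation, RIL population and linkage-map construction
#' (grouping at `lod_min`, SARF ordering, Kosambi distances, anchor
#' labeling), physical placement (from the generating truth positions,
#' emitted as synthetic best hits), Marey fitting with pCENR detection
#' and the landscape summary, diversity-panel simulation with
#' genepool-stratified diversity/LD statistics, LD decay fits, and the
#' sliding-window gene-density analysis. All stage outputs are returned
#' and, when `out_dir` is given, written as TSV/BED alongside a resolved
#' configuration echo.
#'
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param n_lines RIL population size.
#' @param n_markers marker count for the simulated genome.
#' @param n_chrom chromosome count.
#' @param panel_cfg a [panel_config()]; its seed is overridden by a
#'   derived one.
#' @param lod_min,r_max grouping thresholds.
#' @param maf_min,call_rate_min LD marker filters.
#' @param window_size,window_step sliding-window geometry.
#' @param with_panel run the diversity/LD stages (default TRUE).
#' @param out_dir optional output directory.
#' @return list with components `genome`, `ril`, `map`, `placements`,
#'   `fits`, `pcenr`, `landscape`, `panel`, `diversity`, `ld`, `decay`,
#'   `windows`, `window_cor`, `config`.
#' @export
run_pipeline <- function(seed = 1, n_lines = 80, n_markers = 300,
                         n_chrom = 5, panel_cfg = NULL,
                         lod_min = 6, r_max = 0.4,
                         maf_min = 0.05, call_rate_min = 0.80,
                         window_size = 1e6, window_step = 2e5,
                         with_panel = TRUE, out_dir = NULL) {
  seeds <- seed * 100 + 1:6
  genome <- bean_genome_spec(n_chrom = n_chrom, n_markers = n_markers,
                             seed = seeds[1])
  ril <- simulate_ril_population(
    genome, ril_config(n_lines = n_lines, seed = seeds[2]))

  rf <- rf_matrices(ril$calls)
  groups <- group_markers(rf, lod_min = lod_min, r_max = r_max)
  ordered <- lapply(groups, order_markers, rf = rf, calls = ril$calls)
  map <- assemble_map(ordered, rf)
  anchors <- genome$markers[, c("marker", "chrom")]
  names(anchors) <- c("marker", "chromosome")
  map <- place_anchors(map, anchors)

  # synthetic best hits at the generating truth positions
  hits <- data.frame(query = genome$markers$marker,
                     chrom = genome$markers$chrom,
                     pident = 100, length = 121L,
                     sstart = genome$markers$pos_bp - 60L,
                     send = genome$markers$pos_bp + 60L,
                     strand = "+", evalue = 1e-60, bitscore = 200,
                     stringsAsFactors = FALSE)
  placements <- classify_hits(hits, markers = genome$markers$marker)

  curves <- build_marey(map, placements)
  fits <- lapply(curves[vapply(curves, `[[`, logical(1), "fittable")],
                 fit_marey)
  land_tbl <- do.call(rbind, lapply(split(as.data.frame(map), map$linkage_group),
    function(d) {
      ch <- d$chromosome[1]
      if (is.na(ch)) return(NULL)
      data.frame(chromosome = ch, cm = max(d$cm) - min(d$cm),
                 bp = genome$chrom_lengths[[ch]], n_markers = nrow(d))
    }))
  landscape <- landscape_summary(land_tbl)
  mean_rate <- landscape$totals$cm / (landscape$totals$bp / 1e6)
  pcenr <- do.call(rbind, lapply(fits, detect_pcenr,
                                 genome_mean_rate = mean_rate))

  genes <- simulate_gene_models(genome, seed = seeds[3])
  win <- make_windows(genome$chrom_lengths, size = window_size,
                      step = window_step)

  panel <- diversity <- ld_pairs <- decay <- NULL
  if (with_panel) {
    if (is.null(panel_cfg)) panel_cfg <- panel_config(seed = seeds[4])
    panel_cfg$seed <- seeds[4]
    panel <- simulate_diversity_panel(genome, panel_cfg)
    diversity <- marker_diversity(panel$calls, panel$labels)
    kept <- filter_markers(panel$calls, maf_min, call_rate_min)
    sub <- panel$calls[, kept, drop = FALSE]
    ld_pairs <- lapply(c("global", panel_cfg$pool_names), function(sc) {
      lines <- if (sc == "global") rownames(sub) else
        panel$labels$line[panel$labels$pool == sc]
      pairwise_ld(sub, lines = lines, scope = sc, map = map,
                  placements = placements)
    })
    names(ld_pairs) <- c("global", panel_cfg$pool_names)
    decay <- lapply(ld_pairs, function(p)
      tryCatch(ld_decay(p, "cm"), error = function(e) NULL))
  }

  win <- annotate_windows(win, genes, fits = fits,
                          pairs = if (with_panel) ld_pairs$global else NULL,
                          placements = placements)
  window_cor <- list(
    genes_vs_rate = correlate_windows(win$n_genes, win$rate_cm_bp),
    genes_vs_r2 = if (with_panel)
      correlate_windows(win$n_genes, win$mean_r2_pct) else NULL)

  config <- list(seed = seed, n_lines = n_lines, n_markers = n_markers,
                 n_chrom = n_chrom, lod_min = lod_min, r_max = r_max,
                 maf_min = maf_min, call_rate_min = call_rate_min,
                 window_size = window_size, window_step = window_step)

  res <- list(genome = genome, ril = ril, map = map,
              placements = placements, fits = fits, pcenr = pcenr,
              landscape = landscape, genes = genes, panel = panel,
              diversity = diversity, ld = ld_pairs, decay = decay,
              windows = win, window_cor = window_cor, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(ril$calls, file.path(out_dir, "ril_genotypes.tsv"))
    write_map_tsv(map, file.path(out_dir, "genetic_map.tsv"))
    utils::write.table(placements, file.path(out_dir, "placements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pcenr) && nrow(pcenr))
      write_bed(data.frame(chrom = pcenr$chrom,
                           start = round(pcenr$start_bp),
                           end = round(pcenr$end_bp)),
                file.path(out_dir, "pcenr.bed"))
    utils::write.table(win, file.path(out_dir, "windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (with_panel) {
      write_genotypes(panel$calls, file.path(out_dir, "panel_genotypes.tsv"))
      utils::write.table(panel$labels, file.path(out_dir, "labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(diversity, file.path(out_dir, "diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(paste(names(config), unlist(config), sep = "="),
               file.path(out_dir, "config.txt"))
  }
  res
}
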