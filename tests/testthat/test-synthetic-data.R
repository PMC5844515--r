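test_that("genome_spec validates its invariants", {
  g <- tiny_genome(2, m = 3)
  expect_s3_class(g, "genome_spec")
  expect_error(genome_spec(c(chr1 = 1e6),
                           data.frame(marker = c("a", "b"), chrom = "chr1",
                                      pos_bp = c(100, 100))),
               "strictly increasing")
  expect_error(genome_spec(c(chr1 = 1e6),
                           data.frame(marker = "a", chrom = "chr1",
                                      pos_bp = 2e6)),
               "outside")
  expect_error(genome_spec(c(chr1 = 1e6),
                           data.frame(marker = character(), chrom = character(),
                                      pos_bp = numeric())),
               "at least one marker")
})

test_that("genetic positions integrate the intensity profile", {
  lens <- c(chr1 = 10e6)
  intensity <- data.frame(chrom = "chr1",
                          start_bp = c(0, 5e6), end_bp = c(5e6, 10e6),
                          cm_per_mb = c(2, 4))
  g <- genome_spec(lens, data.frame(marker = "m1", chrom = "chr1",
                                    pos_bp = 1e6), intensity = intensity)
  expect_equal(genetic_pos(g, "chr1", c(2.5e6, 5e6, 7.5e6)),
               c(5, 10, 20))
  expect_equal(chrom_genetic_length(g, "chr1"), 30)
})

test_that("zero intensity yields a fully parental population", {
  g <- tiny_genome(1, m = 2, rate = 0)
  ril <- simulate_ril_population(
    g, ril_config(n_lines = 40, missing_rate = 0, het_rate = 0, seed = 3))
  expect_true(all(ril$calls %in% c("A", "B")))
  # no recombinant lines at all
  expect_true(all(ril$calls[, 1] == ril$calls[, 2]))
})

test_that("RIL simulation is byte-identical under the same seed", {
  g <- tiny_genome(2, m = 5)
  a <- simulate_ril_population(g, ril_config(n_lines = 30, seed = 7))
  b <- simulate_ril_population(g, ril_config(n_lines = 30, seed = 7))
  expect_identical(a$calls, b$calls)
  c <- simulate_ril_population(g, ril_config(n_lines = 30, seed = 8))
  expect_false(identical(a$calls, c$calls))
})

test_that("F-infinity recombinant fractions follow Haldane-Waddington", {
  # three chromosomes, each two markers at meiotic r in {0.05, 0.1, 0.25};
  # intensity chosen so the Haldane genetic distance gives that r exactly
  rs <- c(0.05, 0.1, 0.25)
  d_cm <- -50 * log(1 - 2 * rs)          # Haldane inverse
  lens <- stats::setNames(rep(10e6, 3), sprintf("chr%d", 1:3))
  markers <- do.call(rbind, lapply(1:3, function(i)
    data.frame(marker = sprintf("chr%d_m%d", i, 1:2), chrom = names(lens)[i],
               pos_bp = c(1e6, 9e6))))
  intensity <- data.frame(chrom = names(lens), start_bp = 0, end_bp = 10e6,
                          cm_per_mb = d_cm / 8)   # 8 Mb between markers
  g <- genome_spec(lens, markers, intensity = intensity)
  ril <- simulate_ril_population(
    g, ril_config(n_lines = 3000, generations = 25, missing_rate = 0,
                  het_rate = 0, seed = 11))
  for (i in 1:3) {
    m1 <- sprintf("chr%d_m1", i); m2 <- sprintf("chr%d_m2", i)
    obs <- mean(ril$calls[, m1] != ril$calls[, m2])
    expected <- hw_ril(rs[i])
    se <- sqrt(expected * (1 - expected) / 3000)
    expect_lt(abs(obs - expected), 3 * se)
  }
})

test_that("missingness and residual heterozygosity match the config", {
  g <- tiny_genome(2, m = 40)
  cfg <- ril_config(n_lines = 150, missing_rate = 0.03, het_rate = 0.01,
                    seed = 5)
  ril <- simulate_ril_population(g, cfg)
  n_cells <- length(ril$calls)
  miss <- mean(is.na(ril$calls))
  expect_lt(abs(miss - 0.03), 3 * sqrt(0.03 * 0.97 / n_cells))
  het <- mean(ril$calls == "H", na.rm = TRUE)
  # H applied before masking; compare against the pre-mask denominator
  expect_lt(abs(het - 0.01), 4 * sqrt(0.01 * 0.99 / n_cells) + 0.002)
})

test_that("panel divergence 0 gives equal pooled and within-pool diversity", {
  g <- tiny_genome(2, m = 60)
  pan <- simulate_diversity_panel(
    g, panel_config(pool_sizes = c(60, 60), divergence = 0, races = 1,
                    race_drift = 0, hap_divergence = 0.5,
                    missing_rate = 0, het_rate = 0, seed = 9))
  div <- marker_diversity(pan$calls, pan$labels)
  means <- tapply(div$pi, div$scope, mean, na.rm = TRUE)
  expect_lt(abs(means[["global"]] -
                  mean(means[names(means) != "global"])), 0.03)
})

test_that("strong divergence inflates across-pool diversity and MAF", {
  g <- tiny_genome(3, m = 60)
  pan <- simulate_diversity_panel(g, panel_config(divergence = 0.4, seed = 13))
  div <- marker_diversity(pan$calls, pan$labels)
  means <- tapply(div$pi, div$scope, mean, na.rm = TRUE)
  expect_gt(means[["global"]],
            max(means[["Andean"]], means[["Mesoamerican"]]))
  # global folded SFS skewed toward high MAF relative to within-pool
  maf_g <- div$maf[div$scope == "global"]
  maf_w <- div$maf[div$scope != "global"]
  expect_gt(mean(maf_g, na.rm = TRUE), mean(maf_w, na.rm = TRUE))
})

test_that("between-pool divergence grows monotonically with the parameter", {
  g <- tiny_genome(2, m = 50)
  fst_like <- function(pan) {
    a <- pan$labels$line[pan$labels$pool == "Andean"]
    m <- pan$labels$line[pan$labels$pool == "Mesoamerican"]
    pa <- colMeans(pan$calls[a, ] == "B", na.rm = TRUE)
    pm <- colMeans(pan$calls[m, ] == "B", na.rm = TRUE)
    mean((pa - pm)^2, na.rm = TRUE)
  }
  for (seed in 1:3) {
    vals <- vapply(c(0.05, 0.2, 0.4), function(f)
      fst_like(simulate_diversity_panel(
        g, panel_config(divergence = f, races = 1, race_drift = 0,
                        seed = seed))), numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("ignoring pool labels inflates inter-chromosomal LD", {
  g <- tiny_genome(2, m = 30)
  pan <- simulate_diversity_panel(g, panel_config(seed = 17))
  tm <- truth_map_of(g)
  global <- pairwise_ld(pan$calls, scope = "global", map = tm, with_p = FALSE)
  within <- do.call(rbind, lapply(c("Andean", "Mesoamerican"), function(p)
    pairwise_ld(pan$calls, lines = pan$labels$line[pan$labels$pool == p],
                scope = p, map = tm, with_p = FALSE)))
  inter_g <- mean(global$r2[!global$same_group], na.rm = TRUE)
  inter_w <- mean(within$r2[!within$same_group], na.rm = TRUE)
  expect_gt(inter_g, inter_w)
})

test_that("marker flanking sequences embed queries at truth positions", {
  g <- tiny_genome(2, m = 5, len = 50e3)
  seqs <- simulate_marker_sequences(g, flank_len = 60, seed = 21)
  expect_true(all(Biostrings::width(seqs$flanks) == 121))
  # each flank is literally the genome subsequence around its marker
  for (i in 1:3) {
    mk <- g$markers[i, ]
    sub <- substr(as.character(seqs$chromosomes[[mk$chrom]]),
                  mk$pos_bp - 60, mk$pos_bp + 60)
    expect_identical(as.character(seqs$flanks[[mk$marker]]), sub)
  }
  expect_equal(nrow(seqs$paralogs), 0)
})

test_that("paralog copies create exactly the designed multi-hit cases", {
  g <- tiny_genome(2, m = 8, len = 100e3)
  seqs <- simulate_marker_sequences(g, flank_len = 60, n_paralogs = 3,
                                    seed = 23)
  expect_equal(nrow(seqs$paralogs), 3)
  hits <- naive_search(seqs$flanks, seqs$chromosomes)
  dec <- classify_hits(hits, markers = g$markers$marker)
  expect_setequal(dec$marker[dec$status == "multiple"], seqs$paralogs$marker)
  singles <- dec[dec$status == "singleton", ]
  truth_pos <- g$markers$pos_bp[match(singles$marker, g$markers$marker)]
  expect_true(all(abs(singles$pos_bp - truth_pos) <= 1))
})

test_that("overlapping marker contexts are rejected", {
  lens <- c(chr1 = 10e3)
  markers <- data.frame(marker = c("a", "b"), chrom = "chr1",
                        pos_bp = c(500, 550))
  g <- genome_spec(lens, markers)
  expect_error(simulate_marker_sequences(g, flank_len = 60, seed = 1),
               "overlapping")
})
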