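collinear_setup <- function(n = 12, slope = 2, len = 30e6) {
  bp <- seq(1e6, len - 1e6, length.out = n)
  map <- data.frame(linkage_group = "LG-1",
                    marker = sprintf("m%d", seq_len(n)),
                    cm = slope * bp / 1e6, chromosome = "chr1",
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  pl <- data.frame(marker = map$marker, status = "singleton", chrom = "chr1",
                   pos_bp = bp, sstart = bp - 60, send = bp + 60,
                   stringsAsFactors = FALSE)
  list(map = map, placements = pl, bp = bp)
}

test_that("collinear points are unflagged; reversal gives the same curve", {
  s <- collinear_setup()
  curves <- build_marey(s$map, s$placements)
  expect_false(any(curves$chr1$points$flagged))
  rev_map <- s$map
  rev_map$cm <- max(s$map$cm) - s$map$cm
  curves_rev <- build_marey(rev_map, s$placements)
  expect_equal(curves_rev$chr1$points$cm, curves$chr1$points$cm)
})

test_that("a swapped adjacent pair is flagged, and only that pair", {
  s <- collinear_setup()
  swap <- s$map
  swap$cm[5:6] <- swap$cm[6:5]
  curves <- build_marey(swap, s$placements)
  expect_equal(which(curves$chr1$points$flagged), c(5L, 6L))
})

test_that("fewer than 3 shared markers makes a curve unfittable", {
  s <- collinear_setup(n = 2)
  curves <- build_marey(s$map, s$placements)
  expect_false(curves$chr1$fittable)
  expect_error(fit_marey(curves$chr1), "unfittable")
})

test_that("a linear landscape fits with constant derivative", {
  s <- collinear_setup(n = 15, slope = 2)
  fit <- fit_marey(build_marey(s$map, s$placements)$chr1)
  lr <- local_rate(fit)
  expect_true(all(abs(lr$rate_cm_mb - 2) < 0.05))
  expect_equal(nrow(detect_pcenr(fit, genome_mean_rate = 2)), 0)
})

test_that("duplicate bp positions are averaged before fitting", {
  s <- collinear_setup(n = 10)
  pl <- s$placements
  pl$pos_bp[2] <- pl$pos_bp[1]          # collide two markers
  curve <- build_marey(s$map, pl)$chr1
  fit <- fit_marey(curve, degree = 3)
  expect_equal(nrow(fit$points), 9)
})

test_that("isotonic adjustment is non-decreasing and integrates to length", {
  g <- bean_genome_spec(n_chrom = 1, n_markers = 80, seed = 61)
  ril <- simulate_ril_population(g, ril_config(n_lines = 150, seed = 62))
  rf <- rf_matrices(ril$calls)
  ords <- lapply(group_markers(rf), order_markers, rf = rf,
                 calls = ril$calls)
  map <- place_anchors(assemble_map(ords, rf),
                       stats::setNames(g$markers[, c("marker", "chrom")],
                                       c("marker", "chromosome")))
  fit <- fit_marey(build_marey(map, truth_placements_of(g))[[1]])
  expect_true(all(diff(marey_predict(fit, seq(fit$range[1], fit$range[2],
                                              length.out = 400))) >= -1e-9))
  lr <- local_rate(fit)
  integral <- sum(lr$rate_cm_mb * diff(seq(fit$range[1], fit$range[2],
                                           length.out = 513)) / 1e6)
  span <- diff(range(marey_predict(fit, fit$range)))
  expect_lt(abs(integral - span) / max(span, 1), 0.01)
})

test_that("simulated suppression is detected with high overlap", {
  # one chromosome, 10x rate contrast in [15, 25] Mb
  lens <- c(chr1 = 40e6)
  intensity <- data.frame(chrom = "chr1",
                          start_bp = c(0, 15e6, 25e6),
                          end_bp = c(15e6, 25e6, 40e6),
                          cm_per_mb = c(3, 0.15, 3))
  bp <- seq(5e5, 39.5e6, length.out = 60)
  markers <- data.frame(marker = sprintf("m%d", 1:60), chrom = "chr1",
                        pos_bp = round(bp))
  g <- genome_spec(lens, markers, intensity = intensity,
                   pcenr = data.frame(chrom = "chr1", start_bp = 15e6,
                                      end_bp = 25e6))
  map <- truth_map_of(g)
  map$cm <- map$cm + stats::rnorm(60, sd = 0.3)   # observation noise
  map$cm <- map$cm - min(map$cm)
  fit <- fit_marey(build_marey(map, truth_placements_of(g))[[1]])
  pc <- detect_pcenr(fit, genome_mean_rate = chrom_genetic_length(g, "chr1") /
                       (40e6 / 1e6))
  jac <- pcenr_jaccard(pc, g$pcenr)
  expect_gte(attr(jac, "mean"), 0.8)
})

test_that("telocentric suppression yields a single terminal plateau", {
  lens <- c(chr1 = 40e6)
  intensity <- data.frame(chrom = "chr1",
                          start_bp = c(0, 12e6), end_bp = c(12e6, 40e6),
                          cm_per_mb = c(0.15, 3))
  bp <- seq(5e5, 39.5e6, length.out = 50)
  g <- genome_spec(lens, data.frame(marker = sprintf("m%d", 1:50),
                                    chrom = "chr1", pos_bp = round(bp)),
                   intensity = intensity)
  fit <- fit_marey(build_marey(truth_map_of(g),
                               truth_placements_of(g))[[1]])
  pc <- detect_pcenr(fit, genome_mean_rate = chrom_genetic_length(g, "chr1") /
                       40)
  primary <- pc[pc$primary, ]
  expect_equal(nrow(primary), 1)
  expect_lt(primary$start_bp, 2e6)      # plateau starts at the chromosome end
})

test_that("landscape summary distinguishes totals ratio from ratio mean", {
  ref <- bean_reference_map()
  ls <- landscape_summary(ref, totals = attr(ref, "totals"))
  expect_equal(ls$genome_ratio_cm_mb, 2.13)
  expect_equal(ls$ratio_mean, 2.04)
  expect_equal(ls$ratio_sd, 0.53)
  expect_equal(ls$per_chromosome$ratio_cm_mb[ls$per_chromosome$chromosome == "Pv9"],
               1.24)
  # without the printed totals the genome ratio is the column-sum ratio,
  # which equals the mean-of-ratios value for this table
  ls2 <- landscape_summary(ref)
  expect_equal(ls2$genome_ratio_cm_mb, 2.04)
  expect_gt(abs(ls$genome_ratio_cm_mb - ls$ratio_mean), 0.05)
})

test_that("half-up rounding is applied to the reported ratios", {
  tbl <- data.frame(chromosome = "c1", cm = 28.65, bp = 1e7)
  ls <- landscape_summary(tbl)
  expect_equal(ls$per_chromosome$ratio_cm_mb, 2.87)  # 2.865 rounds up
})
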