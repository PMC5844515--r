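test_that("two-point estimates match direct arithmetic", {
  # 50 informative lines, 5 recombinant
  calls <- cbind(m1 = rep("A", 50),
                 m2 = c(rep("B", 5), rep("A", 45)))
  rownames(calls) <- sprintf("L%02d", 1:50)
  tp <- estimate_rf(calls, "m1", "m2")
  expect_equal(tp$R, 0.1)
  expect_equal(tp$lod, 5 * log10(0.2) + 45 * log10(1.8), tolerance = 1e-12)
  expect_equal(round(tp$lod, 2), 7.99)
  # identical columns
  calls2 <- cbind(m1 = rep(c("A", "B"), 20), m2 = rep(c("A", "B"), 20))
  rownames(calls2) <- sprintf("L%02d", 1:40)
  tp2 <- estimate_rf(calls2, "m1", "m2")
  expect_equal(tp2$R, 0)
  expect_equal(tp2$r, 0)
  expect_equal(tp2$lod, 40 * log10(2))
  # HW inversion closed form
  expect_equal(hw_correct(0.2), 0.125)
  # H and missing are excluded pairwise; < 2 informative -> sentinel
  calls3 <- calls_from_strings("AH", "H-", "-B")
  expect_false(estimate_rf(calls3, "m1", "m2")$informative)
})

test_that("LOD is zero at R = 0.5 and rf_matrices agrees with estimate_rf", {
  set.seed(1)
  calls <- matrix(sample(c("A", "B", "H", NA), 300, replace = TRUE,
                         prob = c(.45, .45, .05, .05)),
                  nrow = 30, dimnames = list(sprintf("L%d", 1:30),
                                             sprintf("m%d", 1:10)))
  rf <- rf_matrices(calls)
  for (pair in list(c(1, 2), c(3, 7), c(9, 10))) {
    tp <- estimate_rf(calls, pair[1], pair[2])
    if (tp$informative) {
      expect_equal(rf$R[pair[1], pair[2]], tp$R)
      expect_equal(rf$lod[pair[1], pair[2]], tp$lod)
    }
  }
  # exact R = 0.5: 10 recombinant of 20
  calls4 <- cbind(m1 = rep("A", 20), m2 = rep(c("A", "B"), 10))
  rownames(calls4) <- sprintf("L%d", 1:20)
  expect_equal(estimate_rf(calls4, "m1", "m2")$lod, 0)
})

test_that("Kosambi transform matches closed forms and inverts", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))
  expect_equal(round(kosambi_cm(0.25), 2), 27.47)
  expect_equal(round(kosambi_cm(0.1), 2), 10.14)
  r <- seq(0, 0.49, by = 0.001)
  expect_equal(kosambi_r(kosambi_cm(r)), r, tolerance = 1e-12)
  expect_warning(out <- kosambi_cm(0.5), "capped")
  expect_equal(out, 50)
})

test_that("grouping is transitive and recovers simulated chromosomes", {
  # chain a-b, b-c strong; a-c weak -> still one group
  rf <- list(markers = c("a", "b", "c"),
             r = matrix(c(0, .05, .45, .05, 0, .05, .45, .05, 0), 3, 3,
                        dimnames = list(c("a","b","c"), c("a","b","c"))),
             lod = matrix(c(0, 8, 1, 8, 0, 8, 1, 8, 0), 3, 3,
                          dimnames = list(c("a","b","c"), c("a","b","c"))))
  class(rf) <- "rf_matrices"
  rf$n <- rf$n_rec <- rf$R <- rf$r
  groups <- group_markers(rf)
  expect_length(groups, 1)
  expect_setequal(groups[[1]], c("a", "b", "c"))

  g <- bean_genome_spec(n_chrom = 3, n_markers = 60, seed = 31)
  ril <- simulate_ril_population(g, ril_config(n_lines = 200, seed = 32))
  rf2 <- rf_matrices(ril$calls)
  groups2 <- group_markers(rf2)
  expect_length(groups2, 3)
  for (grp in groups2)
    expect_length(unique(g$markers$chrom[match(grp, g$markers$marker)]), 1)
  # invariance to marker permutation of the input
  set.seed(33)
  perm <- sample(ncol(ril$calls))
  groups3 <- group_markers(rf_matrices(ril$calls[, perm]))
  canon <- function(gs) sort(vapply(gs, function(g)
    paste(sort(g), collapse = ","), character(1)))
  expect_identical(canon(groups2), canon(groups3))
})

test_that("ordering matches brute force on small groups and truth when clean", {
  # 3 markers, only consistent order
  mk <- c("a", "b", "c")
  rmat <- matrix(c(0, .05, .10, .05, 0, .05, .10, .05, 0), 3, 3,
                 dimnames = list(mk, mk))
  rf <- structure(list(markers = mk, r = rmat,
                       lod = matrix(10, 3, 3, dimnames = list(mk, mk))),
                  class = "rf_matrices")
  ord <- order_markers(mk, rf)
  expect_true(identical(ord, c("a", "b", "c")) ||
                identical(ord, c("c", "b", "a")))

  # 6 markers from a simulated chromosome: heuristic SARF equals brute force
  g <- tiny_genome(1, m = 6, len = 30e6, rate = 3)
  ril <- simulate_ril_population(g, ril_config(n_lines = 100, seed = 41))
  rf2 <- rf_matrices(ril$calls)
  est <- order_markers(colnames(ril$calls), rf2)
  bf <- brute_force_order(colnames(ril$calls), rf2)
  sarf_of <- function(ids) {
    idx <- match(ids, rf2$markers)
    sum(rf2$r[cbind(idx[-length(idx)], idx[-1])])
  }
  expect_equal(sarf_of(est), bf$sarf, tolerance = 1e-12)

  # noiseless-ish 20-marker chromosome: truth order recovered up to reversal
  g3 <- tiny_genome(1, m = 20, len = 50e6, rate = 3)
  ril3 <- simulate_ril_population(
    g3, ril_config(n_lines = 400, missing_rate = 0, het_rate = 0, seed = 43))
  rf3 <- rf_matrices(ril3$calls)
  est3 <- order_markers(colnames(ril3$calls), rf3, calls = ril3$calls)
  truth <- g3$markers$marker
  expect_true(identical(est3, truth) || identical(est3, rev(truth)))
})

test_that("map assembly accumulates Kosambi distances and ignores reversal", {
  mk <- c("a", "b", "c")
  rmat <- matrix(c(0, .1, .2, .1, 0, .1, .2, .1, 0), 3, 3,
                 dimnames = list(mk, mk))
  rf <- structure(list(markers = mk, r = rmat), class = "rf_matrices")
  map <- assemble_map(list(mk), rf)
  expect_equal(map$cm, c(0, 10.136628, 20.273255), tolerance = 1e-6)
  map_rev <- assemble_map(list(rev(mk)), rf)
  expect_equal(max(map$cm), max(map_rev$cm))
  # single-marker group has zero length
  map1 <- assemble_map(list("a"), rf)
  expect_equal(map1$cm, 0)
})

test_that("anchor placement labels by majority and reports conflicts", {
  map <- data.frame(linkage_group = rep(c("LG-1", "LG-2", "LG-3"), each = 3),
                    marker = c("a1", "a2", "a3", "b1", "b2", "b3",
                               "c1", "c2", "c3"),
                    cm = rep(c(0, 5, 10), 3), chromosome = NA_character_,
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  anchors <- data.frame(
    marker = c("a1", "a2", "a3", "b1", "b2", "b3", "c1", "c2"),
    chromosome = c("Pv2", "Pv2", "Pv2", "Pv2", "Pv2", "Pv5", "Pv3", "Pv5"))
  # LG-1 and LG-2 both resolve to Pv2 -> duplicate-claim warning
  expect_warning(out <- place_anchors(map, anchors), "claim chromosome")
  expect_equal(unique(out$chromosome[out$linkage_group == "LG-1"]), "Pv2")
  expect_equal(unique(out$chromosome[out$linkage_group == "LG-2"]), "Pv2")
  expect_true("LG-2" %in% names(attr(out, "conflicts")))
  # LG-3 anchors tie 1-1: unlabeled, conflict recorded
  expect_true(is.na(unique(out$chromosome[out$linkage_group == "LG-3"])))
  expect_true("LG-3" %in% names(attr(out, "conflicts")))
})

test_that("map summary reproduces totals and the uniform chi-square", {
  map <- data.frame(
    linkage_group = rep(c("LG-1", "LG-2"), each = 3),
    marker = letters[1:6],
    cm = c(0, 10, 20, 0, 15, 30), chromosome = NA, stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  s <- suppressWarnings(map_summary(map))
  expect_equal(s$total_cm, 50)
  expect_equal(s$avg_group_cm, 25)
  expect_equal(s$avg_marker_spacing_cm, 50 / 6)
  expect_equal(s$chisq$statistic, 0)
  expect_equal(s$chisq$p.value, 1)
})
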