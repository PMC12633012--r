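# marker detection, signature construction, module scoring, AT2-state
# assignment, maturation sets/scores, nearest-centroid labels

test_that("rank_markers agrees with stats::wilcox.test and applies filters", {
  set.seed(2)
  n1 <- 40L; n2 <- 50L
  x <- matrix(rpois(30 * (n1 + n2), 3), 30)
  x[1:5, seq_len(n1)] <- x[1:5, seq_len(n1)] + rpois(5 * n1, 4)
  rownames(x) <- paste0("g", 1:30)
  colnames(x) <- paste0("c", 1:(n1 + n2))
  xl <- log1p(x)
  labels <- rep(c("A", "B"), c(n1, n2))
  mr <- rank_markers(xl, labels, "A", "B", min_pct = 0, min_logfc = 0,
                     exclude_patterns = character(0))
  # oracle: per-gene wilcox.test, normal approximation + continuity
  for (g in sample(mr$gene, 8)) {
    ref <- suppressWarnings(stats::wilcox.test(
      xl[g, labels == "A"], xl[g, labels == "B"], exact = FALSE,
      correct = TRUE))$p.value
    expect_equal(mr$p[mr$gene == g], ref, tolerance = 1e-10)
  }
  # planted genes dominate the ranking
  expect_true(all(paste0("g", 1:5) %in% utils::head(mr$gene, 8)))
  expect_true(all(mr$p_adjusted >= mr$p))
})

test_that("pct and logFC filters and exclusion patterns drop genes", {
  # gene expressed in 20% of A and 10% of B is excluded at min_pct = 0.25
  x <- rbind(rare = c(rep(1, 4), rep(0, 16), rep(1, 2), rep(0, 18)),
             common = c(rpois(20, 5) + 8, rpois(20, 5)),
             `MT-1` = rpois(40, 10) + c(rep(20, 20), rep(0, 20)))
  colnames(x) <- paste0("c", 1:40)
  labels <- rep(c("A", "B"), each = 20)
  mr <- rank_markers(log1p(x), labels, "A", "B")
  expect_false("rare" %in% mr$gene)
  expect_false("MT-1" %in% mr$gene)   # excluded by pattern despite signal
  expect_true("common" %in% mr$gene)
  expect_error(rank_markers(log1p(x), labels, "A", "A"), "overlap")
})

test_that("build_signature ranks by |logFC| with p then gene-ID tie-breaks", {
  mr <- data.frame(gene = c("g1", "g2", "g3"),
                   log2fc = c(2, 1, 0.5), pct_in = 1, pct_out = 1,
                   p = c(0.01, 0.01, 0.01), p_adjusted = 0.03)
  class(mr) <- c("marker_result", "data.frame")
  expect_equal(build_signature(mr, 2, "up")$genes, c("g1", "g2"))
  # tie in logFC -> smaller p first; tie in p -> lexicographic
  mr2 <- data.frame(gene = c("b", "a", "c"), log2fc = c(1, 1, 1),
                    pct_in = 1, pct_out = 1, p = c(0.02, 0.02, 0.001),
                    p_adjusted = 1)
  class(mr2) <- c("marker_result", "data.frame")
  expect_equal(build_signature(mr2, 3, "up")$genes, c("c", "a", "b"))
  expect_warning(build_signature(mr2, 5, "up"), "only")
  expect_error(build_signature(mr2[0, ], 2, "up"), "empty")
  # gene order permutation does not change the result
  mr3 <- mr2[c(3, 1, 2), ]
  expect_equal(build_signature(mr3, 3, "up")$genes,
               build_signature(mr2, 3, "up")$genes)
})

test_that("degenerate binning reduces the module score to a direct contrast", {
  x <- matrix(c(1, 2, 3, 4,
                2, 1, 0, 1,
                5, 5, 5, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:4)))
  x <- rbind(x, g4 = c(0, 1, 2, 3))
  sig <- structure(list(name = "m", genes = "g1"), class = "gene_signature")
  sc <- score_modules(x, sig, n_bins = 1L, n_controls = 3L, seed = 1L)
  expected <- x["g1", ] - colMeans(x[c("g2", "g3", "g4"), ])
  expect_equal(unname(sc[, "m"]), unname(expected), tolerance = 1e-12)
})

test_that("module scores are seed-deterministic and warn on missing genes", {
  norm <- small_cohort_norm()
  sig <- structure(list(name = "s",
                        genes = c(rownames(norm$values)[1:20], "NOPE")),
                   class = "gene_signature")
  a <- suppressWarnings(score_modules(norm, sig, n_controls = 10L, seed = 3L))
  b <- suppressWarnings(score_modules(norm, sig, n_controls = 10L, seed = 3L))
  expect_identical(a, b)
  expect_warning(score_modules(norm, sig, n_controls = 10L, seed = 3L),
                 "missing")
  bad <- structure(list(name = "x", genes = "NOPE"), class = "gene_signature")
  expect_error(suppressWarnings(score_modules(norm, bad)), "no genes")
})

test_that("panel-count AT2-state rules match the printed thresholds", {
  counts <- Matrix::Matrix(rbind(F1 = c(5, 1, 0, 2), F2 = c(0, 0, 0, 2),
                                 C1 = c(0, 1, 3, 4), C2 = c(0, 0, 0, 0)),
                           sparse = TRUE)
  colnames(counts) <- paste0("c", 1:4)
  lab <- assign_at2_state(counts, c("F1", "F2"), c("C1", "C2"),
                          mode = "panel_counts", min_counts = 2L)
  # c1: 5 FMO5 / 0 CFTR -> FMO5+; c2: 1/1 both below threshold ->
  # Unassigned; c3: 0/3 -> CFTR+; c4: 4/4 tied above threshold -> Unassigned
  expect_equal(lab, c("FMO5+", "Unassigned", "CFTR+", "Unassigned"))
  expect_error(assign_at2_state(counts, character(0), "C1",
                                mode = "panel_counts"), "empty")
})

test_that("score-mode AT2-state assignment recovers planted states", {
  coh <- small_cohort()
  norm <- small_cohort_norm()
  tr <- coh$truth$cells[match(colnames(norm$values),
                              coh$truth$cells$cell_id), ]
  at2 <- !is.na(tr$at2_state)
  fmo5 <- structure(list(name = "FMO5",
                         genes = grep("^FMO5S", rownames(norm$values),
                                      value = TRUE)),
                    class = "gene_signature")
  cftr <- structure(list(name = "CFTR",
                         genes = grep("^CFTRS", rownames(norm$values),
                                      value = TRUE)),
                    class = "gene_signature")
  xsub <- structure(list(values = norm$values[, at2]),
                    class = "normalized_matrix")
  lab <- suppressWarnings(
    assign_at2_state(xsub, fmo5, cftr, mode = "score", seed = 1L))
  assigned <- lab != "Unassigned"
  acc <- mean(sub("\\+$", "", lab[assigned]) == tr$at2_state[at2][assigned])
  expect_gt(acc, 0.9)
})

test_that("maturation sets are disjoint and recovered from the series", {
  cfg <- cohort_config(n_genes = 600L, cells_per_specimen = 150L, seed = 15L)
  ser <- generate_maturation_series(cfg, program_size = 40L, types = "AT2")
  norm <- normalize_counts(ser)
  tr <- ser$truth$cells
  sets <- suppressWarnings(build_maturation_sets(
    norm$values, tr$stage, tr$type, top_n = 40L))
  expect_length(intersect(sets$AT2$on$genes, sets$AT2$off$genes), 0L)
  expect_gte(mean(grepl("^ON\\.AT2\\.", sets$AT2$on$genes)), 0.9)
  expect_gte(mean(grepl("^OFF\\.AT2\\.", sets$AT2$off$genes)), 0.9)
})

test_that("fetal cells score below postnatal cells on the on-program", {
  cfg <- cohort_config(n_genes = 600L, cells_per_specimen = 150L, seed = 16L)
  ser <- generate_maturation_series(cfg, program_size = 40L, types = "AT2")
  norm <- normalize_counts(ser)
  tr <- ser$truth$cells
  sets <- suppressWarnings(build_maturation_sets(
    norm$values, tr$stage, tr$type, top_n = 40L))
  sc <- suppressWarnings(score_maturation(norm$values, tr$type, sets,
                                          seed = 5L))
  sc <- sc[sc$type == "AT2", ]
  stage <- tr$stage[match(sc$cell_id, tr$cell_id)]
  ht <- stats::wilcox.test(sc$on_score[stage == "fetal"],
                           sc$on_score[stage != "fetal"],
                           alternative = "less")
  expect_lt(ht$p.value, 1e-6)
  # on and off move in opposite directions across stages
  idx <- tr$stage_index[match(sc$cell_id, tr$cell_id)]
  on_m <- tapply(sc$on_score, idx, mean)
  off_m <- tapply(sc$off_score, idx, mean)
  expect_gt(cor(as.numeric(names(on_m)), on_m), 0.9)
  expect_lt(cor(as.numeric(names(off_m)), off_m), -0.9)
})

test_that("nearest-centroid assignment handles exact matches and ties", {
  set.seed(4)
  cen <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("g", 1:20),
                                                  c("typeA", "typeB")))
  q <- cbind(cellA = cen[, "typeA"], mix = rnorm(20))
  res <- assign_labels_nearest_centroid(q, cen, n_hvg = 20L)
  expect_equal(res$label[res$cell_id == "cellA"], "typeA")
  expect_gt(res$confidence[res$cell_id == "cellA"], 0)
  # identical centroids: lexicographic winner, confidence 0
  cen2 <- cbind(b_type = cen[, 1], a_type = cen[, 1])
  res2 <- assign_labels_nearest_centroid(q[, "cellA", drop = FALSE], cen2,
                                         n_hvg = 20L)
  expect_equal(res2$label, "a_type")
  expect_equal(res2$confidence, 0)
  # constant query cell is Unassigned
  resc <- assign_labels_nearest_centroid(
    matrix(1, 20, 1, dimnames = list(paste0("g", 1:20), "flat")), cen,
    n_hvg = 20L)
  expect_equal(resc$label, "Unassigned")
})

test_that("held-out cells are labelled accurately by nearest centroid", {
  norm <- small_cohort_norm()
  coh <- small_cohort()
  type <- coh$truth$cells$type[match(colnames(norm$values),
                                     coh$truth$cells$cell_id)]
  set.seed(10)
  half <- sample(ncol(norm$values), ncol(norm$values) %/% 2)
  cen <- make_centroids(norm$values[, half], type[half])
  res <- assign_labels_nearest_centroid(
    structure(list(values = norm$values[, -half]),
              class = "normalized_matrix"), cen)
  expect_gt(mean(res$label == type[-half]), 0.9)
})
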