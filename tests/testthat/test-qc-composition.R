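# QC filtering, normalization, specimen classification, equal-weight
# composition and the composition test

make_meta_cohort <- function(meta) {
  counts <- Matrix::Matrix(1, 2, nrow(meta), sparse = TRUE,
                           dimnames = list(c("g1", "g2"), meta$cell_id))
  structure(list(counts = counts, cell_meta = meta),
            class = "cohort_counts")
}

test_that("QC boundary semantics follow the printed wording", {
  meta <- data.frame(
    cell_id = sprintf("c%02d", 1:10),
    n_features = c(499, 7501, 2000, 2000, rep(2000, 6)),
    n_molecules = c(5000, 5000, 1000, 5000, rep(5000, 6)),
    frac_mito = c(0.01, 0.01, 0.01, 0.05, rep(0.01, 6)),
    frac_ribo = c(0.02, 0.02, 0.02, 0.02, rep(0.02, 6)),
    stringsAsFactors = FALSE)
  out <- apply_qc_filters(make_meta_cohort(meta))
  # 499 features (below), 7501 (above), exactly 1000 molecules ("more
  # than" is strict) and exactly 5% mito ("less than" is strict) all fail
  expect_equal(ncol(out$counts), 6L)
  expect_equal(out$cell_meta$cell_id, sprintf("c%02d", 5:10))
  # boundary passes: 500 and 7500 features inclusive, 1001 molecules
  meta2 <- meta[5:7, ]
  meta2$n_features <- c(500, 7500, 2000)
  meta2$n_molecules <- c(1001, 5000, 5000)
  expect_equal(ncol(apply_qc_filters(make_meta_cohort(meta2))$counts), 3L)
})

test_that("QC filter is idempotent and matches the per-cell predicate oracle", {
  coh <- small_cohort()
  # plant violators: inflate mito fraction / shrink features on ~12% cells
  meta <- coh$cell_meta
  set.seed(1)
  bad <- sample(nrow(meta), round(0.12 * nrow(meta)))
  half <- seq_along(bad) %% 2 == 0
  meta$frac_mito[bad[half]] <- 0.2
  meta$n_features[bad[!half]] <- 100
  coh$cell_meta <- meta
  thr <- qc_thresholds()
  once <- apply_qc_filters(coh, thr)
  twice <- apply_qc_filters(once, thr)
  expect_identical(once$counts, twice$counts)
  # independent predicate oracle
  keep <- vapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    m$n_features >= 500 && m$n_features <= 7500 && m$n_molecules > 1000 &&
      m$frac_mito < 0.05 && m$frac_ribo < 0.075
  }, logical(1))
  expect_equal(ncol(once$counts), sum(keep))
  expect_equal(colnames(once$counts), colnames(coh$counts)[keep])
})

test_that("normalization matches the closed form and commutes with subsetting", {
  # single-value example: count 10, total 10,000, scale 1e4 -> ln(11)
  counts <- Matrix::Matrix(c(10, 9990), 2, 1, sparse = TRUE,
                           dimnames = list(c("g1", "g2"), "c1"))
  n <- normalize_counts(list(counts = counts), scale = 1e4)
  expect_equal(n$values["g1", "c1"], log(11), tolerance = 1e-12)
  # random matrix vs an independent two-line recomputation
  set.seed(7)
  m <- Matrix::Matrix(matrix(rpois(50 * 20, 5), 50, 20), sparse = TRUE)
  dimnames(m) <- list(paste0("g", 1:50), paste0("c", 1:20))
  n <- normalize_counts(list(counts = m))
  dense <- as.matrix(m)
  expected <- log1p(sweep(dense, 2, colSums(dense), "/") * 1e4)
  expect_equal(as.matrix(n$values), expected, tolerance = 1e-12)
  # zero count stays zero; per-cell operation commutes with subsetting
  expect_true(all(as.matrix(n$values)[dense == 0] == 0))
  sub <- normalize_counts(list(counts = m[, 3:7]))
  expect_equal(as.matrix(sub$values), as.matrix(n$values[, 3:7]))
  # zero-total cell errors
  m0 <- m; m0[, 2] <- 0
  expect_error(normalize_counts(list(counts = m0)), "zero total")
})

test_that("specimen classification applies the enrichment rule", {
  cells <- rbind(
    data.frame(specimen = "A", at2_state = rep(c("FMO5", "CFTR"), c(80, 20))),
    data.frame(specimen = "B", at2_state = rep(c("FMO5", "CFTR"), c(20, 80))),
    data.frame(specimen = "C", at2_state = rep(c("FMO5", "CFTR"), c(50, 50))),
    data.frame(specimen = "D", at2_state = rep(c("FMO5", "CFTR"), c(15, 15))),
    data.frame(specimen = "E", at2_state = rep("Unassigned", 100)))
  g <- classify_specimens_by_at2_state(cells)
  expect_equal(g$class[match(c("A", "B", "C", "D", "E"), g$specimen)],
               c("FMO5_enriched", "CFTR_enriched", "mixed", "unclassified",
                 "unclassified"))
  # theta boundary: p = 0.65 exactly is enriched (>=)
  b <- classify_specimens_by_at2_state(
    data.frame(specimen = "X", at2_state = rep(c("FMO5", "CFTR"), c(65, 35))))
  expect_equal(b$class, "FMO5_enriched")
})

test_that("planted specimen classes are recovered from generated cohorts", {
  hits <- 0L; total <- 0L
  for (seed in 1:6) {
    cfg <- cohort_config(n_specimens_per_class = c(2L, 2L, 2L),
                         cells_per_specimen = 300L, n_genes = 400L,
                         seed = seed)
    coh <- generate_expression_cohort(cfg)
    tr <- coh$truth$cells
    at2 <- tr[!is.na(tr$at2_state), c("specimen", "at2_state")]
    g <- classify_specimens_by_at2_state(at2, min_at2_cells = 20L)
    planted <- sub("^SP\\d+_", "", g$specimen)
    ok <- g$class == planted
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.9)
})

test_that("equal-weight composition matches hand computation", {
  cells <- data.frame(
    specimen = c("a", "a", "b", "b", "b", "b", "b", "b"),
    type = c("X", "X", "X", "X", "X", "Y", "Y", "Y"))
  groups <- data.frame(specimen = c("a", "b"), class = c("A", "B"))
  wc <- weighted_composition(cells, groups)
  expect_equal(wc$overall[["X"]], 0.75)
  expect_equal(wc$overall[["Y"]], 0.25)
  expect_equal(wc$class_shares["Y", "A"], 0)
  expect_equal(wc$class_shares["Y", "B"], 1)
  # weights sum exactly to 1/G per class and 1 overall
  cls <- groups$class[match(cells$specimen, groups$specimen)]
  expect_equal(sum(wc$weights), 1, tolerance = 1e-14)
  for (g in c("A", "B")) {
    expect_equal(sum(wc$weights[cls == g]), 1 / wc$G, tolerance = 1e-14)
  }
  # identical class compositions give equal class shares
  cells2 <- data.frame(specimen = rep(c("a", "b"), each = 4),
                       type = rep(c("X", "Y"), 4))
  wc2 <- weighted_composition(cells2, groups)
  expect_true(all(abs(wc2$class_shares - 0.5) < 1e-12))
})

test_that("composition test matches the enumeration oracle and edge cases", {
  mk <- function(props, spec_prefix, cls, n_cells = 10L) {
    do.call(rbind, lapply(seq_along(props), function(i) {
      k <- round(props[i] * n_cells)
      data.frame(specimen = paste0(spec_prefix, i),
                 type = rep(c("T", "other"), c(k, n_cells - k)))
    }))
  }
  cells <- rbind(mk(c(0.1, 0.2), "a", "A"), mk(c(0.3, 0.4), "b", "B"))
  groups <- data.frame(specimen = c("a1", "a2", "b1", "b2"),
                       class = rep(c("A", "B"), each = 2))
  res <- compare_composition(cells, groups, "T", classes = c("A", "B"))
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_equal(res$p, enum_wilcox_p(c(0.1, 0.2), c(0.3, 0.4)),
               tolerance = 1e-12)
  # identical samples -> p = 1
  cells_id <- rbind(mk(c(0.1, 0.2), "a", "A"), mk(c(0.1, 0.2), "b", "B"))
  res_id <- compare_composition(cells_id, groups, "T", classes = c("A", "B"))
  expect_equal(res_id$p, 1)
  # a group with < 2 specimens errors
  g1 <- data.frame(specimen = c("a1", "b1", "b2"),
                   class = c("A", "B", "B"))
  expect_error(compare_composition(cells, g1, "T", classes = c("A", "B")),
               "fewer than 2")
})

test_that("qPCR relative abundance follows the 18S normalization formula", {
  expect_equal(qpcr_relative_abundance(20, 10), 2^(-10) * 1e4)
  expect_equal(qpcr_relative_abundance(20, 10), 9.765625)
  expect_equal(qpcr_relative_abundance(15, 15), 10000)
  expect_equal(qpcr_relative_abundance(10, 12), 40000)
  expect_error(qpcr_relative_abundance(NA, 10))
})

test_that("zscore_rows standardizes with sample SD", {
  x <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_rows(x)
  expect_equal(z["a", ], (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
})
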