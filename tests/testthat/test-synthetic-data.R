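# synthetic-data generator: determinism, planted-signal structure,
# conservation, spatial constraints

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- cohort_config(n_specimens_per_class = c(1L, 1L, 1L),
                       cells_per_specimen = 60L, n_genes = 400L, seed = 11L)
  a <- generate_expression_cohort(cfg)
  b <- generate_expression_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cell_meta, b$cell_meta)
  expect_identical(a$truth, b$truth)
})

test_that("Poisson mode conserves the drawn library size per cell", {
  cfg <- cohort_config(n_specimens_per_class = c(1L, 0L, 1L),
                       cells_per_specimen = 80L, n_genes = 400L,
                       nb_dispersion = Inf, seed = 3L)
  coh <- generate_expression_cohort(cfg)
  expect_equal(unname(Matrix::colSums(coh$counts)),
               round(coh$truth$cells$library_size))
})

test_that("marker genes are elevated in their own type (Poisson mode MC)", {
  cfg <- cohort_config(n_specimens_per_class = c(1L, 1L, 1L),
                       cells_per_specimen = 400L, n_genes = 400L,
                       nb_dispersion = Inf, seed = 1L)
  coh <- generate_expression_cohort(cfg)
  truth <- coh$truth
  cpm <- t(t(as.matrix(coh$counts)) / Matrix::colSums(coh$counts))
  ratios <- c()
  for (t in c("AT2", "AF_c3", "Capillary")) {
    mk <- truth$genes$gene[truth$genes$program == paste0("marker:", t)]
    own <- truth$cells$type == t
    ratios <- c(ratios, rowMeans(cpm[mk, own, drop = FALSE]) /
                  rowMeans(cpm[mk, !own, drop = FALSE]))
  }
  expect_true(all(ratios > exp(cfg$marker_log_fold) / 2))
})

test_that("marker_log_fold = 0 removes the type signal", {
  cfg <- cohort_config(n_specimens_per_class = c(1L, 0L, 1L),
                       cells_per_specimen = 200L, n_genes = 400L,
                       marker_log_fold = 0, seed = 9L)
  coh <- generate_expression_cohort(cfg)
  norm <- normalize_counts(coh)
  type <- coh$truth$cells$type
  two <- type %in% c("AT2", "Capillary")
  mr <- rank_markers(norm$values[, two], type[two], "AT2", "Capillary",
                     min_pct = 0, min_logfc = 0,
                     exclude_patterns = character(0))
  rate <- mean(mr$p < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.10)
})

test_that("maturation on genes rise and off genes fall across stages", {
  cfg <- cohort_config(n_genes = 500L, cells_per_specimen = 120L, seed = 5L)
  ser <- generate_maturation_series(cfg, program_size = 30L, types = "AT2",
                                    arrest_specimens = 1L)
  tr <- ser$truth$cells
  at2 <- tr$type == "AT2" & !tr$arrested
  cpm <- t(t(as.matrix(ser$counts[, at2])) /
             Matrix::colSums(ser$counts[, at2]))
  on_genes <- ser$truth$genes$gene[
    ser$truth$genes$program == "maturation_on:AT2"]
  off_genes <- ser$truth$genes$gene[
    ser$truth$genes$program == "maturation_off:AT2"]
  stg <- ser$truth$cells$stage_index[at2]
  on_means <- vapply(sort(unique(stg)), function(s)
    mean(cpm[on_genes, stg == s]), numeric(1))
  off_means <- vapply(sort(unique(stg)), function(s)
    mean(cpm[off_genes, stg == s]), numeric(1))
  expect_true(all(diff(on_means) > 0))
  expect_true(all(diff(off_means) < 0))
})

test_that("disease-arrest specimens express stage-2 program levels", {
  cfg <- cohort_config(n_genes = 500L, cells_per_specimen = 200L, seed = 6L)
  ser <- generate_maturation_series(cfg, program_size = 30L, types = "AT2",
                                    arrest_specimens = 1L)
  tr <- ser$truth$cells
  on_genes <- ser$truth$genes$gene[
    ser$truth$genes$program == "maturation_on:AT2"]
  cpm <- t(t(as.matrix(ser$counts)) / Matrix::colSums(ser$counts))
  at2 <- tr$type == "AT2"
  arrested_mean <- mean(cpm[on_genes, at2 & tr$arrested])
  stage2_mean <- mean(cpm[on_genes, at2 & tr$stage_index == 2 & !tr$arrested])
  final_mean <- mean(cpm[on_genes, at2 & tr$stage_index == 4 & !tr$arrested])
  # arrested cells match stage 2, not their recorded final stage
  expect_lt(abs(arrested_mean - stage2_mean) / stage2_mean, 0.15)
  expect_gt(abs(arrested_mean - final_mean) / final_mean, 0.15)
})

test_that("ramp amplitude 0 leaves on/off genes neutral-like", {
  cfg <- cohort_config(n_genes = 500L, cells_per_specimen = 120L, seed = 8L)
  ser <- generate_maturation_series(cfg, program_size = 30L, types = "AT2",
                                    ramp_log_amplitude = 0)
  tr <- ser$truth$cells
  at2 <- tr$type == "AT2"
  cpm <- t(t(as.matrix(ser$counts[, at2])) /
             Matrix::colSums(ser$counts[, at2]))
  on_genes <- ser$truth$genes$gene[
    ser$truth$genes$program == "maturation_on:AT2"]
  stg <- tr$stage_index[at2]
  fetal <- mean(cpm[on_genes, stg == 1])
  final <- mean(cpm[on_genes, stg == max(stg)])
  expect_lt(abs(final - fetal) / fetal, 0.1)
})

test_that("spatial hard-core spacing holds exactly", {
  scfg <- spatial_config(n_sections = 1L, cells_per_section = 400L,
                         min_spacing_um = 5, section_extent_um = c(400, 400),
                         seed = 2L)
  sp <- generate_spatial_sections(scfg)
  xy <- as.matrix(sp$sections[[1]]$cells[, c("x_um", "y_um")])
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  expect_gte(min(d), 5)
})

test_that("per-region type frequencies match composition within 3 SE", {
  sp <- default_spatial_world()
  comp <- sp$config$region_catalog$composition
  cells <- do.call(rbind, lapply(sp$sections, function(s) s$cells))
  for (r in colnames(comp)) {
    sel <- cells$region == r
    n <- sum(sel)
    for (l in rownames(comp)) {
      p <- comp[l, r]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(cells$label[sel] == l) - p), 3 * se + 1e-12,
                label = paste("region", r, "label", l))
    }
  }
})

test_that("degenerate single-region layout still generates", {
  cat1 <- default_region_catalog()
  cat1$composition <- cat1$composition[, "alveolar_1", drop = FALSE]
  cat1$area_share <- c(alveolar_1 = 1)
  scfg <- spatial_config(n_sections = 1L, cells_per_section = 200L,
                         region_catalog = cat1,
                         section_extent_um = c(300, 300), seed = 4L)
  sp <- generate_spatial_sections(scfg)
  expect_equal(unique(sp$sections[[1]]$cells$region), "alveolar_1")
})

test_that("impossible density errors after bounded attempts", {
  scfg <- spatial_config(n_sections = 1L, cells_per_section = 500L,
                         min_spacing_um = 50,
                         section_extent_um = c(100, 100), seed = 1L)
  expect_error(generate_spatial_sections(scfg), "min spacing")
})

test_that("salt-and-pepper layout intermixes regions at patch scale", {
  scfg <- spatial_config(n_sections = 1L, cells_per_section = 1000L,
                         region_layout = "salt_and_pepper", patch_um = 150,
                         seed = 7L)
  sp <- generate_spatial_sections(scfg)
  cells <- sp$sections[[1]]$cells
  # with iid patches, many distinct contiguous runs of regions exist
  expect_gt(length(unique(cells$region)), 2L)
  expect_gt(length(rle(cells$region[order(cells$x_um)])$lengths), 20L)
})

test_that("oversized gene blocks are a configuration error", {
  cfg <- cohort_config(n_genes = 100L, seed = 1L)
  expect_error(generate_expression_cohort(cfg), "exceed")
  cfg2 <- cohort_config(n_genes = 700L, seed = 1L)
  expect_error(
    generate_maturation_series(cfg2, program_size = 100L,
                               types = c("AT2", "AT1", "AF_c1_2")),
    "exceed")
})
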