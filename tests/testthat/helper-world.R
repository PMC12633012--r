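# Shared fixtures, built in code and memoized so expensive worlds are
# generated once per test run.

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, force(expr), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# small cohort used by several signature/composition tests
small_cohort <- function() memo("small_cohort", {
  generate_expression_cohort(cohort_config(
    n_specimens_per_class = c(2L, 2L, 2L), cells_per_specimen = 250L,
    n_genes = 600L, seed = 42L))
})

small_cohort_norm <- function() memo("small_cohort_norm", {
  normalize_counts(apply_qc_filters(small_cohort()))
})

# the default-scale spatial world of the niche/colocalization acceptance
# criteria: 5 sections x ~3000 cells, 4 regions, default catalog
default_spatial_world <- function() memo("default_spatial_world", {
  generate_spatial_sections(spatial_config(seed = 20240501L))
})

default_niche_models <- function() memo("default_niche_models", {
  sp <- default_spatial_world()
  catalog <- rownames(sp$config$region_catalog$composition)
  lapply(sp$sections, function(s) {
    prof <- neighborhood_profiles(s, k = 20L, catalog = catalog)
    fit_niches(prof, K = 4L, seed = derive_seed_for_tests(s$section_id))
  })
})

derive_seed_for_tests <- function(tag) {
  sum(utf8ToInt(tag)) %% 1000L + 7L
}

# brute-force k-NN oracle: per-point loop, order() ranking
brute_knn <- function(xy, k) {
  n <- nrow(xy)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    d[i] <- Inf
    out[i, ] <- order(d)[seq_len(k)]
  }
  out
}

# brute-force directed mean nearest-neighbour distance oracle
brute_dnn <- function(A, B) {
  mean(vapply(seq_len(nrow(A)), function(i) {
    min(sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2))
  }, numeric(1)))
}

# exact two-sided Wilcoxon rank-sum p by exhaustive enumeration (no ties)
enum_wilcox_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  Ws <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(Ws <= W_obs); p_high <- mean(Ws >= W_obs)
  min(1, 2 * min(p_low, p_high))
}

# toy spatial map constructor
toy_map <- function(x, y, label, section_id = "T01") {
  structure(list(
    section_id = section_id,
    cells = data.frame(cell_id = sprintf("%s_C%03d", section_id,
                                         seq_along(x)),
                       section_id = section_id, x_um = x, y_um = y,
                       label = label, stringsAsFactors = FALSE),
    panel_counts = NULL), class = "spatial_map")
}
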