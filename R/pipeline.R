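# End-to-end orchestration: simulate -> QC -> signatures -> AT2-state
# assignment -> specimen classification -> equal-weight composition ->
# spatial niches -> colocalization statistics -> join counts -> maturation
# scoring, from one config, with a machine-readable run report.

#' Default pipeline configuration
#'
#' Every parameter has a default; the full config is echoed into the run
#' report. One global seed is split deterministically per stage.
#'
#' @param seed global integer seed.
#' @return nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_specimens_per_class = c(3L, 3L, 3L),
                  cells_per_specimen = 400L, n_genes = 1000L),
    spatial = list(n_sections = 3L, cells_per_section = 1200L,
                   region_layout = "segregated"),
    qc = list(),                       # qc_thresholds() overrides
    signatures = list(top_n = 50L, n_bins = 24L, n_controls = 100L),
    classify = list(theta = 0.65, min_at2_cells = 50L),
    composition = list(focal_type = "AF_c3"),
    niche = list(K = 4L, k = 20L, n_init = 10L),
    distances = list(pairs = list(c("AT2_FMO5", "AF_c1_2"),
                                  c("AT2_FMO5", "AF_c3"),
                                  c("AT2_CFTR", "AF_c1_2"),
                                  c("AT2_CFTR", "AF_c3"))),
    joincount = list(labels = c("AT2_FMO5", "AT2_CFTR"), radii = 10:30,
                     null = "analytic"),
    maturation = list(program_size = 50L, top_n = 50L,
                      types = c("AT2", "AT1", "AF_c1_2")),
    stages = list(spatial = TRUE, maturation = TRUE)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults.
#' @param path YAML file.
#' @param seed default seed when the file does not set one.
#' @return `pipeline_config`.
#' @export
load_pipeline_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = if (!is.null(user$seed))
    user$seed else seed)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_in(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  out <- merge_in(unclass(cfg), user)
  class(out) <- "pipeline_config"
  out
}

log_msg <- function(...) message("[alveoniche] ", ...)

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writes all intermediate
#' artifacts under `out_dir` and returns (and writes) a run report. The
#' report carries no timestamps, so identical config + seed reproduces
#' every output byte-identically.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @return run report (list), invisibly also written as `report.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("alveoniche_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("alveoniche")),
                 config = unclass(config), stages = list(), warnings = list())
  note_warnings <- function(stage, expr) {
    ws <- character(0)
    val <- withCallingHandlers(expr, warning = function(w) {
      ws <<- c(ws, conditionMessage(w)); invokeRestart("muffleWarning")
    })
    if (length(ws)) report$warnings[[stage]] <<- ws
    val
  }
  seed <- config$seed

  # -- simulate ------------------------------------------------------------
  log_msg("simulate: cohort")
  ccfg <- do.call(cohort_config,
                  c(config$cohort, list(seed = derive_seed(seed, "cohort"))))
  cohort <- generate_expression_cohort(ccfg)
  write_counts(cohort, file.path(out_dir, "cohort"))
  utils::write.csv(cohort$truth$cells,
                   file.path(out_dir, "cohort", "ground_truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$genes,
                   file.path(out_dir, "cohort", "ground_truth_genes.csv"),
                   row.names = FALSE)
  report$stages$simulate <- list(n_cells = ncol(cohort$counts),
                                 n_genes = nrow(cohort$counts))

  # -- qc + normalize ------------------------------------------------------
  log_msg("qc")
  thr <- do.call(qc_thresholds, config$qc)
  filtered <- note_warnings("qc", apply_qc_filters(cohort, thr))
  norm <- normalize_counts(filtered)
  report$stages$qc <- list(cells_in = ncol(cohort$counts),
                           cells_out = ncol(filtered$counts))

  # -- AT2-state signatures ------------------------------------------------
  log_msg("signatures")
  truth <- filtered$truth$cells
  at2 <- !is.na(truth$at2_state)
  mr <- rank_markers(norm$values[, at2, drop = FALSE], truth$at2_state[at2],
                     "FMO5", "CFTR")
  fmo5_sig <- note_warnings("signatures",
    build_signature(mr, config$signatures$top_n, "up", name = "FMO5"))
  cftr_sig <- note_warnings("signatures",
    build_signature(mr, config$signatures$top_n, "down", name = "CFTR"))
  write_signatures(list(fmo5_sig, cftr_sig),
                   file.path(out_dir, "signatures.csv"))
  report$stages$signatures <- list(n_markers = nrow(mr),
                                   fmo5_size = length(fmo5_sig$genes),
                                   cftr_size = length(cftr_sig$genes))

  # -- AT2-state assignment + specimen classification ----------------------
  log_msg("classify")
  at2_norm <- structure(list(values = norm$values[, at2, drop = FALSE]),
                        class = "normalized_matrix")
  state <- note_warnings("classify", assign_at2_state(
    at2_norm, fmo5_sig, cftr_sig, mode = "score",
    n_bins = config$signatures$n_bins,
    n_controls = config$signatures$n_controls,
    seed = derive_seed(seed, "state_scores")))
  at2_cells <- data.frame(
    cell_id = colnames(norm$values)[at2],
    specimen = filtered$cell_meta$specimen[at2],
    at2_state = sub("\\+$", "", state), stringsAsFactors = FALSE)
  groups <- classify_specimens_by_at2_state(
    at2_cells, theta = config$classify$theta,
    min_at2_cells = config$classify$min_at2_cells)
  utils::write.csv(groups, file.path(out_dir, "specimen_groups.csv"),
                   row.names = FALSE)
  report$stages$classify <- as.list(table(groups$class))

  # -- equal-weight composition --------------------------------------------
  log_msg("composition")
  cells_tab <- data.frame(specimen = filtered$cell_meta$specimen,
                          type = truth$type, stringsAsFactors = FALSE)
  comp <- note_warnings("composition", weighted_composition(cells_tab, groups))
  utils::write.csv(data.frame(type = names(comp$overall),
                              weighted_proportion = comp$overall),
                   file.path(out_dir, "weighted_composition.csv"),
                   row.names = FALSE)
  ctest <- tryCatch(
    compare_composition(cells_tab, groups, config$composition$focal_type),
    error = function(e) NULL)
  report$stages$composition <- list(
    G = comp$G,
    focal_type = config$composition$focal_type,
    focal_p = if (is.null(ctest)) NA else ctest$p)

  # -- spatial -------------------------------------------------------------
  if (isTRUE(config$stages$spatial)) {
    log_msg("spatial: simulate sections")
    scfg <- do.call(spatial_config, c(
      config$spatial,
      list(cohort = ccfg, seed = derive_seed(seed, "spatial"))))
    sp <- generate_spatial_sections(scfg)
    write_spatial(sp$sections, file.path(out_dir, "spatial"))
    utils::write.csv(sp$truth,
                     file.path(out_dir, "spatial", "ground_truth.csv"),
                     row.names = FALSE)

    log_msg("spatial: niches")
    catalog <- rownames(scfg$region_catalog$composition)
    models <- lapply(sp$sections, function(s) {
      prof <- neighborhood_profiles(s, k = config$niche$k, catalog = catalog)
      fit_niches(prof, K = config$niche$K,
                 seed = derive_seed(seed, "niche", s$section_id),
                 n_init = config$niche$n_init)
    })
    corr <- align_niches_across_sections(models)
    utils::write.csv(corr$correlation,
                     file.path(out_dir, "niche_correlation.csv"))
    utils::write.csv(corr$groups, file.path(out_dir, "niche_groups.csv"),
                     row.names = FALSE)
    report$stages$niche <- list(n_models = length(models),
                                n_groups = corr$n_groups)

    log_msg("spatial: distances")
    dist_tab <- do.call(rbind, unlist(lapply(sp$sections, function(s) {
      lapply(config$distances$pairs, function(pr)
        symmetric_mean_nn_distance(s, pr[1], pr[2]))
    }), recursive = FALSE))
    utils::write.csv(dist_tab, file.path(out_dir, "pair_distances.csv"),
                     row.names = FALSE)
    dtest <- tryCatch(distance_anova_tukey(dist_tab), error = function(e) NULL)
    report$stages$distances <- list(
      anova_p = if (is.null(dtest)) NA else dtest$anova_p)

    log_msg("spatial: join counts")
    at2_maps <- lapply(sp$sections, function(s) {
      keep <- s$cells$label %in% config$joincount$labels
      structure(list(section_id = s$section_id,
                     cells = s$cells[keep, , drop = FALSE],
                     panel_counts = NULL), class = "spatial_map")
    })
    jc <- do.call(rbind, lapply(config$joincount$labels, function(l)
      joincount_profile(at2_maps, l, radii = config$joincount$radii,
                        null = config$joincount$null,
                        seed = derive_seed(seed, "joincount", l))))
    utils::write.csv(jc, file.path(out_dir, "joincount.csv"),
                     row.names = FALSE)
    report$stages$joincount <- list(
      max_Z = stats::setNames(
        vapply(config$joincount$labels, function(l)
          max(jc$Z[jc$label == l], na.rm = TRUE), numeric(1)),
        config$joincount$labels))
  }

  # -- maturation ----------------------------------------------------------
  if (isTRUE(config$stages$maturation)) {
    log_msg("maturation")
    mcfg <- do.call(cohort_config, c(
      config$cohort, list(seed = derive_seed(seed, "maturation"))))
    series <- generate_maturation_series(
      mcfg, program_size = config$maturation$program_size,
      types = config$maturation$types)
    mnorm <- normalize_counts(apply_qc_filters(series,
                                               qc_thresholds(min_features = 1L,
                                                             min_molecules = 0.5)))
    sets <- note_warnings("maturation", build_maturation_sets(
      mnorm$values, series$cell_meta$stage[match(colnames(mnorm$values),
                                                 series$cell_meta$cell_id)],
      series$truth$cells$type[match(colnames(mnorm$values),
                                    series$truth$cells$cell_id)],
      top_n = config$maturation$top_n))
    keep_cells <- colnames(mnorm$values)
    scores <- note_warnings("maturation", score_maturation(
      mnorm$values,
      series$truth$cells$type[match(keep_cells, series$truth$cells$cell_id)],
      sets, seed = derive_seed(seed, "maturation_scores")))
    scores$stage <- series$cell_meta$stage[match(scores$cell_id,
                                                 series$cell_meta$cell_id)]
    utils::write.csv(scores, file.path(out_dir, "maturation_scores.csv"),
                     row.names = FALSE)
    agg <- stats::aggregate(on_score ~ stage, scores, mean)
    report$stages$maturation <- list(
      mean_on_by_stage = stats::setNames(agg$on_score, agg$stage))
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_msg("done: ", out_dir)
  invisible(report)
}

#' Serialize gene signatures as two-column CSV and GMT
#' @param sigs list of `gene_signature`s.
#' @param path CSV path; a sibling `.gmt` is written alongside.
#' @export
write_signatures <- function(sigs, path) {
  df <- do.call(rbind, lapply(sigs, function(s)
    data.frame(signature = s$name, gene = s$genes, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  gmt <- vapply(sigs, function(s)
    paste(c(s$name, "alveoniche", s$genes), collapse = "\t"), character(1))
  writeLines(gmt, sub("\\.csv$", ".gmt", path))
  invisible(path)
}
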