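# Synthetic data: seeded snRNA-seq cohorts, staged developmental series and
# multi-section spatial maps with known ground truth. The generator encodes
# the statistical structure the downstream analyses assume: a fixed lung
# cell-type catalog with two mutually exclusive AT2 transcriptional states
# (lipogenic FMO5+ vs inflammatory CFTR+) whose per-specimen mixture differs
# across three specimen classes, gamma-Poisson counts with lognormal library
# sizes, and tissue sections with bronchiolar / interstitial / two alveolar
# regions whose compositions pair FMO5+ AT2 with AF-c1/2 and CFTR+ AT2 with
# AF-c3.

SPECIMEN_CLASSES <- c("FMO5_enriched", "CFTR_enriched", "mixed")

#' Default cell-type catalog with per-class baseline proportions
#'
#' Rows are cell types, columns the three specimen classes. CFTR-enriched
#' specimens carry twice the AT2-to-AT1 transitional fraction and are rich
#' in AF-c3; FMO5-enriched specimens are rich in AF-c1/2. Each column sums
#' to 1.
#' @return numeric matrix (types x classes).
#' @export
default_cell_type_catalog <- function() {
  m <- rbind(
    AT2           = c(0.20, 0.20, 0.20),
    AT1           = c(0.12, 0.12, 0.12),
    AT2toAT1      = c(0.04, 0.08, 0.04),
    AF_c1_2       = c(0.17, 0.05, 0.12),
    AF_c3         = c(0.03, 0.15, 0.08),
    Myofibroblast = c(0.08, 0.08, 0.08),
    Capillary     = c(0.12, 0.12, 0.12),
    Airway        = c(0.09, 0.05, 0.08),
    Macrophage    = c(0.10, 0.10, 0.10),
    Lymphoid      = c(0.05, 0.05, 0.06)
  )
  colnames(m) <- SPECIMEN_CLASSES
  m
}

#' Configuration for a synthetic snRNA-seq cohort
#'
#' @param n_specimens_per_class named or unnamed length-3 integer vector:
#'   specimens in the FMO5-enriched, CFTR-enriched and mixed classes.
#' @param cells_per_specimen cells drawn per specimen.
#' @param cell_type_catalog types x classes matrix of baseline proportions
#'   (columns sum to 1).
#' @param at2_state_mix list of length-2 Beta shape vectors per class for
#'   the FMO5+ fraction among a specimen's AT2 cells. Defaults place the
#'   classes at roughly 80% / 20% / 50% FMO5+, i.e. the ">75%" vs "~35%"
#'   split seen between Dex-treated and Dex-naive specimens brackets the
#'   enriched and mixed classes.
#' @param n_genes total genes (mito + ribo + marker + state + neutral).
#' @param n_markers_per_type marker genes elevated in each cell type.
#' @param n_state_genes state-specific genes per AT2 state (disjoint sets).
#' @param marker_log_fold natural-log elevation of marker (and state) means.
#' @param libsize_lognormal c(meanlog, sdlog) of the per-cell library size.
#' @param nb_dispersion negative-binomial size parameter (variance =
#'   mu + mu^2/size); `Inf` switches to Poisson mode, realized as
#'   multinomial sampling conditioned on the drawn library size.
#' @param mito_gene_fraction,ribo_gene_fraction expected share of a cell's
#'   counts falling in the mitochondrial / ribosomal gene blocks.
#' @param seed integer seed; all randomness flows from it via derived
#'   per-specimen sub-seeds.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_specimens_per_class = c(3L, 3L, 3L),
                          cells_per_specimen = 400L,
                          cell_type_catalog = default_cell_type_catalog(),
                          at2_state_mix = list(
                            FMO5_enriched = c(24, 6),
                            CFTR_enriched = c(6, 24),
                            mixed = c(15, 15)
                          ),
                          n_genes = 1000L,
                          n_markers_per_type = 20L,
                          n_state_genes = 50L,
                          marker_log_fold = 1.0,
                          libsize_lognormal = c(log(5000), 0.35),
                          nb_dispersion = 2,
                          mito_gene_fraction = 0.02,
                          ribo_gene_fraction = 0.03,
                          seed = 1L) {
  n_specimens_per_class <- as.integer(n_specimens_per_class)
  if (length(n_specimens_per_class) != 3L) {
    stop("n_specimens_per_class must have length 3 (",
         paste(SPECIMEN_CLASSES, collapse = ", "), ")")
  }
  names(n_specimens_per_class) <- SPECIMEN_CLASSES
  if (any(n_specimens_per_class < 0L)) stop("specimen counts must be >= 0")
  if (cells_per_specimen <= 0L) stop("cells_per_specimen must be positive")
  if (!all(abs(colSums(cell_type_catalog) - 1) < 1e-8)) {
    stop("cell_type_catalog columns must each sum to 1")
  }
  for (cl in SPECIMEN_CLASSES) {
    if (!cl %in% names(at2_state_mix)) stop("at2_state_mix missing class ", cl)
    if (any(at2_state_mix[[cl]] <= 0)) stop("Beta shapes must be positive")
  }
  if (marker_log_fold < 0) stop("marker_log_fold must be non-negative")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  cfg <- list(
    n_specimens_per_class = n_specimens_per_class,
    cells_per_specimen = as.integer(cells_per_specimen),
    cell_type_catalog = cell_type_catalog,
    at2_state_mix = at2_state_mix,
    n_genes = as.integer(n_genes),
    n_markers_per_type = as.integer(n_markers_per_type),
    n_state_genes = as.integer(n_state_genes),
    marker_log_fold = marker_log_fold,
    libsize_lognormal = libsize_lognormal,
    nb_dispersion = nb_dispersion,
    mito_gene_fraction = mito_gene_fraction,
    ribo_gene_fraction = ribo_gene_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

N_MITO_GENES <- 10L
N_RIBO_GENES <- 20L

# Deterministic gene universe for a cohort config: names, per-gene baseline
# relative means (lognormal, drawn from a seed-derived stream so they are a
# fixed property of the config), and program membership. Mito/ribo blocks
# are rescaled so their expected expression shares match the config.
build_gene_universe <- function(config, maturation_types = NULL,
                                program_size = 0L) {
  n_types <- nrow(config$cell_type_catalog)
  types <- rownames(config$cell_type_catalog)
  n_marker <- n_types * config$n_markers_per_type
  n_state <- 2L * config$n_state_genes
  n_mat <- if (is.null(maturation_types)) 0L else
    2L * program_size * length(maturation_types)
  n_fixed <- N_MITO_GENES + N_RIBO_GENES + n_marker + n_state + n_mat
  if (n_fixed > config$n_genes) {
    stop("configured gene blocks (", n_fixed,
         ") exceed n_genes (", config$n_genes, ")")
  }
  names <- c(
    paste0("MT-", seq_len(N_MITO_GENES)),
    paste0("RPS", seq_len(N_RIBO_GENES / 2L)),
    paste0("RPL", seq_len(N_RIBO_GENES / 2L)),
    unlist(lapply(types, function(t)
      paste0("MK.", t, ".", seq_len(config$n_markers_per_type)))),
    paste0("FMO5S.", seq_len(config$n_state_genes)),
    paste0("CFTRS.", seq_len(config$n_state_genes))
  )
  program <- c(
    rep("mito", N_MITO_GENES),
    rep("ribo", N_RIBO_GENES),
    unlist(lapply(types, function(t)
      rep(paste0("marker:", t), config$n_markers_per_type))),
    rep("state_FMO5", config$n_state_genes),
    rep("state_CFTR", config$n_state_genes)
  )
  if (n_mat > 0L) {
    for (t in maturation_types) {
      names <- c(names, paste0("ON.", t, ".", seq_len(program_size)),
                 paste0("OFF.", t, ".", seq_len(program_size)))
      program <- c(program, rep(paste0("maturation_on:", t), program_size),
                   rep(paste0("maturation_off:", t), program_size))
    }
  }
  n_neutral <- config$n_genes - length(names)
  names <- c(names, paste0("NEUTRAL.", seq_len(n_neutral)))
  program <- c(program, rep("neutral", n_neutral))

  base <- with_seed(derive_seed(config$seed, "gene_universe"),
                    stats::rlnorm(config$n_genes, 0, 1))
  # rescale mito/ribo blocks to the configured expression shares
  is_mito <- program == "mito"
  is_ribo <- program == "ribo"
  other <- !(is_mito | is_ribo)
  tot_other <- sum(base[other])
  share_other <- 1 - config$mito_gene_fraction - config$ribo_gene_fraction
  base[is_mito] <- base[is_mito] / sum(base[is_mito]) *
    tot_other * config$mito_gene_fraction / share_other
  base[is_ribo] <- base[is_ribo] / sum(base[is_ribo]) *
    tot_other * config$ribo_gene_fraction / share_other
  list(names = names, program = program, base = base)
}

# Expected gene proportion vector for one (type, state) combination.
type_mean_profile <- function(universe, config, type, state = NA) {
  mu <- universe$base
  mu[universe$program == paste0("marker:", type)] <-
    mu[universe$program == paste0("marker:", type)] *
    exp(config$marker_log_fold)
  if (identical(type, "AT2") && !is.na(state)) {
    tag <- paste0("state_", state)
    mu[universe$program == tag] <-
      mu[universe$program == tag] * exp(config$marker_log_fold)
  }
  mu / sum(mu)
}

# Draw a genes x n count matrix for n cells sharing a mean profile p, given
# library sizes L. Poisson mode (nb_dispersion = Inf) conditions on L via
# multinomial sampling; otherwise gamma-Poisson per entry.
draw_counts <- function(p, L, nb_dispersion) {
  n <- length(L)
  if (is.infinite(nb_dispersion)) {
    counts <- vapply(seq_len(n), function(i)
      as.numeric(stats::rmultinom(1L, size = round(L[i]), prob = p)),
      numeric(length(p)))
  } else {
    mu <- outer(p, L)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = nb_dispersion),
      nrow = length(p))
  }
  counts
}

#' Generate a synthetic multi-specimen snRNA-seq cohort
#'
#' Each specimen belongs to one of three classes that differ in baseline
#' cell-type proportions and in the Beta-distributed FMO5+ fraction among
#' AT2 cells. Counts are gamma-Poisson with lognormal library sizes; each
#' cell type's markers (and, for AT2 cells, the matching state's genes) are
#' elevated by `exp(marker_log_fold)` in the mean.
#'
#' @param config a [cohort_config()].
#' @return list with elements `counts` (sparse genes x cells matrix),
#'   `cell_meta` (data.frame: cell_id, specimen, class, stage, n_features,
#'   n_molecules, frac_mito, frac_ribo), and `truth` (list with `cells`:
#'   true type/state per cell, and `genes`: program membership per gene).
#' @export
generate_expression_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  universe <- build_gene_universe(config)
  types <- rownames(config$cell_type_catalog)
  blocks <- list()
  meta <- list()
  spec_idx <- 0L
  for (cl in SPECIMEN_CLASSES) {
    for (s in seq_len(config$n_specimens_per_class[[cl]])) {
      spec_idx <- spec_idx + 1L
      spec_id <- sprintf("SP%02d_%s", spec_idx, cl)
      res <- with_seed(derive_seed(config$seed, "specimen", spec_id), {
        fmo5_frac <- stats::rbeta(1L, config$at2_state_mix[[cl]][1],
                                  config$at2_state_mix[[cl]][2])
        n <- config$cells_per_specimen
        type <- sample(types, n, replace = TRUE,
                       prob = config$cell_type_catalog[, cl])
        state <- rep(NA_character_, n)
        is_at2 <- type == "AT2"
        state[is_at2] <- ifelse(
          stats::runif(sum(is_at2)) < fmo5_frac, "FMO5", "CFTR")
        L <- stats::rlnorm(n, config$libsize_lognormal[1],
                           config$libsize_lognormal[2])
        counts <- matrix(0, config$n_genes, n)
        for (key in unique(paste(type, state, sep = "|"))) {
          sel <- paste(type, state, sep = "|") == key
          parts <- strsplit(key, "|", fixed = TRUE)[[1]]
          st <- if (length(parts) >= 2L && parts[2] != "NA") parts[2] else NA
          p <- type_mean_profile(universe, config, parts[1], st)
          counts[, sel] <- draw_counts(p, L[sel], config$nb_dispersion)
        }
        list(counts = counts, type = type, state = state,
             fmo5_frac = fmo5_frac, L = L)
      })
      blocks[[spec_id]] <- res$counts
      meta[[spec_id]] <- data.frame(
        specimen = spec_id, class = cl, type = res$type,
        at2_state = res$state, true_fmo5_frac = res$fmo5_frac,
        library_size = res$L, stringsAsFactors = FALSE)
    }
  }
  if (spec_idx == 0L) stop("zero specimens requested")
  counts <- do.call(cbind, blocks)
  cm <- do.call(rbind, meta)
  cm$cell_id <- sprintf("%s_C%04d", cm$specimen,
                        unlist(lapply(meta, function(m) seq_len(nrow(m)))))
  rownames(cm) <- cm$cell_id
  dimnames(counts) <- list(universe$names, cm$cell_id)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  cell_meta <- data.frame(
    cell_id = cm$cell_id, specimen = cm$specimen, class = cm$class,
    stage = NA_character_, row.names = cm$cell_id, stringsAsFactors = FALSE)
  cell_meta <- add_qc_metrics(cell_meta, counts,
                              mito_genes = universe$names[universe$program == "mito"],
                              ribo_genes = universe$names[universe$program == "ribo"])
  truth <- list(
    cells = data.frame(cell_id = cm$cell_id, specimen = cm$specimen,
                       class = cm$class, type = cm$type,
                       at2_state = cm$at2_state,
                       true_fmo5_frac = cm$true_fmo5_frac,
                       library_size = cm$library_size,
                       row.names = cm$cell_id, stringsAsFactors = FALSE),
    genes = data.frame(gene = universe$names, program = universe$program,
                       stringsAsFactors = FALSE)
  )
  structure(list(counts = counts, cell_meta = cell_meta, truth = truth,
                 config = config),
            class = "cohort_counts")
}

# per-cell QC metrics from counts
add_qc_metrics <- function(cell_meta, counts, mito_genes, ribo_genes) {
  tot <- Matrix::colSums(counts)
  cell_meta$n_features <- Matrix::colSums(counts > 0)
  cell_meta$n_molecules <- tot
  cell_meta$frac_mito <-
    Matrix::colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE]) /
    pmax(tot, 1)
  cell_meta$frac_ribo <-
    Matrix::colSums(counts[rownames(counts) %in% ribo_genes, , drop = FALSE]) /
    pmax(tot, 1)
  cell_meta
}

#' Generate a staged fetal-to-postnatal maturation series
#'
#' For each requested cell type, `program_size` "on" genes rise and
#' `program_size` "off" genes fall monotonically (linear ramp on the log
#' scale) across the ordered stages. Specimens named in `arrest_specimens`
#' have their programs frozen at the second stage regardless of their
#' recorded stage, emulating the developmental arrest seen in neonatal
#' lung disease.
#'
#' @param config a [cohort_config()]; its catalog, library-size and noise
#'   settings are reused. Stage structure replaces the class structure.
#' @param stages ordered character vector of stage names (>= 2); the first
#'   is the fetal reference.
#' @param program_size on/off genes per cell type.
#' @param types cell types given maturation programs (default: AT2, AT1,
#'   AF_c1_2).
#' @param n_specimens_per_stage specimens per stage.
#' @param ramp_log_amplitude total natural-log rise of an "on" gene from
#'   first to last stage (0 = no signal).
#' @param arrest_specimens character vector of specimen IDs (format
#'   `SP<stage index>_<s>`) frozen at stage 2; or an integer: that many
#'   specimens of the final stage are arrested.
#' @return list like [generate_expression_cohort()]; `cell_meta$stage`
#'   records the stage and `truth$cells$arrested` the arrest flag.
#' @export
generate_maturation_series <- function(config,
                                       stages = c("fetal", "birth",
                                                  "6mo_minus", "6mo_plus"),
                                       program_size = 100L,
                                       types = c("AT2", "AT1", "AF_c1_2"),
                                       n_specimens_per_stage = 2L,
                                       ramp_log_amplitude = 1.0,
                                       arrest_specimens = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(stages) < 2L) stop("need at least 2 stages")
  if (!all(types %in% rownames(config$cell_type_catalog))) {
    stop("types must be in the cell-type catalog")
  }
  universe <- build_gene_universe(config, maturation_types = types,
                                  program_size = as.integer(program_size))
  S <- length(stages)
  if (is.numeric(arrest_specimens) && length(arrest_specimens) == 1L) {
    arrest_specimens <- sprintf("SP%d_%d", S, seq_len(arrest_specimens))
  }
  all_types <- rownames(config$cell_type_catalog)
  blocks <- list(); meta <- list()
  for (si in seq_len(S)) {
    for (sp in seq_len(n_specimens_per_stage)) {
      spec_id <- sprintf("SP%d_%d", si, sp)
      arrested <- spec_id %in% arrest_specimens
      # arrested specimens express the stage-2 program
      eff <- if (arrested) min(2L, S) else si
      frac <- (eff - 1) / (S - 1)
      res <- with_seed(derive_seed(config$seed, "maturation", spec_id), {
        n <- config$cells_per_specimen
        type <- sample(all_types, n, replace = TRUE,
                       prob = config$cell_type_catalog[, "mixed"])
        state <- rep(NA_character_, n)
        is_at2 <- type == "AT2"
        state[is_at2] <- ifelse(stats::runif(sum(is_at2)) < 0.5,
                                "FMO5", "CFTR")
        L <- stats::rlnorm(n, config$libsize_lognormal[1],
                           config$libsize_lognormal[2])
        counts <- matrix(0, config$n_genes, n)
        for (key in unique(paste(type, state, sep = "|"))) {
          sel <- paste(type, state, sep = "|") == key
          parts <- strsplit(key, "|", fixed = TRUE)[[1]]
          st <- if (length(parts) >= 2L && parts[2] != "NA") parts[2] else NA
          mu <- universe$base
          mu[universe$program == paste0("marker:", parts[1])] <-
            mu[universe$program == paste0("marker:", parts[1])] *
            exp(config$marker_log_fold)
          if (identical(parts[1], "AT2") && !is.na(st)) {
            tag <- paste0("state_", st)
            mu[universe$program == tag] <- mu[universe$program == tag] *
              exp(config$marker_log_fold)
          }
          if (parts[1] %in% types) {
            on <- universe$program == paste0("maturation_on:", parts[1])
            off <- universe$program == paste0("maturation_off:", parts[1])
            mu[on] <- mu[on] * exp(ramp_log_amplitude * frac)
            mu[off] <- mu[off] * exp(ramp_log_amplitude * (1 - frac))
          }
          p <- mu / sum(mu)
          counts[, sel] <- draw_counts(p, L[sel], config$nb_dispersion)
        }
        list(counts = counts, type = type, state = state)
      })
      blocks[[spec_id]] <- res$counts
      meta[[spec_id]] <- data.frame(
        specimen = spec_id, stage = stages[si], stage_index = si,
        arrested = arrested, type = res$type, at2_state = res$state,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  cm <- do.call(rbind, meta)
  cm$cell_id <- sprintf("%s_C%04d", cm$specimen,
                        unlist(lapply(meta, function(m) seq_len(nrow(m)))))
  rownames(cm) <- cm$cell_id
  dimnames(counts) <- list(universe$names, cm$cell_id)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  cell_meta <- data.frame(
    cell_id = cm$cell_id, specimen = cm$specimen, class = NA_character_,
    stage = cm$stage, row.names = cm$cell_id, stringsAsFactors = FALSE)
  cell_meta <- add_qc_metrics(cell_meta, counts,
                              universe$names[universe$program == "mito"],
                              universe$names[universe$program == "ribo"])
  truth <- list(
    cells = data.frame(cell_id = cm$cell_id, specimen = cm$specimen,
                       stage = cm$stage, stage_index = cm$stage_index,
                       arrested = cm$arrested, type = cm$type,
                       at2_state = cm$at2_state, row.names = cm$cell_id,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene = universe$names, program = universe$program,
                       stringsAsFactors = FALSE)
  )
  structure(list(counts = counts, cell_meta = cell_meta, truth = truth,
                 config = config, stages = stages),
            class = "cohort_counts")
}

#' Default spatial region catalog
#'
#' Compositions over spatial labels (AT2 split into its two states) for the
#' four tissue regions: alveolar niche 1 pairs FMO5+ AT2 with AF-c1/2,
#' alveolar niche 2 pairs CFTR+ AT2 with AF-c3; bronchiolar regions are
#' airway-rich, interstitial regions mesenchyme/immune-rich.
#' @return list with `composition` (labels x regions matrix, columns sum to
#'   1) and `area_share` (named region area fractions).
#' @export
default_region_catalog <- function() {
  labels <- c("AT2_FMO5", "AT2_CFTR", "AT1", "AT2toAT1", "AF_c1_2", "AF_c3",
              "Myofibroblast", "Capillary", "Airway", "Macrophage",
              "Lymphoid")
  comp <- cbind(
    bronchiolar  = c(0.01, 0.01, 0.05, 0.01, 0.02, 0.02, 0.05, 0.05, 0.63,
                     0.10, 0.05),
    interstitial = c(0.01, 0.01, 0.03, 0.02, 0.07, 0.07, 0.28, 0.18, 0.03,
                     0.20, 0.10),
    alveolar_1   = c(0.24, 0.02, 0.18, 0.04, 0.24, 0.02, 0.02, 0.13, 0.01,
                     0.08, 0.02),
    alveolar_2   = c(0.02, 0.24, 0.18, 0.08, 0.02, 0.24, 0.02, 0.10, 0.01,
                     0.07, 0.02)
  )
  rownames(comp) <- labels
  stopifnot(all(abs(colSums(comp) - 1) < 1e-8))
  list(composition = comp,
       area_share = c(bronchiolar = 0.15, interstitial = 0.25,
                      alveolar_1 = 0.30, alveolar_2 = 0.30))
}

#' Configuration for synthetic tissue sections
#'
#' @param n_sections number of sections.
#' @param cells_per_section cells per section.
#' @param region_layout "segregated" (contiguous blobs via seeded Voronoi
#'   anchors) or "salt_and_pepper" (independent region draws on a patch
#'   grid) — the two spatial arrangements seen for the alveolar niches.
#' @param region_catalog as [default_region_catalog()].
#' @param min_spacing_um hard-core minimum distance between cell centroids.
#' @param section_extent_um c(width, height) in micrometres.
#' @param panel_genes targeted panel; default NULL picks all marker and
#'   AT2-state genes of the cohort universe.
#' @param panel_depth_lognormal c(meanlog, sdlog) of per-cell panel counts
#'   (Xenium-typical median ~100 counts/cell).
#' @param n_anchors Voronoi anchors per section (segregated layout).
#' @param patch_um patch edge length (salt-and-pepper layout).
#' @param cohort a [cohort_config()] supplying the gene universe and
#'   expression means for panel-count sampling.
#' @param seed integer seed.
#' @return object of class `spatial_config`.
#' @export
spatial_config <- function(n_sections = 5L,
                           cells_per_section = 3000L,
                           region_layout = c("segregated", "salt_and_pepper"),
                           region_catalog = default_region_catalog(),
                           min_spacing_um = 8,
                           section_extent_um = c(1000, 1000),
                           panel_genes = NULL,
                           panel_depth_lognormal = c(log(100), 0.4),
                           n_anchors = 12L,
                           patch_um = 150,
                           cohort = cohort_config(),
                           seed = 1L) {
  region_layout <- match.arg(region_layout)
  if (min_spacing_um <= 0) stop("min_spacing_um must be positive")
  comp <- region_catalog$composition
  if (!all(abs(colSums(comp) - 1) < 1e-8)) {
    stop("region composition columns must sum to 1")
  }
  structure(list(
    n_sections = as.integer(n_sections),
    cells_per_section = as.integer(cells_per_section),
    region_layout = region_layout,
    region_catalog = region_catalog,
    min_spacing_um = min_spacing_um,
    section_extent_um = section_extent_um,
    panel_genes = panel_genes,
    panel_depth_lognormal = panel_depth_lognormal,
    n_anchors = as.integer(n_anchors),
    patch_um = patch_um,
    cohort = cohort,
    seed = as.integer(seed)
  ), class = "spatial_config")
}

# Hard-core point sampling by dart throwing with a grid occupancy index.
sample_hardcore <- function(n, extent, min_spacing, max_attempts = 50L * n) {
  cell <- min_spacing / sqrt(2)
  nx <- max(1L, ceiling(extent[1] / cell))
  ny <- max(1L, ceiling(extent[2] / cell))
  grid <- matrix(NA_integer_, nx, ny)
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L; attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- stats::runif(1L, 0, extent[1]); y <- stats::runif(1L, 0, extent[2])
    gx <- min(nx, 1L + floor(x / cell)); gy <- min(ny, 1L + floor(y / cell))
    ok <- TRUE
    for (ix in max(1L, gx - 2L):min(nx, gx + 2L)) {
      for (iy in max(1L, gy - 2L):min(ny, gy + 2L)) {
        j <- grid[ix, iy]
        if (!is.na(j) &&
            (x - pts[j, 1])^2 + (y - pts[j, 2])^2 < min_spacing^2) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- c(x, y)
      grid[gx, gy] <- placed
    }
  }
  if (placed < n) {
    stop("could not place ", n, " points with min spacing ", min_spacing,
         " um after ", max_attempts, " attempts")
  }
  pts
}

#' Generate synthetic multi-section spatial maps
#'
#' Cell centroids are laid out with a hard-core minimum spacing; regions
#' are contiguous Voronoi blobs (segregated) or independent patch draws
#' (salt-and-pepper); each cell's label is drawn from its region's
#' composition, and targeted-panel counts are sampled from the cohort gene
#' model restricted to the panel.
#'
#' @param config a [spatial_config()].
#' @param cohort optional [cohort_config()] overriding `config$cohort`.
#' @return list with `sections` (list of `spatial_map`: data.frame `cells`
#'   with cell_id, section_id, x_um, y_um, label, region plus sparse
#'   `panel_counts`), and `truth` (per-cell region/label table).
#' @export
generate_spatial_sections <- function(config, cohort = config$cohort) {
  stopifnot(inherits(config, "spatial_config"))
  universe <- build_gene_universe(cohort)
  panel <- config$panel_genes
  if (is.null(panel)) {
    panel <- universe$names[grepl("^(MK\\.|FMO5S\\.|CFTRS\\.)",
                                  universe$names)]
  }
  if (!all(panel %in% universe$names)) {
    stop("panel_genes must be a subset of the cohort gene universe")
  }
  pidx <- match(panel, universe$names)
  comp <- config$region_catalog$composition
  regions <- colnames(comp)
  share <- config$region_catalog$area_share[regions]
  # spatial label -> (cohort type, AT2 state) for expression sampling
  label_to_type <- function(lab) {
    if (lab == "AT2_FMO5") c("AT2", "FMO5")
    else if (lab == "AT2_CFTR") c("AT2", "CFTR")
    else c(lab, NA)
  }
  sections <- list(); truth <- list()
  for (s in seq_len(config$n_sections)) {
    sec_id <- sprintf("S%02d", s)
    res <- with_seed(derive_seed(config$seed, "section", s), {
      ext <- config$section_extent_um
      xy <- sample_hardcore(config$cells_per_section, ext,
                            config$min_spacing_um)
      if (config$region_layout == "segregated") {
        anchors <- cbind(stats::runif(config$n_anchors, 0, ext[1]),
                         stats::runif(config$n_anchors, 0, ext[2]))
        # proportional (largest-remainder) anchor allocation so every
        # section contains all regions at roughly their area shares
        quota <- share / sum(share) * config$n_anchors
        n_each <- floor(quota)
        rem <- config$n_anchors - sum(n_each)
        if (rem > 0) {
          extra <- order(quota - n_each, decreasing = TRUE)[seq_len(rem)]
          n_each[extra] <- n_each[extra] + 1L
        }
        anchor_region <- sample(rep(regions, n_each))
        d2 <- outer(rowSums(xy^2), rowSums(anchors^2), "+") -
          2 * tcrossprod(xy, anchors)
        region <- anchor_region[max.col(-d2)]
      } else {
        nxp <- max(1L, ceiling(ext[1] / config$patch_um))
        nyp <- max(1L, ceiling(ext[2] / config$patch_um))
        patch_region <- matrix(sample(regions, nxp * nyp, replace = TRUE,
                                      prob = share), nxp, nyp)
        px <- pmin(nxp, 1L + floor(xy[, 1] / config$patch_um))
        py <- pmin(nyp, 1L + floor(xy[, 2] / config$patch_um))
        region <- patch_region[cbind(px, py)]
      }
      label <- character(nrow(xy))
      for (r in unique(region)) {
        sel <- region == r
        label[sel] <- sample(rownames(comp), sum(sel), replace = TRUE,
                             prob = comp[, r])
      }
      depth <- stats::rlnorm(nrow(xy), config$panel_depth_lognormal[1],
                             config$panel_depth_lognormal[2])
      counts <- matrix(0, length(panel), nrow(xy))
      for (lab in unique(label)) {
        sel <- label == lab
        ts <- label_to_type(lab)
        p_full <- type_mean_profile(universe, cohort, ts[1],
                                    if (is.na(ts[2])) NA else ts[2])
        p <- p_full[pidx]; p <- p / sum(p)
        counts[, sel] <- vapply(which(sel), function(i)
          as.numeric(stats::rmultinom(1L, size = round(depth[i]), prob = p)),
          numeric(length(panel)))
      }
      list(xy = xy, region = region, label = label, counts = counts)
    })
    cells <- data.frame(
      cell_id = sprintf("%s_C%05d", sec_id, seq_len(nrow(res$xy))),
      section_id = sec_id, x_um = res$xy[, 1], y_um = res$xy[, 2],
      label = res$label, region = res$region, stringsAsFactors = FALSE)
    pc <- methods::as(Matrix::Matrix(res$counts, sparse = TRUE,
                                     dimnames = list(panel, cells$cell_id)),
                      "CsparseMatrix")
    sections[[sec_id]] <- structure(
      list(section_id = sec_id, cells = cells, panel_counts = pc),
      class = "spatial_map")
    truth[[sec_id]] <- cells[, c("cell_id", "section_id", "label", "region")]
  }
  list(sections = sections, truth = do.call(rbind, truth), config = config)
}

#' Simulate a labelled point field for join-count calibration and power
#'
#' Under `clustered = FALSE` labels are complete-spatial-randomness: a fixed
#' number of positives assigned uniformly at random. Under `clustered =
#' TRUE` the positives are planted in compact clusters of radius
#' `cluster_radius_um`.
#'
#' @param n total points; `prop_positive` fraction carrying the label.
#' @param extent c(width, height) in um.
#' @param clustered plant positive-label clusters?
#' @param cluster_radius_um cluster scale (default 20 um).
#' @param n_clusters number of planted clusters.
#' @param seed integer seed.
#' @return `spatial_map` with labels "POS"/"NEG".
#' @export
simulate_label_field <- function(n = 400L, extent = c(500, 500),
                                 prop_positive = 0.3, clustered = FALSE,
                                 cluster_radius_um = 20, n_clusters = 5L,
                                 seed = 1L) {
  with_seed(seed, {
    n1 <- round(n * prop_positive)
    if (clustered) {
      centers <- cbind(stats::runif(n_clusters, cluster_radius_um,
                                    extent[1] - cluster_radius_um),
                       stats::runif(n_clusters, cluster_radius_um,
                                    extent[2] - cluster_radius_um))
      ci <- sample.int(n_clusters, n1, replace = TRUE)
      ang <- stats::runif(n1, 0, 2 * pi)
      rad <- cluster_radius_um * sqrt(stats::runif(n1))
      pos <- centers[ci, , drop = FALSE] +
        cbind(rad * cos(ang), rad * sin(ang))
      neg <- cbind(stats::runif(n - n1, 0, extent[1]),
                   stats::runif(n - n1, 0, extent[2]))
      xy <- rbind(pos, neg)
      label <- c(rep("POS", n1), rep("NEG", n - n1))
    } else {
      xy <- cbind(stats::runif(n, 0, extent[1]),
                  stats::runif(n, 0, extent[2]))
      label <- rep("NEG", n)
      label[sample.int(n, n1)] <- "POS"
    }
    cells <- data.frame(
      cell_id = sprintf("F_C%05d", seq_len(n)), section_id = "F01",
      x_um = xy[, 1], y_um = xy[, 2], label = label,
      stringsAsFactors = FALSE)
    structure(list(section_id = "F01", cells = cells, panel_counts = NULL),
              class = "spatial_map")
  })
}
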