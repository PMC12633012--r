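# QC filtering, log-normalization, specimen stratification by AT2-state
# abundance, equal-weight compositional analysis, specimen-level composition
# tests and the RT-qPCR normalization utility.

#' QC thresholds for nuclei and spatial segmentations
#'
#' Boundary semantics follow the printed filtering rules literally:
#' "between 500 to 7500 features" is inclusive, "more than 1000 unique
#' molecules" is strict, "less than 5% mitochondrial / 7.5% ribosomal" are
#' strict, and spatial segmentations with "less than 25" panel counts are
#' excluded (25 retained).
#'
#' @param min_features,max_features inclusive bounds on detected genes.
#' @param min_molecules exclusive lower bound on total counts.
#' @param max_frac_mito,max_frac_ribo exclusive upper bounds on QC
#'   fractions.
#' @param spatial_min_counts inclusive lower bound on panel counts per
#'   spatial segmentation.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 500L, max_features = 7500L,
                          min_molecules = 1000L, max_frac_mito = 0.05,
                          max_frac_ribo = 0.075, spatial_min_counts = 25L) {
  if (min_features >= max_features) stop("min_features must be < max_features")
  if (min_molecules <= 0 || min_features <= 0) stop("bounds must be positive")
  structure(list(min_features = min_features, max_features = max_features,
                 min_molecules = min_molecules, max_frac_mito = max_frac_mito,
                 max_frac_ribo = max_frac_ribo,
                 spatial_min_counts = spatial_min_counts),
            class = "qc_thresholds")
}

#' Apply per-cell QC filters to a count matrix
#'
#' Retains exactly the cells with `min_features <= n_features <=
#' max_features`, `n_molecules > min_molecules`, `frac_mito <
#' max_frac_mito` and `frac_ribo < max_frac_ribo`. Genes and cell order are
#' preserved; the filter is idempotent.
#'
#' @param m a `cohort_counts` object (or list with `counts` and
#'   `cell_meta`). Missing QC columns are computed from the counts, which
#'   requires `mito_genes`/`ribo_genes`.
#' @param thresholds a [qc_thresholds()].
#' @param mito_genes,ribo_genes gene-ID vectors used only when QC fractions
#'   must be computed; default: symbols prefixed MT- / RPS,RPL.
#' @return the filtered object, same class and gene set.
#' @export
apply_qc_filters <- function(m, thresholds = qc_thresholds(),
                             mito_genes = NULL, ribo_genes = NULL) {
  meta <- m$cell_meta
  need <- c("n_features", "n_molecules", "frac_mito", "frac_ribo")
  if (!all(need %in% colnames(meta))) {
    genes <- rownames(m$counts)
    if (is.null(mito_genes)) mito_genes <- genes[grepl("^MT-", genes)]
    if (is.null(ribo_genes)) ribo_genes <- genes[grepl("^RP[SL]", genes)]
    if (!length(mito_genes) && !length(ribo_genes)) {
      stop("QC fractions absent and no mito/ribo gene annotation available")
    }
    meta <- add_qc_metrics(meta, m$counts, mito_genes, ribo_genes)
  }
  keep <- meta$n_features >= thresholds$min_features &
    meta$n_features <= thresholds$max_features &
    meta$n_molecules > thresholds$min_molecules &
    meta$frac_mito < thresholds$max_frac_mito &
    meta$frac_ribo < thresholds$max_frac_ribo
  if (!any(keep)) warning("QC filter removed every cell")
  m$counts <- m$counts[, keep, drop = FALSE]
  m$cell_meta <- meta[keep, , drop = FALSE]
  if (!is.null(m$truth) && !is.null(m$truth$cells)) {
    m$truth$cells <- m$truth$cells[keep, , drop = FALSE]
  }
  m
}

#' Log-normalize a count matrix
#'
#' `value(g, c) = ln(1 + count(g, c) * scale / total(c))`, the standard
#' log counts-per-`scale` transform (default counts per 10,000).
#'
#' @param m `cohort_counts` object or a bare genes x cells matrix.
#' @param scale positive scale factor (default 1e4).
#' @return list of class `normalized_matrix` with `values` (sparse matrix),
#'   `scale_factor` and the input `cell_meta` when present.
#' @export
normalize_counts <- function(m, scale = 1e4) {
  counts <- if (is.list(m)) m$counts else m
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("cells with zero total counts must be filtered first")
  values <- counts %*% Matrix::Diagonal(x = scale / tot)
  values@x <- log1p(values@x)
  dimnames(values) <- dimnames(counts)
  structure(list(values = values, scale_factor = scale,
                 cell_meta = if (is.list(m)) m$cell_meta else NULL),
            class = "normalized_matrix")
}

#' Classify specimens by AT2-state abundance
#'
#' Among each specimen's assigned AT2 cells, let `p` be the FMO5+ fraction
#' of FMO5+ plus CFTR+ cells. The specimen is FMO5-enriched if `p >= theta`,
#' CFTR-enriched if `p <= 1 - theta`, mixed otherwise, and unclassified if
#' it has fewer than `min_at2_cells` assigned AT2 cells (mirroring the one
#' specimen dropped for low AT2 representation).
#'
#' @param cells data.frame with columns `specimen` and `at2_state`
#'   (values "FMO5", "CFTR", "Unassigned" or NA; only AT2 rows should carry
#'   a state).
#' @param theta enrichment threshold (default 0.65).
#' @param min_at2_cells minimum assigned AT2 cells (default 50).
#' @return data.frame (specimen, n_fmo5, n_cftr, p_fmo5, class) of class
#'   `specimen_groups`, with `theta`/`min_at2_cells` stored as attributes.
#' @export
classify_specimens_by_at2_state <- function(cells, theta = 0.65,
                                            min_at2_cells = 50L) {
  st <- cells$at2_state
  st[is.na(st)] <- "none"
  specs <- sort(unique(cells$specimen))
  out <- do.call(rbind, lapply(specs, function(sp) {
    sel <- cells$specimen == sp
    n_f <- sum(st[sel] == "FMO5"); n_c <- sum(st[sel] == "CFTR")
    n_assigned <- n_f + n_c
    p <- if (n_assigned > 0) n_f / n_assigned else NA_real_
    cl <- if (n_assigned < min_at2_cells) "unclassified"
      else if (p >= theta) "FMO5_enriched"
      else if (p <= 1 - theta) "CFTR_enriched"
      else "mixed"
    data.frame(specimen = sp, n_fmo5 = n_f, n_cftr = n_c, p_fmo5 = p,
               class = cl, stringsAsFactors = FALSE)
  }))
  attr(out, "theta") <- theta
  attr(out, "min_at2_cells") <- min_at2_cells
  class(out) <- c("specimen_groups", "data.frame")
  out
}

#' Equal-weight composition analysis across specimen classes
#'
#' Cells are weighted so each specimen class contributes equally to the
#' overall dataset: a cell in class `g` gets weight `1 / (G * N_g)` where
#' `N_g` is the class's cell count in the compartment and `G` the number of
#' classes with cells. Reports (a) weighted full-data type proportions,
#' (b) per-class type proportions and (c) per-type class shares (the
#' fraction of a type's total weight contributed by each class).
#'
#' @param cells data.frame with columns `specimen` and `type`.
#' @param groups a `specimen_groups` table (or data.frame specimen/class);
#'   unclassified specimens are excluded.
#' @param compartment optional character vector restricting the analysed
#'   types.
#' @return list of class `weighted_composition`: `weights` (per cell),
#'   `overall`, `per_class`, `class_shares`, `G`, `class_sizes`.
#' @export
weighted_composition <- function(cells, groups, compartment = NULL) {
  cls <- groups$class[match(cells$specimen, groups$specimen)]
  keep <- !is.na(cls) & cls != "unclassified"
  cells <- cells[keep, , drop = FALSE]; cls <- cls[keep]
  if (!is.null(compartment)) {
    keep <- cells$type %in% compartment
    cells <- cells[keep, , drop = FALSE]; cls <- cls[keep]
  }
  if (!nrow(cells)) stop("no cells left after class/compartment filtering")
  sizes <- table(cls)
  if (any(sizes == 0)) sizes <- sizes[sizes > 0]
  if (length(sizes) < length(unique(groups$class[groups$class != "unclassified"]))) {
    warning("dropping classes with zero compartment cells")
  }
  G <- length(sizes)
  w <- 1 / (G * as.numeric(sizes[cls]))
  types <- sort(unique(cells$type))
  overall <- vapply(types, function(t) sum(w[cells$type == t]), numeric(1))
  per_class <- sapply(names(sizes), function(g) {
    sel <- cls == g
    vapply(types, function(t) mean(cells$type[sel] == t), numeric(1))
  })
  class_shares <- sapply(names(sizes), function(g) {
    vapply(types, function(t) {
      tot <- sum(w[cells$type == t])
      if (tot == 0) return(NA_real_)
      sum(w[cells$type == t & cls == g]) / tot
    }, numeric(1))
  })
  structure(list(weights = w, overall = overall,
                 per_class = as.matrix(per_class),
                 class_shares = as.matrix(class_shares),
                 G = G, class_sizes = as.numeric(sizes),
                 classes = names(sizes)),
            class = "weighted_composition")
}

#' Compare a cell type's abundance between two specimen groups
#'
#' Two-sided Wilcoxon rank-sum test on per-specimen proportions of
#' `cell_type`, treating each specimen as a replicate. Exact p-value for
#' combined n <= 20 without ties; normal approximation with continuity
#' correction otherwise.
#'
#' @param cells data.frame with columns `specimen` and `type`.
#' @param groups `specimen_groups` table.
#' @param cell_type type whose per-specimen proportion is compared.
#' @param classes length-2 vector of compared specimen classes.
#' @return list (statistic W, p, proportions per group, method).
#' @export
compare_composition <- function(cells, groups, cell_type,
                                classes = c("FMO5_enriched",
                                            "CFTR_enriched")) {
  stopifnot(length(classes) == 2L)
  prop_of <- function(cl) {
    specs <- groups$specimen[groups$class == cl]
    if (length(specs) < 2L) {
      stop("class ", cl, " has fewer than 2 specimens")
    }
    vapply(specs, function(sp) {
      sel <- cells$specimen == sp
      if (!any(sel)) return(NA_real_)
      mean(cells$type[sel] == cell_type)
    }, numeric(1))
  }
  a <- prop_of(classes[1]); b <- prop_of(classes[2])
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n <- length(a) + length(b)
  exact <- n <= 20L && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       proportions = stats::setNames(list(a, b), classes),
       method = if (exact) "exact" else "normal approximation")
}

#' RT-qPCR relative abundance in arbitrary units
#'
#' `2^(Ct_18S - Ct_target) * 10,000`: target abundance normalized to the
#' 18S ribosomal RNA reference.
#'
#' @param ct_target,ct_18s cycle-threshold values (vectorized).
#' @return numeric arbitrary units.
#' @export
qpcr_relative_abundance <- function(ct_target, ct_18s) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_18s)))
  2^(ct_18s - ct_target) * 10000
}
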