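# Marker detection (Wilcoxon rank-sum with percent-expressed and
# fold-change filters), gene-signature construction, binned-control module
# scoring, AT2-state assignment, maturation on/off benchmarking and a
# nearest-centroid label-assignment stand-in for anchor-based transfer.

#' Vectorized two-sided Wilcoxon rank-sum test over matrix rows
#'
#' Normal approximation with tie correction and continuity correction,
#' applied independently to every row (gene).
#' @noRd
rank_sum_rows <- function(x, in_group) {
  x <- as.matrix(x)
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  p <- apply(x, 1L, function(v) {
    r <- rank(v)
    W <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- W - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
  p
}

#' Rank marker genes between two cell groups
#'
#' Tests only genes expressed in at least `min_pct` of either group, with
#' |logFC| above `min_logfc`, and not matching the exclusion patterns
#' (mitochondrial and ribosomal symbols by default). logFC is base-2 on
#' de-logged group means with a small pseudocount; p-values come from a
#' two-sided Wilcoxon rank-sum test on the normalized values, Bonferroni
#' adjusted over the full gene universe of `x`.
#'
#' @param x `normalized_matrix` (or genes x cells matrix of log-normalized
#'   values).
#' @param labels per-cell label vector.
#' @param group1,group2 label values defining the two groups.
#' @param min_pct minimum detection fraction (default 0.25).
#' @param min_logfc minimum |log2 fold change| (default 0.25).
#' @param exclude_patterns regexes removed from the tested universe.
#' @param p_adjust "bonferroni" (default) or "BH".
#' @return data.frame of class `marker_result`: gene, log2fc, pct_in,
#'   pct_out, p, p_adjusted, ordered by decreasing log2fc.
#' @export
rank_markers <- function(x, labels, group1, group2, min_pct = 0.25,
                         min_logfc = 0.25,
                         exclude_patterns = c("^MT-", "^RPS", "^RPL"),
                         p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  vals <- if (inherits(x, "normalized_matrix")) x$values else x
  if (length(intersect(group1, group2))) stop("groups overlap")
  i1 <- labels %in% group1; i2 <- labels %in% group2
  if (!any(i1) || !any(i2)) stop("both groups must be non-empty")
  sub <- as.matrix(vals[, i1 | i2, drop = FALSE])
  in_g <- i1[i1 | i2]
  pct_in <- rowMeans(sub[, in_g, drop = FALSE] > 0)
  pct_out <- rowMeans(sub[, !in_g, drop = FALSE] > 0)
  eps <- 1e-9
  m1 <- rowMeans(expm1(sub[, in_g, drop = FALSE]))
  m2 <- rowMeans(expm1(sub[, !in_g, drop = FALSE]))
  log2fc <- log2((m1 + eps) / (m2 + eps))
  genes <- rownames(vals)
  excluded <- rep(FALSE, length(genes))
  for (pat in exclude_patterns) excluded <- excluded | grepl(pat, genes)
  test <- !excluded & (pct_in >= min_pct | pct_out >= min_pct) &
    abs(log2fc) > min_logfc
  if (!any(test)) {
    res <- data.frame(gene = character(), log2fc = numeric(),
                      pct_in = numeric(), pct_out = numeric(),
                      p = numeric(), p_adjusted = numeric())
    class(res) <- c("marker_result", "data.frame")
    return(res)
  }
  p <- rank_sum_rows(sub[test, , drop = FALSE], in_g)
  n_universe <- nrow(vals)
  p_adj <- if (p_adjust == "bonferroni") pmin(1, p * n_universe)
    else stats::p.adjust(p, "BH")
  res <- data.frame(gene = genes[test], log2fc = log2fc[test],
                    pct_in = pct_in[test], pct_out = pct_out[test],
                    p = p, p_adjusted = p_adj, stringsAsFactors = FALSE)
  res <- res[order(-res$log2fc), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("marker_result", "data.frame")
  res
}

#' Build an ordered gene signature from a marker table
#'
#' Takes the `top_n` genes by |logFC| in the requested direction; ties are
#' broken by smaller p-value, then lexicographic gene ID.
#'
#' @param mr a `marker_result`.
#' @param top_n signature size (50 for AT2-state sets, 100 for maturation
#'   sets by convention).
#' @param direction "up" (logFC > 0) or "down" (logFC < 0).
#' @param name signature name.
#' @return list of class `gene_signature` (name, genes, direction).
#' @export
build_signature <- function(mr, top_n, direction = c("up", "down"),
                            name = NULL) {
  direction <- match.arg(direction)
  if (!nrow(mr)) stop("empty marker result")
  sel <- if (direction == "up") mr$log2fc > 0 else mr$log2fc < 0
  sub <- mr[sel, , drop = FALSE]
  ord <- order(-abs(sub$log2fc), sub$p, sub$gene)
  sub <- sub[ord, , drop = FALSE]
  if (nrow(sub) < top_n) {
    warning("only ", nrow(sub), " genes available for a top-", top_n,
            " signature")
  }
  genes <- utils::head(sub$gene, top_n)
  structure(list(name = if (is.null(name)) direction else name,
                 genes = genes, direction = direction),
            class = "gene_signature")
}

#' Binned-control gene-module scores
#'
#' Genes are binned into `n_bins` equal-size bins by the rank of their
#' dataset-average expression. Each module gene draws `n_controls` control
#' genes from its own bin (module genes excluded; with replacement, once
#' warned, when the bin is too small). The cell's score is the mean of the
#' module genes minus the mean of the pooled control multiset.
#'
#' @param x `normalized_matrix` or genes x cells matrix.
#' @param sigs a `gene_signature` or list of them.
#' @param n_bins expression bins (default 24).
#' @param n_controls control genes per module gene (default 100).
#' @param seed integer seed for control sampling.
#' @return matrix cells x signatures of class `module_scores` with scoring
#'   parameters in attributes.
#' @export
score_modules <- function(x, sigs, n_bins = 24L, n_controls = 100L,
                          seed = 1L) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else x
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  nm <- vapply(seq_along(sigs), function(i) {
    if (!is.null(sigs[[i]]$name)) sigs[[i]]$name else paste0("sig", i)
  }, character(1))
  genes <- rownames(vals)
  avg <- Matrix::rowMeans(vals)
  # equal-size bins by rank of average expression
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / (length(genes) / n_bins))
  scores <- matrix(NA_real_, ncol(vals), length(sigs),
                   dimnames = list(colnames(vals), nm))
  with_seed(seed, {
    for (j in seq_along(sigs)) {
      sg <- intersect(sigs[[j]]$genes, genes)
      if (!length(sg)) stop("signature '", nm[j],
                            "' shares no genes with the matrix")
      if (length(sg) < length(sigs[[j]]$genes)) {
        warning("signature '", nm[j], "': ",
                length(sigs[[j]]$genes) - length(sg),
                " genes missing from the matrix, dropped")
      }
      sg_idx <- match(sg, genes)
      warned <- FALSE
      ctrl <- integer(0)
      for (gi in sg_idx) {
        pool <- which(bin == bin[gi])
        pool <- setdiff(pool, sg_idx)
        if (!length(pool)) next
        if (length(pool) < n_controls) {
          if (!warned) {
            warning("bin smaller than n_controls for signature '", nm[j],
                    "'; sampling controls with replacement")
            warned <- TRUE
          }
          ctrl <- c(ctrl, sample(pool, n_controls, replace = TRUE))
        } else {
          ctrl <- c(ctrl, sample(pool, n_controls, replace = FALSE))
        }
      }
      mod_mean <- Matrix::colMeans(vals[sg_idx, , drop = FALSE])
      # pooled control multiset: genes drawn for several module genes count
      # with multiplicity
      ctrl_mean <- Matrix::colMeans(vals[ctrl, , drop = FALSE])
      scores[, j] <- mod_mean - ctrl_mean
    }
  })
  structure(scores, class = c("module_scores", class(scores)),
            n_bins = n_bins, n_controls = n_controls, seed = seed)
}

#' Assign AT2 transcriptional state labels
#'
#' Score mode: each AT2 cell is labelled with the state whose module score
#' is higher, provided the maximum exceeds `tau`; otherwise Unassigned
#' (scores tied above `tau` are also Unassigned). Panel-counts mode
#' (spatial): a state is positive when at least `min_counts` transcripts
#' fall across its panel genes; both positive resolves to the larger count
#' (exact ties Unassigned); neither positive is Unassigned — mirroring the
#' manual annotation that leaves AT2 cells without FMO5/CFTR expression
#' unassigned.
#'
#' @param x `normalized_matrix` over AT2 cells (score mode) or a genes x
#'   cells panel count matrix (panel_counts mode).
#' @param fmo5_sig,cftr_sig `gene_signature`s (or plain gene vectors in
#'   panel mode).
#' @param mode "score" or "panel_counts".
#' @param tau minimum winning module score (default 0).
#' @param min_counts minimum panel transcripts for positivity (default 2).
#' @param ... passed to [score_modules()] in score mode.
#' @return character vector of labels "FMO5+", "CFTR+", "Unassigned".
#' @export
assign_at2_state <- function(x, fmo5_sig, cftr_sig,
                             mode = c("score", "panel_counts"), tau = 0,
                             min_counts = 2L, ...) {
  mode <- match.arg(mode)
  as_genes <- function(s) if (inherits(s, "gene_signature")) s$genes else s
  if (!length(as_genes(fmo5_sig)) || !length(as_genes(cftr_sig))) {
    stop("empty signature")
  }
  if (mode == "score") {
    sc <- score_modules(x, list(
      structure(list(name = "FMO5", genes = as_genes(fmo5_sig)),
                class = "gene_signature"),
      structure(list(name = "CFTR", genes = as_genes(cftr_sig)),
                class = "gene_signature")), ...)
    top <- pmax(sc[, "FMO5"], sc[, "CFTR"])
    lab <- ifelse(top <= tau, "Unassigned",
                  ifelse(sc[, "FMO5"] > sc[, "CFTR"], "FMO5+",
                         ifelse(sc[, "CFTR"] > sc[, "FMO5"], "CFTR+",
                                "Unassigned")))
    return(unname(lab))
  }
  counts <- if (is.list(x) && !is.null(x$panel_counts)) x$panel_counts else x
  gsum <- function(gset) {
    gset <- intersect(gset, rownames(counts))
    if (!length(gset)) return(rep(0, ncol(counts)))
    Matrix::colSums(counts[gset, , drop = FALSE])
  }
  nf <- gsum(as_genes(fmo5_sig)); nc <- gsum(as_genes(cftr_sig))
  fpos <- nf >= min_counts; cpos <- nc >= min_counts
  lab <- rep("Unassigned", ncol(counts))
  lab[fpos & !cpos] <- "FMO5+"
  lab[cpos & !fpos] <- "CFTR+"
  both <- fpos & cpos
  lab[both & nf > nc] <- "FMO5+"
  lab[both & nc > nf] <- "CFTR+"
  lab
}

#' Build per-type maturation on/off gene sets
#'
#' For each cell type present in both the fetal stage and at least one
#' postnatal stage, markers of pooled-postnatal vs fetal cells define the
#' "on" set (top `top_n` upregulated genes) and "off" set (top `top_n`
#' downregulated genes).
#'
#' @param x `normalized_matrix` over the staged reference.
#' @param stage,type per-cell stage and type labels.
#' @param fetal_stage stage name of the fetal reference (default "fetal").
#' @param top_n set size per direction (default 100).
#' @param ... passed to [rank_markers()].
#' @return named list of class `maturation_sets`; per type a list with
#'   `on` and `off` `gene_signature`s.
#' @export
build_maturation_sets <- function(x, stage, type, fetal_stage = "fetal",
                                  top_n = 100L, ...) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else x
  sets <- list()
  for (t in sort(unique(type))) {
    sel <- type == t
    has_fetal <- any(stage[sel] == fetal_stage)
    has_post <- any(stage[sel] != fetal_stage)
    if (!has_fetal || !has_post) {
      warning("type ", t, " absent from a stage; skipped")
      next
    }
    grp <- ifelse(stage[sel] == fetal_stage, "fetal", "postnatal")
    mr <- rank_markers(vals[, sel, drop = FALSE], grp, "postnatal", "fetal",
                       ...)
    if (!nrow(mr)) {
      warning("type ", t, ": no markers passed the filters; skipped")
      next
    }
    on <- tryCatch(build_signature(mr, top_n, "up",
                                   name = paste0(t, ".on")),
                   error = function(e) NULL)
    off <- tryCatch(build_signature(mr, top_n, "down",
                                    name = paste0(t, ".off")),
                    error = function(e) NULL)
    sets[[t]] <- list(on = on, off = off)
  }
  class(sets) <- "maturation_sets"
  sets
}

#' Score cells for maturation on/off programs
#'
#' Computes binned-control module scores of each cell for its own type's
#' on and off sets. When a reference matrix is supplied, query and
#' reference are pooled on shared genes so expression bins are defined in
#' a common frame.
#'
#' @param x `normalized_matrix` over query cells.
#' @param type per-cell type labels mapping onto `sets` names.
#' @param sets a `maturation_sets`.
#' @param reference optional `normalized_matrix` pooled into the bin frame.
#' @param ... passed to [score_modules()].
#' @return data.frame (cell_id, type, on_score, off_score); cells of
#'   unmapped types are skipped with a warning.
#' @export
score_maturation <- function(x, type, sets, reference = NULL, ...) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else x
  pooled <- vals
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "normalized_matrix")) reference$values
      else reference
    shared <- intersect(rownames(vals), rownames(ref))
    pooled <- cbind(vals[shared, , drop = FALSE], ref[shared, , drop = FALSE])
  }
  unmapped <- setdiff(unique(type), names(sets))
  if (length(unmapped)) {
    warning("no maturation sets for type(s): ",
            paste(unmapped, collapse = ", "), "; skipped")
  }
  out <- list()
  for (t in intersect(unique(type), names(sets))) {
    st <- sets[[t]]
    if (is.null(st$on) && is.null(st$off)) next
    sl <- list()
    if (!is.null(st$on)) sl <- c(sl, list(st$on))
    if (!is.null(st$off)) sl <- c(sl, list(st$off))
    sc <- score_modules(pooled, sl, ...)
    cells <- colnames(vals)[type == t]
    out[[t]] <- data.frame(
      cell_id = cells, type = t,
      on_score = if (!is.null(st$on)) sc[cells, st$on$name] else NA_real_,
      off_score = if (!is.null(st$off)) sc[cells, st$off$name] else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-type expression centroids
#'
#' @param x `normalized_matrix` or genes x cells matrix.
#' @param labels per-cell type labels.
#' @return genes x types matrix of mean normalized expression.
#' @export
make_centroids <- function(x, labels) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else x
  types <- sort(unique(labels))
  cen <- vapply(types, function(t)
    Matrix::rowMeans(vals[, labels == t, drop = FALSE]),
    numeric(nrow(vals)))
  rownames(cen) <- rownames(vals)
  cen
}

#' Nearest-centroid label assignment
#'
#' Declared stand-in for anchor-based label transfer: each query cell is
#' labelled with the reference type whose centroid has the highest Pearson
#' correlation over highly variable genes; confidence is the margin over
#' the runner-up. Ties break lexicographically; all-constant cells are
#' Unassigned.
#'
#' @param x `normalized_matrix` over query cells.
#' @param centroids genes x types matrix (see [make_centroids()]).
#' @param n_hvg number of highly variable genes (by variance across
#'   centroids) used for the correlation (default 500, capped at the
#'   shared gene count).
#' @return data.frame (cell_id, label, confidence).
#' @export
assign_labels_nearest_centroid <- function(x, centroids, n_hvg = 500L) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else x
  shared <- intersect(rownames(vals), rownames(centroids))
  if (!length(shared)) stop("no shared genes between query and centroids")
  cen <- centroids[shared, , drop = FALSE]
  v <- apply(cen, 1L, stats::var)
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, length(v)))]
  q <- as.matrix(vals[hvg, , drop = FALSE])
  cmat <- suppressWarnings(stats::cor(q, cen[hvg, , drop = FALSE]))
  types <- colnames(cen)[order(colnames(cen))]
  cmat <- cmat[, types, drop = FALSE]
  lab <- character(ncol(q)); conf <- numeric(ncol(q))
  for (i in seq_len(ncol(q))) {
    ci <- cmat[i, ]
    if (all(is.na(ci))) { lab[i] <- "Unassigned"; conf[i] <- NA_real_; next }
    best <- max(ci, na.rm = TRUE)
    # lexicographically first among ties (columns are sorted)
    lab[i] <- types[which(ci == best)[1L]]
    rest <- ci[-which(ci == best)[1L]]
    conf[i] <- if (length(rest)) best - max(rest, na.rm = TRUE) else NA_real_
  }
  data.frame(cell_id = colnames(q), label = lab, confidence = conf,
             stringsAsFactors = FALSE)
}
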