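# Neighborhood-composition niche detection per tissue section, cross-
# section niche alignment by correlation clustering, and per-label niche
# composition comparison (Welch's t-test with sections as replicates).

#' Neighborhood composition profiles
#'
#' For every cell, counts the cell-type labels among its `k` Euclidean
#' nearest neighbours (self excluded; ties at the k-th distance broken by
#' cell order).
#'
#' @param s a `spatial_map` (list with `cells`: cell_id, x_um, y_um,
#'   label).
#' @param k neighbours per cell (default 20, the full-catalog setting;
#'   the supervised two-niche variant uses 10).
#' @param catalog label catalog defining the profile columns (default: the
#'   labels present).
#' @return list of class `neighborhood_profiles`: `profiles` (cells x
#'   labels integer matrix, rows sum to k), `labels` (own label per cell),
#'   `cell_id`, `section_id`, `k`.
#' @export
neighborhood_profiles <- function(s, k = 20L, catalog = NULL) {
  cells <- s$cells
  n <- nrow(cells)
  if (k >= n) stop("k must be smaller than the section's cell count")
  if (is.null(catalog)) catalog <- sort(unique(cells$label))
  nn <- knn_indices(cbind(cells$x_um, cells$y_um), k)
  lab_idx <- match(cells$label, catalog)
  prof <- matrix(0L, n, length(catalog),
                 dimnames = list(cells$cell_id, catalog))
  neigh_lab <- matrix(lab_idx[nn], n, k)
  for (j in seq_along(catalog)) {
    prof[, j] <- as.integer(rowSums(neigh_lab == j))
  }
  structure(list(profiles = prof, labels = cells$label,
                 cell_id = cells$cell_id, section_id = s$section_id, k = k),
            class = "neighborhood_profiles")
}

#' Fit spatial niches by k-means on neighborhood composition
#'
#' Columns (labels) of the neighborhood-composition matrix are standardized
#' to zero mean and unit variance (zero-variance columns dropped), then
#' clustered with k-means (Lloyd's algorithm, k-means++ initialization,
#' `n_init` seeded restarts, best inertia kept). Each niche's composition
#' profile is the distribution of its member cells' own labels.
#'
#' @param p a `neighborhood_profiles`.
#' @param K number of niches (default 4; the supervised alveolar-only
#'   variant uses 2).
#' @param seed integer seed.
#' @param n_init k-means restarts (default 10).
#' @param standardize standardize columns before clustering (default TRUE).
#' @return list of class `niche_model`: `assignment` (niche id per cell),
#'   `composition` (K x labels matrix, rows are probability vectors),
#'   `section_id`, `K`, `k`, `seed`, `scaling`.
#' @export
fit_niches <- function(p, K = 4L, seed = 1L, n_init = 10L,
                       standardize = TRUE) {
  stopifnot(inherits(p, "neighborhood_profiles"))
  X <- p$profiles
  if (K > nrow(X)) stop("K exceeds the number of cells")
  scaling <- NULL
  if (standardize) {
    mu <- colMeans(X); sdv <- apply(X, 2L, stats::sd)
    keep <- sdv > 0
    X <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
    scaling <- list(center = mu[keep], scale = sdv[keep], dropped = !keep)
  } else {
    X <- X * 1.0
  }
  fit <- kmeans_pp(X, K, seed = seed, n_init = n_init)
  catalog <- colnames(p$profiles)
  comp <- t(vapply(seq_len(K), function(j) {
    own <- p$labels[fit$cluster == j]
    vapply(catalog, function(l) mean(own == l), numeric(1))
  }, numeric(length(catalog))))
  dimnames(comp) <- list(paste0(p$section_id, ".niche", seq_len(K)), catalog)
  structure(list(assignment = fit$cluster, composition = comp,
                 labels = p$labels, cell_id = p$cell_id,
                 section_id = p$section_id,
                 K = K, k = p$k, seed = seed, scaling = scaling,
                 inertia = fit$tot.withinss),
            class = "niche_model")
}

#' Align niches across sections by composition correlation
#'
#' Pearson correlation between all (section, niche) composition profiles,
#' average-linkage hierarchical clustering on distance `1 - r`, tree cut
#' into `n_groups` groups (default: the niche count K of the first model).
#'
#' @param models list of `niche_model`s sharing a label catalog.
#' @param n_groups number of aligned niche groups.
#' @return list of class `niche_correspondence`: `correlation` (symmetric
#'   matrix with unit diagonal), `tree` (hclust), `groups` (data.frame:
#'   section, niche, profile id, group).
#' @export
align_niches_across_sections <- function(models, n_groups = NULL) {
  if (length(models) < 2L) stop("need at least 2 sections")
  if (is.null(n_groups)) n_groups <- models[[1L]]$K
  prof <- do.call(rbind, lapply(models, function(m) m$composition))
  sec <- unlist(lapply(models, function(m) rep(m$section_id, m$K)))
  niche <- unlist(lapply(models, function(m) seq_len(m$K)))
  sdv <- apply(prof, 1L, stats::sd)
  if (any(sdv == 0)) {
    warning("constant niche profile(s): correlation undefined; ",
            "assigned via nearest valid profile")
  }
  ok <- sdv > 0
  r <- matrix(NA_real_, nrow(prof), nrow(prof),
              dimnames = list(rownames(prof), rownames(prof)))
  r[ok, ok] <- stats::cor(t(prof[ok, , drop = FALSE]))
  diag(r) <- 1
  # constant profiles inherit the correlations of the Euclidean-nearest
  # valid profile
  for (i in which(!ok)) {
    d <- rowSums((prof[ok, , drop = FALSE] -
                    matrix(prof[i, ], sum(ok), ncol(prof), byrow = TRUE))^2)
    j <- which(ok)[which.min(d)]
    r[i, ] <- r[j, ]; r[, i] <- r[, j]; r[i, i] <- 1
  }
  tree <- stats::hclust(stats::as.dist(1 - r), method = "average")
  grp <- stats::cutree(tree, k = n_groups)
  groups <- data.frame(profile = rownames(prof), section = sec,
                       niche = niche, group = unname(grp),
                       stringsAsFactors = FALSE)
  structure(list(correlation = r, tree = tree, groups = groups,
                 profiles = prof, n_groups = n_groups),
            class = "niche_correspondence")
}

#' Compare cell-type composition between two aligned niche groups
#'
#' Per label, a two-sided Welch unequal-variance t-test on per-section
#' composition proportions, each section a biological replicate. A
#' section's proportion for a group pools the member cells of all its
#' niches in that group. Significance stars at 0.05 / 0.01 / 0.001;
#' BH-adjusted p-values also reported.
#'
#' @param corr a `niche_correspondence`.
#' @param models the `niche_model` list used to build it.
#' @param groupA,groupB group ids from `corr$groups$group`.
#' @return data.frame (label, mean_A, mean_B, t, df, p, p_bh, stars).
#' @export
compare_niche_composition <- function(corr, models, groupA, groupB) {
  names(models) <- vapply(models, function(m) m$section_id, character(1))
  catalog <- colnames(models[[1L]]$composition)
  by_sec <- function(g) {
    rows <- corr$groups[corr$groups$group == g, , drop = FALSE]
    secs <- unique(rows$section)
    if (length(secs) < 2L) {
      stop("group ", g, " present in fewer than 2 sections")
    }
    out <- t(vapply(secs, function(s) {
      m <- models[[s]]
      niches <- rows$niche[rows$section == s]
      sel <- m$assignment %in% niches
      vapply(catalog, function(l) mean(m$labels[sel] == l), numeric(1))
    }, numeric(length(catalog))))
    colnames(out) <- catalog
    out
  }
  A <- by_sec(groupA); B <- by_sec(groupB)
  labels <- colnames(A)
  res <- do.call(rbind, lapply(labels, function(l) {
    a <- A[, l]; b <- B[, l]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      return(data.frame(label = l, mean_A = mean(a), mean_B = mean(b),
                        t = 0, df = NA_real_, p = 1,
                        stringsAsFactors = FALSE))
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(label = l, mean_A = mean(a), mean_B = mean(b),
               t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, stringsAsFactors = FALSE)
  }))
  res$p_bh <- stats::p.adjust(res$p, "BH")
  res$stars <- cut(res$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  res
}
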