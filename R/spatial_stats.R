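# Cell-type colocalization statistics: symmetric mean nearest-neighbor
# distances with one-way ANOVA + Tukey HSD across sections, and same-label
# join-count statistics over distance bands with analytic (random-
# labeling) and permutation nulls.

#' Symmetric mean nearest-neighbor distance between two cell types
#'
#' `d(A->B)` is the mean over A cells of the Euclidean distance to the
#' closest B cell; the symmetric distance is the average of the two
#' directed means (both directed means are returned so the pooled
#' alternative is checkable).
#'
#' @param s a `spatial_map`.
#' @param typeA,typeB distinct labels.
#' @return data.frame (section, typeA, typeB, d_ab, d_ba, d_sym, n_A,
#'   n_B); all-NA with a warning if a type is missing.
#' @export
symmetric_mean_nn_distance <- function(s, typeA, typeB) {
  stopifnot(typeA != typeB)
  cells <- s$cells
  A <- cells[cells$label == typeA, c("x_um", "y_um"), drop = FALSE]
  B <- cells[cells$label == typeB, c("x_um", "y_um"), drop = FALSE]
  if (!nrow(A) || !nrow(B)) {
    warning("type ", if (!nrow(A)) typeA else typeB, " missing from section ",
            s$section_id)
    return(data.frame(section = s$section_id, typeA = typeA, typeB = typeB,
                      d_ab = NA_real_, d_ba = NA_real_, d_sym = NA_real_,
                      n_A = nrow(A), n_B = nrow(B)))
  }
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d_ab <- mean(sqrt(apply(d2, 1L, min)))
  d_ba <- mean(sqrt(apply(d2, 2L, min)))
  data.frame(section = s$section_id, typeA = typeA, typeB = typeB,
             d_ab = d_ab, d_ba = d_ba, d_sym = (d_ab + d_ba) / 2,
             n_A = nrow(A), n_B = nrow(B))
}

#' One-way ANOVA with Tukey HSD on pair distances across sections
#'
#' Pools the per-section symmetric distances of each type pair and tests
#' for differences between pairs, with Tukey's Honest Significant
#' Difference for all pairwise contrasts.
#'
#' @param d data.frame as returned by stacking
#'   [symmetric_mean_nn_distance()] rows across sections, with a `pair`
#'   column (created from typeA/typeB when absent).
#' @return list (anova_F, anova_p, tukey: data.frame contrast, diff, lwr,
#'   upr, p_adj, fit).
#' @export
distance_anova_tukey <- function(d) {
  d <- d[!is.na(d$d_sym), , drop = FALSE]
  if (is.null(d$pair)) d$pair <- paste(d$typeA, d$typeB, sep = "|")
  counts <- table(d$pair)
  if (length(counts) < 2L) stop("need at least 2 type pairs")
  if (any(counts < 2L)) stop("every pair needs >= 2 observations")
  d$pair <- factor(d$pair)
  fit <- stats::aov(d_sym ~ pair, data = d)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$pair
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(anova_F = an[["F value"]][1L], anova_p = an[["Pr(>F)"]][1L],
       tukey = tukey, fit = fit)
}

# Concatenate sections into one field by offsetting y so no distance-band
# edge can cross sections.
concat_sections <- function(sections, max_radius) {
  offset <- 0
  out <- list()
  for (s in sections) {
    cells <- s$cells
    h <- max(cells$y_um) - min(cells$y_um)
    cells$y_um <- cells$y_um - min(cells$y_um) + offset
    offset <- offset + h + 10 * max_radius
    out[[length(out) + 1L]] <- cells
  }
  do.call(rbind, out)
}

#' Join-count self-association over distance bands
#'
#' Sections are concatenated into one field by y-offsetting (gap = section
#' height + 10x the maximum radius). For each radius `r`, binary weights
#' `w_ij = 1` iff `0 < d_ij <= r`; the statistic is the number of edges
#' joining two cells that both carry `label`. The analytic null uses
#' nonfree-sampling (random-labeling) moments; the permutation null
#' shuffles labels across the whole field.
#'
#' @param sections list of `spatial_map`s (typically pre-filtered to the
#'   two AT2-state labels, as in the self-association analysis).
#' @param label the label whose self-association is tested.
#' @param radii distance bands in um (default 10:30, 1 um steps).
#' @param null "analytic" or "permutation".
#' @param n_perm permutations (default 999).
#' @param seed integer seed (permutation null).
#' @return data.frame of class `joincount_result`: label, radius, n,
#'   n_positive, S0, J_obs, EJ, sdJ, Z, p, degenerate, null, n_perm.
#' @export
joincount_profile <- function(sections, label, radii = 10:30,
                              null = c("analytic", "permutation"),
                              n_perm = 999L, seed = 1L) {
  null <- match.arg(null)
  if (inherits(sections, "spatial_map")) sections <- list(sections)
  cells <- concat_sections(sections, max(radii))
  n <- nrow(cells)
  x <- as.numeric(cells$label == label)
  n1 <- sum(x)
  if (n1 < 2L) stop("fewer than 2 cells carry label ", label)
  xy <- cbind(cells$x_um, cells$y_um)
  d2 <- outer(rowSums(xy^2), rowSums(xy^2), "+") - 2 * tcrossprod(xy)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  perm_labels <- NULL
  if (null == "permutation") {
    perm_labels <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample(x), numeric(n))
    })
  }
  res <- lapply(radii, function(r) {
    W <- d2 <= r^2                      # symmetric, diag FALSE (Inf)
    S0 <- sum(W)                        # both directions
    deg <- rowSums(W)
    J_obs <- sum(W[x == 1, x == 1]) / 2
    if (S0 == 0) {
      return(data.frame(label = label, radius = r, n = n, n_positive = n1,
                        S0 = 0, J_obs = 0, EJ = NA_real_, sdJ = NA_real_,
                        Z = NA_real_, p = NA_real_, degenerate = TRUE,
                        null = null, n_perm = if (null == "permutation")
                          n_perm else NA_integer_))
    }
    if (null == "analytic") {
      # random-labeling (nonfree sampling) moments, binary symmetric weights
      S1 <- 2 * S0
      S2 <- 4 * sum(deg^2)
      p2 <- n1 * (n1 - 1) / (n * (n - 1))
      p3 <- p2 * (n1 - 2) / (n - 2)
      p4 <- p3 * (n1 - 3) / (n - 3)
      EJ <- S0 / 2 * p2
      EJ2 <- (S1 * p2 + (S2 - 2 * S1) * p3 + (S0^2 + S1 - S2) * p4) / 4
      varJ <- EJ2 - EJ^2
      degenerate <- varJ <= 0 || n1 == n
      Z <- if (degenerate) NA_real_ else (J_obs - EJ) / sqrt(varJ)
      p <- if (degenerate) NA_real_ else 2 * stats::pnorm(-abs(Z))
      data.frame(label = label, radius = r, n = n, n_positive = n1, S0 = S0,
                 J_obs = J_obs, EJ = EJ,
                 sdJ = if (degenerate) NA_real_ else sqrt(varJ), Z = Z,
                 p = p, degenerate = degenerate, null = null,
                 n_perm = NA_integer_)
    } else {
      ij <- which(W & upper.tri(W), arr.ind = TRUE)
      J_perm <- vapply(seq_len(n_perm), function(b) {
        xb <- perm_labels[, b]
        sum(xb[ij[, 1]] * xb[ij[, 2]])
      }, numeric(1))
      EJ <- mean(J_perm); sdJ <- stats::sd(J_perm)
      degenerate <- !is.finite(sdJ) || sdJ == 0
      Z <- if (degenerate) NA_real_ else (J_obs - EJ) / sdJ
      p <- (1 + sum(abs(J_perm - EJ) >= abs(J_obs - EJ))) / (n_perm + 1)
      data.frame(label = label, radius = r, n = n, n_positive = n1, S0 = S0,
                 J_obs = J_obs, EJ = EJ, sdJ = sdJ, Z = Z, p = p,
                 degenerate = degenerate, null = null, n_perm = n_perm)
    }
  })
  out <- do.call(rbind, res)
  class(out) <- c("joincount_result", "data.frame")
  out
}
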