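#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic 31-bit sub-seed from a parent seed and a path
#'
#' Splittable-seed stand-in: hashes the parent seed together with string/
#' integer path components so each specimen/section/stage draws from an
#' independent, reproducible stream.
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    for (ch in utf8ToInt(p)) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h %% 2147483646) + 1L
}

#' k nearest neighbours by Euclidean distance
#'
#' Returns an n x k matrix of row indices of the k nearest neighbours of
#' each point, excluding the point itself. Ties at the k-th distance are
#' broken by row (cell) order.
#'
#' @param xy numeric matrix of coordinates (points in rows).
#' @param k number of neighbours.
#' @param block number of query rows handled per vectorized block.
#' @return integer matrix, one row per point, k columns.
#' @export
knn_indices <- function(xy, k, block = 512L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (k >= n) stop("k must be smaller than the number of points")
  sq <- rowSums(xy^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # squared distances from block rows to all points
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(xy[idx, , drop = FALSE], xy)
    d2[cbind(seq_along(idx), idx)] <- Inf
    res <- vapply(seq_len(nrow(d2)), function(i)
      order(d2[i, ])[seq_len(k)], integer(k))
    if (k == 1L) out[idx, 1L] <- res else out[idx, ] <- t(res)
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)
  (sij - expected) / (max_index - expected)
}

#' k-means++ initial centers
#' @noRd
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(K - 1L) + 1L) {
    prob <- d2 / sum(d2)
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = prob)
    }
    nd <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Seeded k-means with k-means++ restarts (Lloyd's algorithm)
#' @noRd
kmeans_pp <- function(x, K, seed, n_init = 10L, iter_max = 300L) {
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      cen <- kmeanspp_centers(x, K)
      # jitter duplicate centers so stats::kmeans accepts them
      if (anyDuplicated(cen)) {
        cen <- cen + matrix(rnorm(length(cen), sd = 1e-8), nrow(cen))
      }
      fit <- suppressWarnings(
        stats::kmeans(x, centers = cen, iter.max = iter_max,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
}

#' Z-score a numeric matrix row-wise (sample SD)
#'
#' Used for heatmap-style standardization of assay values (e.g. RT-qPCR
#' panels across treatments): each row is centred by its mean and scaled by
#' its sample standard deviation (denominator n - 1).
#'
#' @param x numeric matrix.
#' @return matrix of the same shape; constant rows become 0.
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  (x - mu) / sdv
}
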