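# Genetic-diversity clustering of posterior-mean genotypic values:
# squared Mahalanobis distances between family vectors, Ward
# minimum-variance agglomeration carried out in whitened coordinates so
# fusion levels are exact within-cluster SSE increases in the Mahalanobis
# metric, and the Mojena stopping rule for the number of clusters.

# upper Cholesky factor of S^-1 with a singularity guard; whitening with
# this factor turns Mahalanobis distances into Euclidean ones
whitening_factor <- function(S) {
  if (!is_spd(S)) {
    kap <- tryCatch(kappa(S, exact = TRUE), error = function(e) Inf)
    stop(sprintf("covariance matrix is singular or not positive-definite (condition number %.3g)",
                 kap), call. = FALSE)
  }
  chol(chol2inv(chol(S)))
}

#' Pairwise squared Mahalanobis distances
#'
#' `d2(g1, g2) = (g1 - g2)' S^-1 (g1 - g2)` for every pair of rows of the
#' genotypic-value matrix.
#'
#' @param gv Numeric matrix, one row per family, columns in canonical
#'   trait order.
#' @param S Trait covariance matrix defining the metric (classically the
#'   residual covariance `R0`); must be positive-definite.
#' @return Symmetric `n x n` matrix of squared distances, zero diagonal.
#' @examples
#' gv <- matrix(rnorm(20 * 3), 20)
#' D2 <- mahalanobis_matrix(gv, diag(3))  # squared Euclidean
#' @export
mahalanobis_matrix <- function(gv, S) {
  gv <- as.matrix(gv)
  R_u <- whitening_factor(S)
  D2 <- as.matrix(stats::dist(gv %*% t(R_u)))^2
  dimnames(D2) <- list(rownames(gv), rownames(gv))
  D2
}

#' Ward minimum-variance clustering in the Mahalanobis metric
#'
#' Whitens the genotypic values by a square-root factor of `S^-1`
#' (Mahalanobis geometry becomes Euclidean), then agglomerates by Ward's
#' criterion: at each step the pair of clusters whose merge minimizes the
#' increase in total within-cluster sum of squared errors is joined, and
#' that SSE increase is recorded as the fusion level. Fusion levels are
#' non-decreasing; the stored merge history is `hclust`-compatible (see
#' [as.hclust.mt_ward()]).
#'
#' @param gv Numeric matrix of posterior-mean genotypic values, one row
#'   per family (rownames used as labels).
#' @param S Metric covariance matrix; `NULL` uses the identity (plain
#'   Euclidean Ward).
#' @return Object of class `mt_ward`: list with `merge`, `height`
#'   (SSE-increase fusion levels), `order`, `labels`.
#' @seealso [mojena_cut()], [write_newick()]
#' @export
ward_cluster <- function(gv, S = NULL) {
  gv <- as.matrix(gv)
  n <- nrow(gv)
  if (n < 2L) stop("need at least 2 families to cluster", call. = FALSE)
  X <- if (is.null(S)) gv else gv %*% t(whitening_factor(S))
  labels <- rownames(gv)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active-cluster state: centroids, sizes, hclust-style ids
  cent <- X
  size <- rep(1, n)
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  # Ward merge cost for all active pairs against cluster i (vectorized)
  cost_against <- function(i, js) {
    dd <- cent[js, , drop = FALSE] -
      matrix(cent[i, ], length(js), ncol(X), byrow = TRUE)
    (size[i] * size[js] / (size[i] + size[js])) * rowSums(dd * dd)
  }
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) cost[i, (i + 1L):n] <- cost_against(i, (i + 1L):n)

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- arrayInd(which.min(cost), dim(cost))
    i <- k[1L]; j <- k[2L]
    height[step] <- cost[i, j]
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    # merged cluster replaces slot i; slot j retires
    cent[i, ] <- (size[i] * cent[i, ] + size[j] * cent[j, ]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    id[i] <- step
    active[j] <- FALSE
    cost[j, ] <- Inf; cost[, j] <- Inf
    others <- which(active)
    others <- others[others != i]
    if (length(others)) {
      cc <- cost_against(i, others)
      lo <- others < i
      if (any(lo)) cost[cbind(others[lo], i)] <- cc[lo]
      if (any(!lo)) cost[cbind(i, others[!lo])] <- cc[!lo]
    }
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge), labels = labels,
                 metric = if (is.null(S)) "euclidean" else "mahalanobis"),
            class = "mt_ward")
}

# leaf ordering by iterative traversal of the merge tree (left before
# right), matching hclust's plotting convention
hclust_order <- function(merge) {
  n <- nrow(merge) + 1L
  out <- integer(0)
  stack <- nrow(merge)  # start at the root
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node < 0L) out <- c(out, -node)
    else stack <- c(stack, merge[node, 2L], merge[node, 1L])
  }
  out
}

#' @export
print.mt_ward <- function(x, ...) {
  cat(sprintf("Ward minimum-variance clustering (%s metric): %d leaves, %d merges\n",
              x$metric, length(x$labels), nrow(x$merge)))
  cat(sprintf("fusion levels (SSE increase): min %.4g, max %.4g\n",
              min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a Ward clustering to an `hclust` object
#'
#' Heights are the SSE-increase fusion levels, so [stats::cutree()] and
#' [ape::as.phylo()] work directly.
#'
#' @param x An [ward_cluster()] object.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.mt_ward <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "ward",
                 dist.method = x$metric, call = match.call()),
            class = "hclust")
}

#' Cut a dendrogram by the Mojena stopping rule
#'
#' Computes the mean and (sample, `n - 1` divisor) standard deviation of
#' the `n - 1` fusion levels and scans the merges in agglomeration order
#' for the first level exceeding `mean + omega * sd`. The tree is cut
#' immediately before that merge, giving `k = n - j + 1` clusters for
#' first exceedance at step `j`; if no level exceeds the threshold the
#' whole tree is one cluster.
#'
#' @param dend An [ward_cluster()] or `hclust` object.
#' @param omega Threshold constant (conventional default 1.25).
#' @return List with `k`, `assignments` (named integer vector of cluster
#'   labels), `threshold`, `cut_step` (`NA` when `k = 1`), `omega`, and
#'   `sizes` (cluster size table).
#' @examples
#' gv <- rbind(matrix(rnorm(30, 0), 10), matrix(rnorm(30, 8), 10))
#' mojena_cut(ward_cluster(gv))$k
#' @export
mojena_cut <- function(dend, omega = 1.25) {
  h <- if (inherits(dend, "mt_ward")) stats::as.hclust(dend)
       else if (inherits(dend, "hclust")) dend
       else stop("dend must be an mt_ward or hclust object", call. = FALSE)
  alpha <- h$height
  n <- length(alpha) + 1L
  thr <- mean(alpha) + omega * stats::sd(alpha)
  exceed <- which(alpha > thr)
  if (!length(exceed) || is.na(thr)) {
    k <- 1L; cut_step <- NA_integer_
  } else {
    cut_step <- exceed[1L]
    k <- n - cut_step + 1L
  }
  assignments <- stats::cutree(h, k = k)
  names(assignments) <- h$labels
  list(k = k, assignments = assignments, threshold = thr,
       cut_step = cut_step, omega = omega,
       sizes = table(assignments))
}

#' Export a dendrogram and its companion tables
#'
#' `write_newick()` writes the tree in Newick format with the fusion
#' levels as node heights (via [ape::as.phylo()]); `write_merge_table()`
#' writes the merge history (step, joined members, fusion level);
#' `write_assignments()` writes a two-column family-to-cluster table.
#'
#' @param x An [ward_cluster()] object (`write_assignments()` takes a
#'   [mojena_cut()] result).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "mt_ward"))
  ape::write.tree(ape::as.phylo(stats::as.hclust(x)), file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
write_merge_table <- function(x, path) {
  stopifnot(inherits(x, "mt_ward"))
  utils::write.csv(data.frame(step = seq_along(x$height),
                              member1 = x$merge[, 1L], member2 = x$merge[, 2L],
                              fusion_level = x$height),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_newick
#' @export
write_assignments <- function(x, path) {
  stopifnot(is.list(x), !is.null(x$assignments))
  utils::write.csv(data.frame(family_id = names(x$assignments),
                              cluster = as.integer(x$assignments)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
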