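#' Build a cross-collection feature matrix from meristograms
#'
#' Concatenates several interpolated meristograms into one matrix whose
#' rows are collections and whose columns are hook variables at each
#' integer percent-position (`L` block, then `B`, `A`, `R`), restricted to
#' the intersection of the position grids of all inputs so that every cell
#' is observed. All meristograms must be interpolated (so they sit on the
#' integer grid) and computed at the same moving-average interval, since
#' curve shape depends on the window width.
#'
#' @param ms A list of [meristogram()] objects (at least 2).
#' @return A `feature_matrix`: a tibble whose first column is `label`,
#'   followed by numeric columns named like `L_25`, with attributes
#'   `positions` (the common grid) and `mai`.
#' @export
feature_matrix <- function(ms) {
  if (length(ms) < 2) {
    abort("need at least 2 meristograms to compare",
          class = "meristo_usage_error")
  }
  if (!all(vapply(ms, function(m) isTRUE(attr(m, "interpolated")), TRUE))) {
    abort("all meristograms must be interpolated; recompute with interpolate = TRUE",
          class = "meristo_usage_error")
  }
  mais <- vapply(ms, function(m) attr(m, "mai"), 1L)
  if (length(unique(mais)) != 1) {
    abort("meristograms were computed at different moving-average intervals",
          class = "meristo_usage_error")
  }
  grid <- Reduce(intersect, lapply(ms, function(m) curve_points(m)$x))
  if (length(grid) == 0) {
    abort("position grids of the meristograms do not overlap",
          class = "meristo_usage_error")
  }
  grid <- sort(grid)
  rows <- lapply(ms, function(m) {
    pts <- curve_points(m)
    pts <- pts[match(grid, pts$x), ]
    vals <- c(pts$L, pts$B, pts$A, pts$R)
    names(vals) <- paste(rep(c("L", "B", "A", "R"), each = length(grid)),
                         rep(grid, 4), sep = "_")
    c(list(label = attr(m, "label")), as.list(vals))
  })
  out <- bind_rows(rows)
  new_tibble(out, positions = grid, mai = mais[1], class = "feature_matrix")
}

#' @export
as.matrix.feature_matrix <- function(x, ...) {
  m <- as.matrix(as_tibble(x)[-1])
  rownames(m) <- x$label
  m
}

#' Principal component analysis of meristogram curves
#'
#' Covariance PCA of the feature matrix: columns are mean-centred but not
#' variance-scaled, since every feature already lives on the common
#' percent-of-maximum scale. The sign of each component is fixed so that
#' the largest-magnitude loading entry is positive, making scores
#' reproducible across platforms.
#'
#' @param fm A [feature_matrix()].
#' @return A `meristogram_pca` with elements `scores` (tibble: `label`,
#'   `PC1`, ...), `loadings` (tibble: `feature`, `variable`, `position`,
#'   `PC1`, ...), `variance_fraction`, `total_variance` and `center`.
#' @export
meristogram_pca <- function(fm) {
  x <- as.matrix(fm)
  if (nrow(x) < 2) {
    abort("PCA needs at least 2 collections", class = "meristo_usage_error")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # fix sign: largest-magnitude entry of each loading vector positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_comp <- pc$sdev^2
  total <- sum(var_comp)
  scores <- as_tibble(pc$x)
  scores <- bind_cols(tibble(label = fm$label), scores)
  feats <- colnames(x)
  parts <- strsplit(feats, "_", fixed = TRUE)
  loadings <- bind_cols(
    tibble(feature = feats,
           variable = vapply(parts, `[`, "", 1),
           position = as.numeric(vapply(parts, `[`, "", 2))),
    as_tibble(pc$rotation))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = if (total > 0) var_comp / total
                                     else rep(NaN, length(var_comp)),
                 total_variance = total,
                 center = pc$center),
            class = "meristogram_pca")
}

#' @export
print.meristogram_pca <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("<meristogram PCA: %d collections, PC1 %.1f%%, PC2 %.1f%% of variance>\n",
              nrow(x$scores), 100 * vf[1],
              if (length(vf) > 1) 100 * vf[2] else 0))
  invisible(x)
}

#' @rdname meristogram_pca
#' @param x A `meristogram_pca`.
#' @param ... Unused.
#' @export
tidy.meristogram_pca <- function(x, ...) x$scores

#' @rdname meristogram_pca
#' @export
glance.meristogram_pca <- function(x, ...) {
  vf <- x$variance_fraction
  tibble(n_collections = nrow(x$scores),
         n_features = nrow(x$loadings),
         total_variance = x$total_variance,
         pc1_fraction = vf[1],
         pc2_fraction = if (length(vf) > 1) vf[2] else NA_real_,
         pc12_fraction = sum(vf[seq_len(min(2, length(vf)))]))
}

#' Scatterplot of PCA scores
#'
#' @param object A [meristogram_pca()].
#' @param ... Unused.
#' @return A ggplot of the first two component scores, points labelled by
#'   collection.
#' @export
autoplot.meristogram_pca <- function(object, ...) {
  vf <- 100 * object$variance_fraction
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.7, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", vf[1]),
                  y = sprintf("PC2 (%.1f%%)", vf[2])) +
    ggplot2::theme_minimal()
}

#' Pairwise distances between PCA scores
#'
#' @param scores Score tibble (from `meristogram_pca()$scores`) or a
#'   numeric matrix with row names.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"maximum"`
#'   (Chebyshev) or `"minkowski"`.
#' @param p Minkowski exponent (> 0); default 3 so the metric is distinct
#'   from Euclidean.
#' @param components Number of leading components to use (default 2).
#' @return A `dist` object.
#' @export
score_distances <- function(scores, metric = c("euclidean", "manhattan",
                                               "maximum", "minkowski"),
                            p = 3, components = 2) {
  metric <- match.arg(metric)
  if (is.data.frame(scores)) {
    m <- as.matrix(scores[setdiff(names(scores), "label")])
    rownames(m) <- scores$label
  } else {
    m <- as.matrix(scores)
  }
  components <- min(components, ncol(m))
  m <- m[, seq_len(components), drop = FALSE]
  if (nrow(m) < 2) {
    abort("need at least 2 score points", class = "meristo_usage_error")
  }
  if (!is.finite(p) || p <= 0) {
    abort("Minkowski exponent must be positive",
          class = "meristo_usage_error")
  }
  stats::dist(m, method = metric, p = p)
}

#' UPGMA clustering of collections
#'
#' Classic unweighted pair group method with arithmetic mean: at each step
#' the two clusters at minimal distance are merged at a node of height half
#' that distance, and distances to the merged cluster are the
#' size-weighted average of the members' distances. Ties are broken by the
#' lexicographically smallest pair of cluster labels (each cluster
#' represented by its alphabetically first leaf), so the result is
#' deterministic across platforms. The result is a rooted, ultrametric
#' tree.
#'
#' @param d A `dist` object or symmetric non-negative matrix.
#' @param labels Leaf labels; defaults to the labels of `d`.
#' @return An [ape::phylo] tree (rooted, ultrametric, with edge lengths).
#' @export
upgma <- function(d, labels = NULL) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8)) {
    abort("distance matrix must be symmetric", class = "meristo_usage_error")
  }
  if (any(dm < 0)) {
    abort("distance matrix has negative entries",
          class = "meristo_usage_error")
  }
  n <- nrow(dm)
  if (is.null(labels)) labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n < 2) {
    abort("need at least 2 leaves", class = "meristo_usage_error")
  }

  # agglomerate, recording merges in hclust convention
  # (negative index = singleton leaf, positive = earlier merge row)
  cl_idx <- -seq_len(n)          # hclust index of each active cluster
  size <- rep(1, n)
  rep_label <- labels            # alphabetically first leaf of each cluster
  D <- dm
  merge <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    k <- length(cl_idx)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        lab <- sort(c(rep_label[i], rep_label[j]))
        cand <- list(d = D[i, j], lab1 = lab[1], lab2 = lab[2], i = i, j = j)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (cand$lab1 < best$lab1 ||
              (cand$lab1 == best$lab1 && cand$lab2 < best$lab2)))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- as.integer(c(cl_idx[i], cl_idx[j]))
    heights[step] <- best$d
    new_row <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_row[keep]),
               c(new_row[keep], 0))
    cl_idx <- c(cl_idx[keep], step)
    size <- c(size[keep], size[i] + size[j])
    rep_label <- c(rep_label[keep], min(rep_label[i], rep_label[j]))
  }

  hc <- structure(list(merge = merge, height = heights,
                       order = hclust_order(merge), labels = labels,
                       method = "average",
                       call = match.call(), dist.method = "unknown"),
                  class = "hclust")
  ape::as.phylo(hc)  # node heights = merge distance / 2 -> ultrametric
}

# leaf ordering consistent with the merge matrix (left-to-right traversal)
hclust_order <- function(merge) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(nrow(merge))
}

#' Write a dendrogram in Newick format
#'
#' @param tree An [ape::phylo] tree (e.g. from [upgma()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Full comparative clustering step
#'
#' Runs PCA on a feature matrix and clusters the leading component scores
#' by UPGMA under the requested distance metric.
#'
#' @param fm A [feature_matrix()].
#' @param metric,p,components Passed to [score_distances()].
#' @return An [ape::phylo] dendrogram.
#' @export
cluster_collections <- function(fm, metric = "euclidean", p = 3,
                                components = 2) {
  pca <- meristogram_pca(fm)
  if (pca$total_variance <= 0) {
    abort("collections are identical (zero total variance); clustering refused",
          class = "meristo_usage_error")
  }
  d <- score_distances(pca$scores, metric = metric, p = p,
                       components = components)
  upgma(d)
}
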