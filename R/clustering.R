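#' Pearson correlation with degeneracy checks
#'
#' Thin wrapper over the sample Pearson coefficient that refuses
#' zero-variance input instead of silently returning `NA`. On binary
#' vectors this equals the phi coefficient.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero-variance input: correlation is undefined")
  }
  stats::cor(x, y)
}

#' Correlation-distance matrix over rows or columns
#'
#' Computes pairwise Pearson correlations between innervation profiles
#' (matrix rows = DN types, columns = neuropils) and returns the
#' dissimilarity `d = 1 - r`, with range \[0, 2\]. Zero-variance profiles
#' (e.g. compartments no DN innervates, or all-innervating types) have no
#' defined correlation; the default policy drops them with a warning,
#' mirroring the convention of omitting uninnervated regions, and the
#' alternative assigns them the maximal distance 2 from everything.
#'
#' @param matrix numeric matrix (typically a [build_matrix()] result).
#' @param axis `"rows"` or `"cols"`: which profiles to compare.
#' @param degenerate `"exclude"` (default) or `"max"`.
#' @return a `dn_distance` object: symmetric matrix with zero diagonal,
#'   attributes `metric = "pearson"` and `excluded` (character vector of
#'   dropped labels).
#' @export
correlation_distance_matrix <- function(matrix, axis = c("rows", "cols"),
                                        degenerate = c("exclude", "max")) {
  axis <- match.arg(axis)
  degenerate <- match.arg(degenerate)
  prof <- if (axis == "rows") t(matrix) else matrix  # profiles in columns
  v <- apply(prof, 2, stats::var)
  degen <- colnames(prof)[v == 0]
  if (degenerate == "exclude") {
    if (length(degen) > 0) {
      warning("excluding ", length(degen), " zero-variance profile(s): ",
              paste(degen, collapse = ", "))
      prof <- prof[, v > 0, drop = FALSE]
    }
    if (ncol(prof) < 2) stop("fewer than 2 usable profiles")
    d <- 1 - stats::cor(prof)
  } else {
    if (ncol(prof) < 2) stop("fewer than 2 usable profiles")
    d <- matrix(2, ncol(prof), ncol(prof),
                dimnames = list(colnames(prof), colnames(prof)))
    ok <- which(v > 0)
    if (length(ok) >= 2) {
      d[ok, ok] <- 1 - stats::cor(prof[, ok, drop = FALSE])
    }
    diag(d) <- 0
  }
  # clamp tiny negative fp residue
  d[d < 0 & d > -1e-12] <- 0
  structure(d, metric = "pearson", excluded = degen,
            class = c("dn_distance", class(d)))
}

#' Autocorrelation matrix of innervation profiles
#'
#' Pairwise Pearson correlation between neuropil profiles (`axis =
#' "cols"`, the compartment-by-compartment similarity maps) or DN-type
#' profiles (`axis = "rows"`). Zero-variance labels are excluded with a
#' warning and reported in the `excluded` attribute.
#'
#' @inheritParams correlation_distance_matrix
#' @return a symmetric correlation matrix (class `dn_correlation`) with
#'   unit diagonal and attribute `excluded`.
#' @export
autocorrelation <- function(matrix, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  d <- correlation_distance_matrix(matrix, axis = axis,
                                   degenerate = "exclude")
  r <- 1 - unclass(d)
  structure(r, excluded = attr(d, "excluded"),
            class = c("dn_correlation", class(r)))
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates a dissimilarity matrix by unweighted average linkage: at
#' every step the pair of clusters with the smallest mean pairwise
#' dissimilarity is merged at a height equal to that mean, and distances
#' to the merged cluster are maintained with the size-weighted
#' Lance-Williams update, which keeps them exactly equal to the mean of
#' the original dissimilarities across the two clusters. Ties on the
#' minimum are broken deterministically in favour of the candidate pair
#' whose smallest member leaf indices are lexicographically least.
#'
#' @param distance a symmetric dissimilarity matrix with zero diagonal
#'   (e.g. from [correlation_distance_matrix()]), n >= 2, or a
#'   `dn_distance` object.
#' @return a `dn_dendrogram`: list with `merge` (hclust-style (n-1) x 2
#'   matrix, negative entries = leaves, positive = earlier merges),
#'   `height` (merge heights, non-decreasing), `labels`, and
#'   `method = "average"`.
#' @examples
#' d <- matrix(c(0, 2, 6, 10,
#'               2, 0, 6, 10,
#'               6, 6, 0, 4,
#'               10, 10, 4, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' average_linkage(d)$height  # 2, 4, 8
#' @export
average_linkage <- function(distance) {
  d <- unclass(distance)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2) stop("need at least two items to cluster")
  if (any(d < 0)) stop("negative dissimilarities are not allowed")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix is asymmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active[i]: cluster id occupying slot i (negative = leaf, positive =
  # merge index); size[i]: member count; minleaf[i]: smallest leaf index.
  active <- -seq_len(n)
  size <- rep(1L, n)
  minleaf <- seq_len(n)
  alive <- rep(TRUE, n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    best_val <- Inf
    best_key <- c(Inf, Inf)
    idx <- which(alive)
    for (ai in seq_along(idx)) {
      i <- idx[ai]
      for (bj in seq_along(idx)) {
        if (bj <= ai) next
        j <- idx[bj]
        val <- D[i, j]
        key <- sort(c(minleaf[i], minleaf[j]))
        if (val < best_val ||
            (val == best_val &&
             (key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best_val <- val
          best_key <- key
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    # order merge entries: leaves before merges, then by appearance
    pair <- sort(c(active[i], active[j]))
    merge[step, ] <- pair
    height[step] <- best_val
    # Lance-Williams UPGMA update into slot i
    others <- setdiff(idx, c(i, j))
    if (length(others) > 0) {
      D[i, others] <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[others, i] <- D[i, others]
    }
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    active[i] <- step
    alive[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = labels,
                 method = "average"),
            class = "dn_dendrogram")
}

#' @export
print.dn_dendrogram <- function(x, ...) {
  cat(sprintf("<dn_dendrogram> %d leaves, %s linkage; merge heights: %s\n",
              length(x$labels), x$method,
              paste(signif(x$height, 4), collapse = ", ")))
  invisible(x)
}

# Leaf ordering compatible with the merge matrix (for hclust conversion).
.dendrogram_order <- function(merge) {
  n <- nrow(merge) + 1L
  members <- function(k) {
    if (k < 0) return(-k)
    c(members(merge[k, 1]), members(merge[k, 2]))
  }
  members(n - 1L)
}

#' Convert a dendrogram to an hclust object
#' @param x a `dn_dendrogram`.
#' @param ... unused.
#' @return a [stats::hclust] object (usable with `plot`, `cutree`, ape).
#' @export
as.hclust.dn_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = .dendrogram_order(x$merge), labels = x$labels,
                 method = x$method, call = match.call(),
                 dist.method = "1 - pearson"),
            class = "hclust")
}

#' Flat clusters from a dendrogram
#'
#' Cuts the tree either into `k` clusters (undoing the last `k - 1`
#' merges) or at height `h` (keeping merges with height <= `h`).
#' Cluster numbers are assigned stably by leaf order: cluster 1 contains
#' the first leaf, and so on.
#'
#' @param dendrogram a `dn_dendrogram`.
#' @param k desired number of clusters (1..n), or
#' @param h height threshold (>= 0); exactly one of `k`, `h` is given.
#' @return named integer vector of cluster memberships (names = labels).
#' @export
cut_dendrogram <- function(dendrogram, k = NULL, h = NULL) {
  stopifnot(inherits(dendrogram, "dn_dendrogram"))
  n <- length(dendrogram$labels)
  if (is.null(k) == is.null(h)) stop("give exactly one of k or h")
  if (!is.null(k)) {
    if (k < 1 || k > n) stop("k must be between 1 and ", n)
    n_merges <- n - k
  } else {
    if (h < 0) stop("h must be nonnegative")
    n_merges <- sum(dendrogram$height <= h)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  cluster_rep <- integer(n - 1L)  # leaf representative of each merge node
  for (s in seq_len(n - 1L)) {
    a <- dendrogram$merge[s, 1]
    b <- dendrogram$merge[s, 2]
    ra <- if (a < 0) -a else cluster_rep[a]
    rb <- if (b < 0) -b else cluster_rep[b]
    cluster_rep[s] <- min(ra, rb)
    if (s <= n_merges) parent[find(max(ra, rb))] <- find(min(ra, rb))
  }
  root <- vapply(seq_len(n), find, 1L)
  ids <- unique(root)            # first-appearance = leaf order
  membership <- match(root, ids)
  stats::setNames(membership, dendrogram$labels)
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths are height differences between nested merges — the
#' standard ultrametric embedding of an hclust-style tree, as produced by
#' the ape conversion.
#'
#' @param dendrogram a `dn_dendrogram`.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
export_newick <- function(dendrogram, path = NULL) {
  phy <- ape::as.phylo(as.hclust.dn_dendrogram(dendrogram))
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
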