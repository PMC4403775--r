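#' Hierarchical agglomerative clustering with the study's scheme pairings
#'
#' Three schemes are offered with their fixed metric pairings: single linkage
#' and group-average linkage on Euclidean distance, and Ward's method on
#' squared Euclidean distance (no post-hoc square-rooting of heights).
#' Agglomeration follows the Lance-Williams update; among pairs at equal
#' dissimilarity the pair with the lexicographically smallest (i, j) active
#' cluster indices is merged first, so the merge sequence is fully
#' deterministic.
#'
#' @param profiles Numeric matrix or data frame, items in rows, features in
#'   columns. Cluster genes or samples by transposing as needed.
#' @param scheme One of `"single"`, `"average"`, `"ward"`.
#' @return A `dendro` object: `merge` (hclust-style merge matrix: negative
#'   entries are leaves, positive entries earlier merges), `height`
#'   (nondecreasing merge dissimilarities), `labels`, `scheme`, `metric`.
#' @export
hcluster <- function(profiles, scheme = c("single", "average", "ward")) {
  scheme <- match.arg(scheme)
  X <- as.matrix(profiles)
  if (!is.numeric(X) || any(!is.finite(X))) {
    stop("`profiles` must be a finite numeric matrix", call. = FALSE)
  }
  n <- nrow(X)
  if (n < 2) stop("need at least 2 items to cluster", call. = FALSE)
  labels <- rownames(X)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))

  d <- as.matrix(stats::dist(X, method = "euclidean"))
  metric <- "euclidean"
  if (scheme == "ward") {
    d <- d^2
    metric <- "squared_euclidean"
  }
  diag(d) <- Inf

  # active[i]: hclust-style id of the cluster currently living in slot i
  # (negative leaf or positive merge index); size[i]: its cardinality
  active <- -seq_len(n)
  alive <- rep(TRUE, n)
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(alive)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    # ascending (ii, jj) scan: the first pair at the minimum is the
    # lexicographically smallest, which is the tie-break rule
    for (ii in idx) {
      for (jj in idx) {
        if (jj <= ii) next
        if (d[ii, jj] < best_d - 1e-12) {
          best_d <- d[ii, jj]
          best <- c(ii, jj)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort_merge_pair(active[i], active[j])
    height[step] <- d[i, j]

    ni <- size[i]; nj <- size[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- size[k]
      d_new <- switch(scheme,
        single  = min(d[i, k], d[j, k]),
        average = (ni * d[i, k] + nj * d[j, k]) / (ni + nj),
        ward    = ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
                  (ni + nj + nk)
      )
      d[i, k] <- d[k, i] <- d_new
    }
    alive[j] <- FALSE
    d[j, ] <- Inf
    d[, j] <- Inf
    size[i] <- ni + nj
    active[i] <- step
  }
  structure(list(merge = merge, height = height, labels = labels,
                 scheme = scheme, metric = metric),
            class = "dendro")
}

# hclust convention: leaves (negative) before merges (positive); two leaves
# or two merges ordered ascending by absolute value
sort_merge_pair <- function(a, b) {
  pair <- c(a, b)
  pair[order(pair >= 0, abs(pair))]
}

#' @export
print.dendro <- function(x, ...) {
  cat(sprintf("<dendro> %d leaves, %s linkage on %s distance\n",
              length(x$labels), x$scheme, x$metric))
  invisible(x)
}

#' Convert to a base-R hclust object
#'
#' @param x A `dendro`.
#' @param ... Unused.
#' @return An object of class `hclust` (plottable, exportable to newick via
#'   `ape::as.phylo`).
#' @export
as.hclust.dendro <- function(x, ...) {
  n <- length(x$labels)
  h <- list(merge = x$merge, height = x$height,
            order = dendro_leaf_order(x$merge, n),
            labels = x$labels,
            method = x$scheme, dist.method = x$metric,
            call = match.call())
  class(h) <- "hclust"
  h
}

dendro_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand_last <- expand(nrow(merge))
  as.integer(expand_last)
}

#' Cut a dendrogram into k clusters
#'
#' Labels are canonicalized by order of first appearance over the leaf input
#' order, so the partition is invariant to internal cluster numbering.
#'
#' @param dendro A `dendro`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels (1..k), named by leaf label.
#' @export
partition <- function(dendro, k) {
  stopifnot(inherits(dendro, "dendro"))
  n <- length(dendro$labels)
  if (k < 1 || k > n) stop("`k` must be between 1 and ", n, call. = FALSE)
  raw <- stats::cutree(as.hclust.dendro(dendro), k = k)
  canonicalize_partition(raw, dendro$labels)
}

canonicalize_partition <- function(raw, labels = names(raw)) {
  out <- match(raw, unique(raw))
  names(out) <- labels
  out
}

#' Three-scheme clustering robustness check
#'
#' Clusters the same profiles with single linkage (Euclidean), group average
#' (Euclidean) and Ward (squared Euclidean), cuts each tree at `k`, and
#' reports whether all three partitions coincide up to label permutation,
#' plus the pairwise Rand indices.
#'
#' @param profiles Items x features matrix.
#' @param k Number of clusters at which to compare.
#' @return A list with `partitions` (named list of canonical label vectors),
#'   `all_agree` (logical), and `rand` (tibble of pairwise Rand indices).
#' @export
robustness_check <- function(profiles, k) {
  schemes <- c("single", "average", "ward")
  parts <- purrr::map(schemes, function(s) partition(hcluster(profiles, s), k))
  names(parts) <- schemes
  pairs <- utils::combn(schemes, 2)
  rand <- purrr::map_dfr(seq_len(ncol(pairs)), function(m) {
    a <- pairs[1, m]; b <- pairs[2, m]
    tibble::tibble(scheme_a = a, scheme_b = b,
                   rand_index = rand_index(parts[[a]], parts[[b]]))
  })
  agree <- all(vapply(parts, function(p) identical(unname(p), unname(parts[[1]])),
                      logical(1)))
  list(partitions = parts, all_agree = agree, rand = rand)
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two partitions agree (together in both or
#' apart in both).
#'
#' @param a,b Integer label vectors of equal length.
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}

#' Serialize a dendrogram as a merge table
#'
#' @param x A `dendro`.
#' @param ... Unused.
#' @return A tibble with one row per merge: `step`, `left`, `right`
#'   (hclust-convention indices), `height`.
#' @method tidy dendro
#' @export
tidy.dendro <- function(x, ...) {
  tibble::tibble(step = seq_along(x$height),
                 left = x$merge[, 1], right = x$merge[, 2],
                 height = x$height)
}
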