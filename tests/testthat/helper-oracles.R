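# Independent oracles used to cross-check the package's own implementations.

# Textbook one-way fixed-effects F via stats::oneway.test (Welch disabled).
oracle_f <- function(values_list) {
  y <- unlist(values_list, use.names = FALSE)
  g <- factor(rep(seq_along(values_list), lengths(values_list)))
  ot <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(f = unname(ot$statistic), p = unname(ot$p.value))
}

# Prim's algorithm: weights of the minimum spanning tree over Euclidean
# distances. Single-linkage merge heights must equal these, sorted.
oracle_mst_heights <- function(X) {
  d <- as.matrix(stats::dist(X))
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    heights[step] <- min(sub)
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    in_tree[j] <- TRUE
  }
  sort(heights)
}

# Equal-priors Mahalanobis nearest-group rule in the original variable space,
# using the pooled within-group covariance (denominator N - g).
oracle_mahalanobis_classify <- function(train, groups, newdata) {
  groups <- droplevels(as.factor(groups))
  n_g <- as.vector(table(groups))
  means <- rowsum(as.matrix(train), groups) / n_g
  Xc <- as.matrix(train) - means[groups, , drop = FALSE]
  W <- crossprod(Xc) / (nrow(train) - nlevels(groups))
  Winv <- solve(W)
  d2 <- apply(as.matrix(newdata), 1, function(z) {
    apply(means, 1, function(m) {
      dv <- z - m
      drop(dv %*% Winv %*% dv)
    })
  })
  lev <- levels(groups)
  factor(lev[apply(d2, 2, which.min)], levels = lev)
}

# Leaf sets merged at each agglomeration step, as canonical sorted vectors;
# lets merge sequences from different implementations be compared without
# depending on within-row ordering conventions.
merge_leafsets <- function(merge) {
  sets <- vector("list", nrow(merge))
  leaves <- function(node) {
    if (node < 0) return(-node)
    sets[[node]]
  }
  for (s in seq_len(nrow(merge))) {
    sets[[s]] <- sort(c(leaves(merge[s, 1]), leaves(merge[s, 2])))
  }
  sets
}

# Small labelled random expression matrix on the linear scale.
random_matrix <- function(n_probes, n_samples, seed) {
  withr::with_seed(seed, {
    v <- matrix(2^rnorm(n_probes * n_samples, 7, 1.5), n_probes, n_samples)
  })
  dimnames(v) <- list(paste0("p", seq_len(n_probes)),
                      paste0("s", seq_len(n_samples)))
  expression_matrix(v)
}

# The study's 15-chip design (5 groups x 3 replicates).
full_design <- function() {
  tibble::tibble(
    sample_id = paste0(rep(predation_groups, each = 3), "_", 1:3),
    group = rep(predation_groups, each = 3)
  )
}

# Compact scenario for fast unit tests: same structure, fewer probes.
small_scenario <- function(seed = 1, templates = default_templates()) {
  predation_scenario(n_probes = 400, n_control_probes = 20,
                     templates = templates, seed = seed)
}
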