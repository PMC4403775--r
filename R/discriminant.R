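#' Fit a canonical (linear) discriminant analysis
#'
#' Solves the generalized eigenproblem that maximizes the ratio of
#' between-group to within-group scatter of a linear combination of the
#' selected genes. The within-group scatter is pooled with denominator
#' `N - g` and the between-group scatter is weighted by group sizes; the
#' eigenproblem is solved by two-sided whitening (inverse symmetric square
#' root of the pooled within-group covariance) followed by a symmetric eigen
#' decomposition, which keeps the solution stable and the eigenvalues real.
#'
#' Scaling convention: unstandardized coefficients are scaled so the pooled
#' within-group covariance of the training scores is the identity, and each
#' function's constant absorbs the grand mean so the size-weighted grand
#' centroid maps to the origin. Eigenvectors are sign-ambiguous, so each
#' function is oriented deterministically: the first group's centroid
#' coordinate (the control group, in the study design) is made non-negative
#' on function 1; every later function is flipped, if needed, so its first
#' centroid coordinate exceeding `1e-8` in magnitude is positive.
#'
#' With `p` variables, `N` samples and `g` groups the pooled within-group
#' covariance is singular whenever `p > N - g`; the fit then stops with an
#' error reporting the maximum usable number of variables. (This is exactly
#' why a 14-chip, 5-group design supports at most 9 genes.)
#'
#' @param data Numeric matrix or data frame, samples in rows, selected
#'   genes/probes in columns (column names are the variable list).
#' @param groups Factor (or coercible) of group labels, one per sample.
#' @return A `cda` object: `coefficients` (p x q), `constants` (length q),
#'   `eigenvalues` (nonincreasing, length q), `centroids` (g x q),
#'   `grand_means`, `variables`, `groups` (levels), `n_per_group`, `scores`
#'   (training scores), `whitener` (the within-covariance factor used).
#' @export
fit_cda <- function(data, groups) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("`data` must be numeric", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(X)) {
    stop("`groups` must have one label per sample (row)", call. = FALSE)
  }
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  n_g <- as.vector(table(groups))
  if (any(n_g < 2)) stop("every group needs at least 2 samples", call. = FALSE)
  if (p > n - g) {
    stop(sprintf(paste0("singular within-group covariance: %d variables exceed ",
                        "the maximum usable %d (= N - g = %d - %d); drop ",
                        "variables to at most %d"),
                 p, n - g, n, g, n - g), call. = FALSE)
  }

  grand <- colMeans(X)
  means <- rowsum(X, groups) / n_g            # g x p group means
  Xc <- X - means[groups, , drop = FALSE]     # within-group deviations
  W <- crossprod(Xc) / (n - g)                # pooled within covariance
  dev <- sweep(means, 2, grand)               # centroid deviations
  B <- crossprod(dev * sqrt(n_g))             # size-weighted between SSCP

  eW <- eigen(W, symmetric = TRUE)
  if (min(eW$values) <= max(eW$values) * 1e-10) {
    stop("singular within-group covariance: a variable is (nearly) a linear ",
         "combination of the others within groups; remove redundant variables",
         call. = FALSE)
  }
  Wi_half <- eW$vectors %*% (t(eW$vectors) / sqrt(eW$values))  # W^(-1/2)
  M <- Wi_half %*% B %*% Wi_half
  M <- (M + t(M)) / 2
  eM <- eigen(M, symmetric = TRUE)
  q <- min(g - 1, p)
  # eigenvalues reported in the conventional W^-1 B (SSCP-ratio) scale
  lambda <- pmax(eM$values[seq_len(q)], 0) / (n - g)
  A <- Wi_half %*% eM$vectors[, seq_len(q), drop = FALSE]  # a' W a = 1

  centroids <- dev %*% A
  for (k in seq_len(q)) {
    pivot <- if (k == 1) 1 else which(abs(centroids[, k]) > 1e-8)[1]
    if (!is.na(pivot) && centroids[pivot, k] < 0) {
      A[, k] <- -A[, k]
      centroids[, k] <- -centroids[, k]
    }
  }
  constants <- -drop(grand %*% A)
  scores <- X %*% A + rep(constants, each = n)
  fn_names <- paste0("CF", seq_len(q))
  dimnames(A) <- list(colnames(X), fn_names)
  dimnames(centroids) <- list(levels(groups), fn_names)
  colnames(scores) <- fn_names
  rownames(scores) <- rownames(X)
  structure(
    list(coefficients = A, constants = stats::setNames(constants, fn_names),
         eigenvalues = stats::setNames(lambda, fn_names),
         centroids = centroids, grand_means = grand,
         variables = colnames(X), groups = levels(groups), n_per_group = n_g,
         scores = scores, training_groups = groups, whitener = Wi_half),
    class = "cda"
  )
}

#' @export
print.cda <- function(x, ...) {
  q <- length(x$eigenvalues)
  cat(sprintf("<cda> %d variables, %d groups, %d canonical function(s)\n",
              length(x$variables), length(x$groups), q))
  cat("eigenvalues:", paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  if (q >= 2) {
    cat(sprintf("first 2 functions carry %.1f%% of the discrimination\n",
                percent_discrimination(x, 2)))
  }
  invisible(x)
}

#' Project observations onto the canonical discriminant functions
#'
#' Each score is `constant + sum(coefficient * value)` per function; the
#' training grand mean maps to the origin.
#'
#' @param model A `cda` fit.
#' @param observations Samples x variables matrix/data frame; column names
#'   must cover the model's variable list (order is fixed by name).
#' @return Numeric matrix of canonical scores (samples x q).
#' @export
project_cda <- function(model, observations) {
  stopifnot(inherits(model, "cda"))
  X <- as.matrix(observations)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$variables)) {
      stop("observations have ", ncol(X), " variables; model expects ",
           length(model$variables), call. = FALSE)
    }
    colnames(X) <- model$variables
  }
  missing <- setdiff(model$variables, colnames(X))
  extra <- setdiff(colnames(X), model$variables)
  if (length(missing)) {
    stop("observations lack model variable(s): ", paste(missing, collapse = ", "),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  X <- X[, model$variables, drop = FALSE]
  X %*% model$coefficients + rep(model$constants, each = nrow(X))
}

#' @export
predict.cda <- function(object, newdata, ...) {
  classify_cda(object, newdata)
}

#' Nearest-centroid classification in canonical space
#'
#' Scores are whitened (pooled within-group covariance is the identity), so
#' Euclidean distance to the group centroids in full canonical space equals
#' Mahalanobis distance in the original variable space restricted to the
#' discriminant subspace; with `q = g - 1` functions the rule is exactly the
#' equal-priors Mahalanobis classifier. Ties go to the lowest group index.
#'
#' @param model A `cda` fit.
#' @param observations As in [project_cda()].
#' @return Factor of group labels, levels as in the model.
#' @export
classify_cda <- function(model, observations) {
  sc <- project_cda(model, observations)
  d2 <- outer(rowSums(sc^2), rowSums(model$centroids^2), "+") -
    2 * sc %*% t(model$centroids)
  idx <- apply(d2, 1, function(r) which(r <= min(r) + 1e-9)[1])
  factor(model$groups[idx], levels = model$groups)
}

#' Percent of total discrimination carried by the leading functions
#'
#' `100 * sum(eigenvalues[1:k]) / sum(eigenvalues)`.
#'
#' @param model A `cda` fit.
#' @param k Number of leading canonical functions, `1 <= k <= q`.
#' @return A percentage in `[0, 100]`.
#' @export
percent_discrimination <- function(model, k) {
  stopifnot(inherits(model, "cda"))
  q <- length(model$eigenvalues)
  if (k < 1 || k > q) stop("`k` must be between 1 and ", q, call. = FALSE)
  tot <- sum(model$eigenvalues)
  if (tot <= 0) stop("all eigenvalues are zero; discrimination undefined",
                     call. = FALSE)
  100 * sum(model$eigenvalues[seq_len(k)]) / tot
}

#' Territorial-map boundary between two group centroids
#'
#' Under whitened scores and equal priors the nearest-centroid decision
#' boundary between two groups in the plane of the first two canonical
#' functions is the perpendicular bisector of the centroid pair. Returned in
#' general form `a*x + b*y = c`, with the slope/intercept view filled in when
#' the line is not vertical.
#'
#' @param c_i,c_j Numeric 2-vectors: the two centroids in the (CF1, CF2)
#'   plane.
#' @return A one-row tibble: `a`, `b`, `c`, `slope`, `intercept` (the last
#'   two `NA` for a vertical line).
#' @export
#' @examples
#' boundary_line(c(-3.883, -2.388), c(-49.253, -3.269))
boundary_line <- function(c_i, c_j) {
  c_i <- as.numeric(c_i); c_j <- as.numeric(c_j)
  stopifnot(length(c_i) == 2, length(c_j) == 2)
  if (isTRUE(all.equal(c_i, c_j, tolerance = 0))) {
    stop("coincident centroids: boundary undefined", call. = FALSE)
  }
  d <- c_j - c_i
  if (all(d == 0)) stop("coincident centroids: boundary undefined", call. = FALSE)
  a <- d[1]; b <- d[2]
  cc <- sum((c_j^2 - c_i^2)) / 2        # d . midpoint
  if (b != 0) {
    tibble::tibble(a = a, b = b, c = cc, slope = -a / b, intercept = cc / b)
  } else {
    tibble::tibble(a = a, b = b, c = cc, slope = NA_real_, intercept = NA_real_)
  }
}

#' All pairwise territorial-map boundaries of a fit
#'
#' @param model A `cda` fit with at least two canonical functions.
#' @return A tibble with one row per group pair: `group_i`, `group_j`, and
#'   the [boundary_line()] columns.
#' @export
boundary_lines <- function(model) {
  stopifnot(inherits(model, "cda"))
  if (length(model$eigenvalues) < 2) {
    stop("territorial map needs at least 2 canonical functions", call. = FALSE)
  }
  cen <- model$centroids[, 1:2, drop = FALSE]
  pairs <- utils::combn(seq_along(model$groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dplyr::bind_cols(
      tibble::tibble(group_i = model$groups[i], group_j = model$groups[j]),
      boundary_line(cen[i, ], cen[j, ])
    )
  })
}

#' Largest number of variables a design can support
#'
#' The pooled within-group covariance of `N` samples in `g` groups has rank
#' at most `N - g`; more variables than that make it singular.
#'
#' @param n_samples Total number of samples.
#' @param n_groups Number of groups.
#' @return `n_samples - n_groups`.
#' @export
max_usable_variables <- function(n_samples, n_groups) n_samples - n_groups

#' Tidy the canonical discriminant functions
#'
#' @param x A `cda` fit.
#' @param ... Unused.
#' @return A tibble with one row per variable per function: `function_name`
#'   (`CF1`, ...), `term` (variable or `"(constant)"`), `estimate`.
#' @method tidy cda
#' @export
tidy.cda <- function(x, ...) {
  q <- length(x$eigenvalues)
  purrr::map_dfr(seq_len(q), function(k) {
    tibble::tibble(
      function_name = names(x$constants)[k],
      term = c("(constant)", x$variables),
      estimate = c(x$constants[k], x$coefficients[, k])
    )
  })
}

#' One-row summary of a canonical discriminant fit
#'
#' @param x A `cda` fit.
#' @param ... Unused.
#' @return A tibble with `n_variables`, `n_groups`, `n_functions`,
#'   `percent_first_two` (share of discrimination carried by the first two
#'   functions; 100 when only one exists), `training_accuracy`.
#' @method glance cda
#' @export
glance.cda <- function(x, ...) {
  q <- length(x$eigenvalues)
  acc <- mean(classify_scores(x, x$scores) == x$training_groups)
  tibble::tibble(
    n_variables = length(x$variables),
    n_groups = length(x$groups),
    n_functions = q,
    percent_first_two = percent_discrimination(x, min(2, q)),
    training_accuracy = acc
  )
}

# nearest-centroid rule applied to already-projected scores (training points
# keep their stored scores, so no re-projection is needed)
classify_scores <- function(model, scores) {
  d2 <- outer(rowSums(scores^2), rowSums(model$centroids^2), "+") -
    2 * scores %*% t(model$centroids)
  idx <- apply(d2, 1, function(r) which(r <= min(r) + 1e-9)[1])
  factor(model$groups[idx], levels = model$groups)
}

#' Territorial-map plot
#'
#' Scatter of the training scores in the (CF1, CF2) plane with group
#' centroids and the pairwise nearest-centroid boundary lines.
#'
#' @param object A `cda` fit with at least two canonical functions.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cda
#' @export
autoplot.cda <- function(object, ...) {
  stopifnot(inherits(object, "cda"))
  sc <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE]) |>
    dplyr::mutate(group = group_display_name(as.character(object$training_groups)))
  cen <- tibble::as_tibble(object$centroids[, 1:2, drop = FALSE]) |>
    dplyr::mutate(group = group_display_name(rownames(object$centroids)))
  bnd <- boundary_lines(object) |> dplyr::filter(!is.na(.data$slope))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$CF1, y = .data$CF2)) +
    ggplot2::geom_abline(data = bnd,
                         ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
    ggplot2::geom_point(data = cen, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::labs(x = "Canonical function 1", y = "Canonical function 2",
                  colour = "Group", title = "Territorial map") +
    ggplot2::theme_minimal()
}
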