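#' Exact Sidak per-test significance level
#'
#' For `m` independent tests and a family-wise error rate `fwer` (the
#' probability that at least one test is falsely significant when all null
#' hypotheses hold), the exact per-test level is
#' `alpha = 1 - (1 - fwer)^(1/m)`. Computed via `expm1(log1p(-fwer)/m)` so
#' that tiny alphas retain full relative precision.
#'
#' With 15611 probes this gives 3.2857e-6 (0.00032857%) at a 5% family-wise
#' rate and 1.474867e-4 (0.01474867%) at 90%.
#'
#' @param fwer Family-wise error rate, strictly between 0 and 1.
#' @param m Number of independent tests, a positive integer.
#' @return The per-test significance level.
#' @export
#' @examples
#' sidak_alpha(0.05, 15611)
#' sidak_alpha(0.90, 15611)
sidak_alpha <- function(fwer, m) {
  if (!is.numeric(fwer) || length(fwer) != 1 || fwer <= 0 || fwer >= 1) {
    stop("`fwer` must be a single probability strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  -expm1(log1p(-fwer) / m)
}

#' Family-wise error policy
#'
#' Bundles the family-wise error rate, the number of tests, and the derived
#' exact per-test level.
#'
#' @param fwer Family-wise error rate in (0, 1). The screening default is
#'   0.90: with more than ten thousand probes a 5% family-wise rate leaves a
#'   per-test level too strict to detect anything in low-signal cross-species
#'   hybridizations, so the screen deliberately tolerates a high probability
#'   of at least one false positive.
#' @param m Number of tests; defaults to the number of probes actually tested
#'   when the policy is applied by [screen_probes()].
#' @return A list with `fwer`, `m`, `alpha`.
#' @export
fwer_policy <- function(fwer = 0.90, m = NULL) {
  out <- list(fwer = fwer, m = m, alpha = if (!is.null(m)) sidak_alpha(fwer, m))
  structure(out, class = "fwer_policy")
}

#' @export
print.fwer_policy <- function(x, ...) {
  cat(sprintf("<fwer_policy> FWER %.4g over %s tests; per-test alpha %s\n",
              x$fwer, if (is.null(x$m)) "(n probes)" else format(x$m),
              if (is.null(x$alpha)) "(derived at screen time)" else
                format(x$alpha, digits = 7)))
  invisible(x)
}

#' One-way fixed-effects ANOVA for a single probe
#'
#' @param values List of numeric vectors, one per group (at least two groups,
#'   each with at least two observations). Groups may be unbalanced.
#' @return A list with `f`, `p`, `df1` (g - 1), `df2` (N - g).
#' @export
#' @examples
#' anova_probe(list(c(1, 2, 3), c(4, 5, 6), c(1, 3, 2)))
anova_probe <- function(values) {
  if (!is.list(values) || length(values) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  n_g <- lengths(values)
  if (any(n_g < 2)) stop("every group needs at least 2 observations", call. = FALSE)
  all_v <- unlist(values, use.names = FALSE)
  g <- length(values)
  n <- length(all_v)
  grand <- mean(all_v)
  means <- vapply(values, mean, numeric(1))
  ssb <- sum(n_g * (means - grand)^2)
  ssw <- sum(vapply(seq_len(g), function(i) sum((values[[i]] - means[i])^2),
                    numeric(1)))
  if (ssw <= 0) {
    stop("degenerate within-group variance (SSW = 0); F undefined", call. = FALSE)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  list(f = f, p = stats::pf(f, g - 1, n - g, lower.tail = FALSE),
       df1 = g - 1, df2 = n - g)
}

# Vectorised per-probe one-way ANOVA over the rows of a matrix.
# groups: factor of length ncol(values). Returns data.frame of f, p, ssw.
row_f_stats <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  n <- ncol(values)
  n_g <- as.vector(table(groups))
  # group sums via indicator matrix: values %*% G, G[j, k] = 1{sample j in group k}
  ind <- vapply(levels(groups), function(l) as.numeric(groups == l), numeric(n))
  gsum <- values %*% ind
  gmean <- sweep(gsum, 2, n_g, "/")
  grand <- rowSums(values) / n
  ssb <- rowSums(sweep((gmean - grand)^2, 2, n_g, "*"))
  sst <- rowSums(values^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  list(f = f, ssb = ssb, ssw = ssw, df1 = g - 1, df2 = n - g, gmean = gmean)
}

#' Family-wise-error-gated per-probe ANOVA screen
#'
#' Runs a one-way fixed-effects ANOVA across treatment groups for every probe
#' and gates significance at the exact Sidak per-test level. Probes whose
#' ANOVA is undefined (zero within-group variance) are reported with reason
#' `"degenerate"` and never pass: an infinite F in this framework is an
#' artifact, not evidence.
#'
#' @param x An `expression_matrix` with a design attached ([join_design()]).
#'   By convention the normalized log2 matrix ([baseline_to_median()]) is
#'   screened; the function accepts either scale.
#' @param fwer Family-wise error rate (default 0.90; see [fwer_policy()]).
#' @param m Number of tests for the Sidak correction. Defaults to the number
#'   of probes in `x`; pass the array's full probe count explicitly when
#'   screening a pre-filtered matrix.
#' @return A tibble with one row per probe, in input probe order: `probe_id`,
#'   per-group mean columns (`mean_<group>`), `f`, `df1`, `df2`, `p`, `pass`,
#'   `reason` (`"ok"` or `"degenerate"`), plus the `alpha` applied (same value
#'   in every row).
#' @export
screen_probes <- function(x, fwer = 0.90, m = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  groups <- group_factor(x)
  if (nlevels(groups) < 2) stop("screen needs at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 samples; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  if (is.null(m)) m <- nrow(x$values)
  alpha <- sidak_alpha(fwer, m)
  st <- row_f_stats(x$values, groups)
  degenerate <- st$ssw <= 0
  p <- stats::pf(st$f, st$df1, st$df2, lower.tail = FALSE)
  gmeans <- st$gmean
  colnames(gmeans) <- paste0("mean_", levels(groups))
  rownames(gmeans) <- NULL
  tibble::tibble(
    probe_id = probe_ids(x),
    tibble::as_tibble(gmeans),
    f = unname(ifelse(degenerate, NA_real_, st$f)),
    df1 = st$df1, df2 = st$df2,
    p = unname(ifelse(degenerate, NA_real_, p)),
    pass = unname(!degenerate & !is.na(p) & p < alpha),
    reason = unname(ifelse(degenerate, "degenerate", "ok")),
    alpha = alpha
  )
}
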