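#' Control-probe hybridization QC
#'
#' Flags failed hybridizations from the spiked control probes (the AFFX-BioB
#' ... AFFX-r2-P1-cre series on Affymetrix arrays). For each chip the control
#' probe profile is rank-correlated (Spearman) against every other chip; a
#' chip fails when its median rank correlation falls below `min_correlation`.
#' A successfully hybridized chip shares the control-probe profile of its
#' peers, so its median correlation is high; a failed hybridization is close
#' to independent noise.
#'
#' @param x An `expression_matrix` (design optional).
#' @param control_prefix Prefix identifying control probes (default `"AFFX"`).
#' @param min_correlation Threshold in `[-1, 1]` below which a chip is
#'   flagged; default 0.8.
#' @return A tibble (one row per sample) with `sample_id`,
#'   `median_control_intensity`, `median_rank_correlation`, `pass`, and the
#'   threshold used in `min_correlation`.
#' @export
qc_control_probes <- function(x, control_prefix = "AFFX", min_correlation = 0.8) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!is.numeric(min_correlation) || min_correlation < -1 || min_correlation > 1) {
    stop("`min_correlation` must be in [-1, 1]", call. = FALSE)
  }
  is_ctrl <- startsWith(probe_ids(x), control_prefix)
  if (sum(is_ctrl) < 2) {
    stop("fewer than 2 probes match control prefix ", sQuote(control_prefix),
         call. = FALSE)
  }
  if (ncol(x$values) < 3) {
    stop("control-probe QC needs at least 3 samples to form a correlation panel",
         call. = FALSE)
  }
  ctrl <- x$values[is_ctrl, , drop = FALSE]
  rho <- stats::cor(ctrl, method = "spearman")
  diag(rho) <- NA_real_
  med_rho <- apply(rho, 2, stats::median, na.rm = TRUE)
  tibble::tibble(
    sample_id = sample_ids(x),
    median_control_intensity = apply(ctrl, 2, stats::median),
    median_rank_correlation = unname(med_rho),
    pass = unname(med_rho) >= min_correlation,
    min_correlation = min_correlation
  )
}

#' Drop QC-failed chips from an expression matrix
#'
#' Removes samples flagged by [qc_control_probes()] and, when a design is
#' attached, refuses to leave any treatment group with fewer than two chips
#' (the downstream ANOVA would be undefined).
#'
#' @param x An `expression_matrix`.
#' @param report QC tibble from [qc_control_probes()] on the same matrix.
#' @return The matrix restricted to passing samples.
#' @export
drop_failed <- function(x, report) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!setequal(report$sample_id, sample_ids(x))) {
    stop("QC report does not cover this matrix's samples", call. = FALSE)
  }
  failed <- report$sample_id[!report$pass]
  if (length(failed) == 0) return(x)
  keep <- setdiff(sample_ids(x), failed)
  design <- x$design
  if (!is.null(design)) {
    design <- design[design$sample_id %in% keep, , drop = FALSE]
    sizes <- table(design$group)
    if (any(sizes < 2)) {
      small <- names(sizes)[sizes < 2]
      stop("dropping failed chip(s) would leave group(s) with < 2 samples: ",
           paste(small, collapse = ", "), call. = FALSE)
    }
  }
  message("dropping failed chip(s): ", paste(failed, collapse = ", "))
  out <- expression_matrix(x$values[, keep, drop = FALSE], is_log = x$is_log)
  if (!is.null(design)) out <- join_design(out, design)
  out
}

#' Baseline-to-median normalization
#'
#' Per-probe median centering on the log2 scale: each probe's log2 signal has
#' the median over all samples subtracted, so every row's median is exactly
#' zero. Linear input is log2-transformed first; input already on the log2
#' scale is centered as is.
#'
#' @param x An `expression_matrix`. Linear-scale values must be strictly
#'   positive (the log is undefined otherwise).
#' @return A log2-scale `expression_matrix` with per-probe median zero.
#' @export
baseline_to_median <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (!x$is_log) {
    if (any(v <= 0)) {
      bad <- probe_ids(x)[which(rowSums(v <= 0) > 0)[1]]
      stop("zero or negative linear signal (log2 undefined) at probe ", sQuote(bad),
           call. = FALSE)
    }
    v <- log2(v)
  }
  med <- apply(v, 1, stats::median)
  expression_matrix(v - med, is_log = TRUE, design = x$design)
}
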