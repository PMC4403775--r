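#' Pipeline configuration
#'
#' Defaults reproduce the study's stated settings: family-wise error rate
#' 0.90 for the ANOVA gate, a 5-fold volcano threshold, a 2-fold
#' revert-to-control band, five treatment groups, and control-probe QC at
#' rank-correlation 0.8.
#'
#' @param fwer Family-wise error rate for the Sidak-gated screen.
#' @param m Number of tests for the Sidak correction; `NULL` uses the number
#'   of probes after QC.
#' @param control_prefix,min_correlation Control-probe QC settings.
#' @param run_qc Set `FALSE` to skip chip QC.
#' @param fold_threshold Volcano fold threshold.
#' @param revert_band Revert-to-control band.
#' @param cluster_k Clusters for the robustness check; `NULL` uses the number
#'   of treatment groups.
#' @param lda_genes Optional character vector of probes for the discriminant
#'   stage; `NULL` uses the ANOVA passes.
#' @param lda_drop Probes to drop before the discriminant fit (the escape
#'   hatch from a singular within-group covariance).
#' @param anova_on_normalized Screen on the normalized log2 matrix (default)
#'   or on raw linear signals.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fwer = 0.90, m = NULL,
                            control_prefix = "AFFX", min_correlation = 0.8,
                            run_qc = TRUE,
                            fold_threshold = 5, revert_band = 2,
                            cluster_k = NULL,
                            lda_genes = NULL, lda_drop = character(0),
                            anova_on_normalized = TRUE) {
  structure(list(fwer = fwer, m = m, control_prefix = control_prefix,
                 min_correlation = min_correlation, run_qc = run_qc,
                 fold_threshold = fold_threshold, revert_band = revert_band,
                 cluster_k = cluster_k, lda_genes = lda_genes,
                 lda_drop = lda_drop,
                 anova_on_normalized = anova_on_normalized),
            class = "pipeline_config")
}

#' Run the whole screening pipeline
#'
#' Stages run in order: chip QC on control probes, removal of failed chips,
#' baseline-to-median normalization, the Sidak-gated ANOVA screen, the
#' canonical discriminant fit with territorial-map boundaries (skipped with a
#' note when the screened gene set is unusable for the design), the
#' three-scheme clustering robustness check on the screened genes, linear
#' fold changes with volcano screening, and the revert-to-control
#' specificity calls. When `outdir` is given every stage's table is written
#' as TSV together with a manifest.
#'
#' @param x An `expression_matrix` with design attached (e.g.
#'   `simulate_predation()$matrix`, or [read_expression_matrix()] +
#'   [join_design()]).
#' @param config A [pipeline_config()].
#' @param outdir Optional directory for TSV artifacts.
#' @return A list with `qc`, `matrix` (post-QC linear matrix), `normalized`,
#'   `screen`, `alpha`, `cda` (or `NULL`), `boundaries` (or `NULL`),
#'   `robustness`, `fold_change`, `screened_sets`, `specificity`, `manifest`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(x, "expression_matrix"), inherits(config, "pipeline_config"))
  if (is.null(x$design)) stop("pipeline input needs a design; call join_design()",
                              call. = FALSE)
  artifacts <- list()

  qc <- NULL
  if (config$run_qc) {
    qc <- qc_control_probes(x, config$control_prefix, config$min_correlation)
    x <- drop_failed(x, qc)
    artifacts$qc_report <- qc
  }
  normalized <- baseline_to_median(x)

  screen_input <- if (config$anova_on_normalized) normalized else x
  screen <- screen_probes(screen_input, fwer = config$fwer, m = config$m)
  artifacts$screen <- screen
  alpha <- screen$alpha[1]

  genes <- config$lda_genes
  if (is.null(genes)) genes <- screen$probe_id[screen$pass]
  genes <- setdiff(genes, config$lda_drop)
  cda <- NULL
  boundaries <- NULL
  robustness <- NULL
  groups <- group_factor(normalized)
  k <- config$cluster_k
  if (is.null(k)) k <- nlevels(groups)
  if (length(genes) >= 2) {
    prof <- t(normalized$values[genes, , drop = FALSE])
    max_p <- max_usable_variables(nrow(prof), nlevels(groups))
    if (length(genes) <= max_p) {
      cda <- fit_cda(prof, groups)
      if (length(cda$eigenvalues) >= 2) {
        boundaries <- boundary_lines(cda)
        artifacts$boundaries <- boundaries
      }
      artifacts$cda_functions <- tidy(cda)
    } else {
      message(sprintf(paste0("discriminant stage skipped: %d screened genes ",
                             "exceed the maximum usable %d for this design; ",
                             "pass `lda_genes`/`lda_drop` to choose a subset"),
                      length(genes), max_p))
    }
    robustness <- robustness_check(prof, k = min(k, nrow(prof)))
  }

  fc <- fold_change(x)
  screened <- volcano_screen(fc, config$fold_threshold)
  calls <- classify_specificity(fc, screened, config$revert_band)
  artifacts$fold_change <- fc
  artifacts$specificity <- calls

  manifest <- tibble::tibble(
    artifact = names(artifacts),
    rows = vapply(artifacts, nrow, integer(1))
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(artifacts)) {
      readr::write_tsv(artifacts[[nm]], file.path(outdir, paste0(nm, ".tsv")))
    }
    readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  }
  list(qc = qc, matrix = x, normalized = normalized, screen = screen,
       alpha = alpha, cda = cda, boundaries = boundaries,
       robustness = robustness, fold_change = fc, screened_sets = screened,
       specificity = calls, manifest = manifest)
}
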