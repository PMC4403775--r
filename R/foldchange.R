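#' Signed fold changes of each treatment versus control
#'
#' For every probe and every non-control group the ratio of group mean signal
#' to control mean signal is computed on the linear scale and reported in the
#' signed convention: a ratio `r >= 1` is reported as `r` ("up"); a ratio
#' `r < 1` is reported as `-1/r` ("down"), so e.g. a ratio of 0.302 appears
#' as -3.31. `|FC|` is therefore always at least 1, and `FC = +1` exactly
#' when the means are equal.
#'
#' @param x An `expression_matrix` with design attached. Must hold
#'   linear-scale signals (fold changes are ratios of signal means, not of
#'   log values); a log2-scale matrix is an error.
#' @param control Control group label (default `"Cont"`).
#' @return A tibble with one row per probe per treatment: `probe_id`,
#'   `treatment`, `mean_treatment`, `mean_control`, `ratio`, `fold_change`
#'   (signed), `direction` (`"up"`/`"down"`).
#' @export
fold_change <- function(x, control = "Cont") {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$is_log) {
    stop("fold changes are ratios of linear signal means; got a log2 matrix",
         call. = FALSE)
  }
  groups <- group_factor(x)
  if (!control %in% levels(groups)) {
    stop("control group ", sQuote(control), " not present in design", call. = FALSE)
  }
  if (sum(groups == control) < 2) {
    stop("control group needs at least 2 samples", call. = FALSE)
  }
  n_g <- as.vector(table(groups))
  ind <- vapply(levels(groups), function(l) as.numeric(groups == l),
                numeric(ncol(x$values)))
  gmean <- sweep(x$values %*% ind, 2, n_g, "/")
  ctrl <- gmean[, control]
  if (any(ctrl == 0)) {
    bad <- probe_ids(x)[which(ctrl == 0)[1]]
    stop("control mean is zero for probe ", sQuote(bad),
         "; fold change undefined", call. = FALSE)
  }
  treatments <- setdiff(levels(groups), control)
  purrr::map_dfr(treatments, function(tr) {
    r <- unname(gmean[, tr] / ctrl)
    tibble::tibble(
      probe_id = probe_ids(x),
      treatment = tr,
      mean_treatment = unname(gmean[, tr]),
      mean_control = unname(ctrl),
      ratio = r,
      fold_change = signed_fold_change(r),
      direction = ifelse(r >= 1, "up", "down")
    )
  })
}

#' Signed fold-change convention
#'
#' @param r Positive mean ratio(s).
#' @return `r` where `r >= 1`, `-1/r` otherwise.
#' @export
#' @examples
#' signed_fold_change(c(0.302, 1, 8.46))
signed_fold_change <- function(r) {
  if (any(r <= 0)) stop("ratios must be positive", call. = FALSE)
  ifelse(r >= 1, r, -1 / r)
}

#' Volcano screening at a fold-change threshold
#'
#' A probe enters a treatment's screened set when its absolute signed fold
#' change strictly exceeds the threshold ("more than" the threshold, so a
#' probe exactly at it is excluded). The predator sets are keyed on the
#' continuous-exposure groups: the dragonfly set on `Drago`, the salamander
#' set on `Salam`.
#'
#' @param fc Fold-change tibble from [fold_change()].
#' @param threshold Fold threshold, `>= 1` (default 5).
#' @return A list: `sets` (named list of probe-ID character vectors, one per
#'   treatment present in `fc`), plus `threshold`.
#' @export
volcano_screen <- function(fc, threshold = 5) {
  if (!is.numeric(threshold) || threshold < 1) {
    stop("`threshold` must be >= 1", call. = FALSE)
  }
  sets <- fc |>
    dplyr::filter(abs(.data$fold_change) > threshold) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(probes = list(.data$probe_id), .groups = "drop")
  out <- stats::setNames(sets$probes, sets$treatment)
  for (tr in setdiff(unique(fc$treatment), names(out))) out[[tr]] <- character(0)
  list(sets = out, threshold = threshold)
}

#' Predator-specificity calls via the revert-to-control rule
#'
#' A gene responsive to a predator (in that predator's screened set) whose
#' expression returns to the control level after the predator is removed
#' (absolute fold change in the removal group within `revert_band`) is called
#' specific to that predator — unless it also responds to the other predator.
#' Genes in both screened sets are `common`. Genes screened for one predator
#' that neither revert nor are common are `responsive_nonreverting`; all
#' remaining probes are `not_responsive`.
#'
#' @param fc Fold-change tibble from [fold_change()] (must contain treatments
#'   `Drago`, `Salam`, `MinusDrago`, `MinusSalam`).
#' @param screened Result of [volcano_screen()] on the same table.
#' @param revert_band No-change band, `>= 1` (default 2): a removal-group
#'   `|FC| <= revert_band` counts as returned to control.
#' @return A tibble, one row per probe: `probe_id`, `label`, and the evidence
#'   columns `fc_drago`, `fc_minus_drago`, `fc_salam`, `fc_minus_salam`,
#'   `in_dragonfly_set`, `in_salamander_set`, `reverts_drago`,
#'   `reverts_salam`.
#' @export
classify_specificity <- function(fc, screened, revert_band = 2) {
  if (!is.numeric(revert_band) || revert_band < 1) {
    stop("`revert_band` must be >= 1", call. = FALSE)
  }
  need <- c("Drago", "Salam", "MinusDrago", "MinusSalam")
  have <- unique(fc$treatment)
  if (!all(need %in% have)) {
    stop("fold-change table lacks treatment(s): ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  }
  wide <- fc |>
    dplyr::select("probe_id", "treatment", "fold_change") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "fold_change")
  evidence <- wide |>
    dplyr::transmute(
      probe_id = .data$probe_id,
      fc_drago = .data$Drago,
      fc_minus_drago = .data$MinusDrago,
      fc_salam = .data$Salam,
      fc_minus_salam = .data$MinusSalam,
      in_dragonfly_set = .data$probe_id %in% screened$sets[["Drago"]],
      in_salamander_set = .data$probe_id %in% screened$sets[["Salam"]],
      reverts_drago = abs(.data$MinusDrago) <= revert_band,
      reverts_salam = abs(.data$MinusSalam) <= revert_band
    )
  evidence |>
    dplyr::mutate(
      label = dplyr::case_when(
        in_dragonfly_set & in_salamander_set ~ "common",
        in_dragonfly_set & reverts_drago ~ "dragonfly_specific",
        in_salamander_set & reverts_salam ~ "salamander_specific",
        in_dragonfly_set | in_salamander_set ~ "responsive_nonreverting",
        TRUE ~ "not_responsive"
      ),
      .after = "probe_id"
    )
}

#' Count specificity labels
#'
#' @param calls Tibble from [classify_specificity()].
#' @return A tibble of `label`, `n`, including zero counts for absent labels.
#' @export
specificity_counts <- function(calls) {
  lv <- c("dragonfly_specific", "salamander_specific", "common",
          "responsive_nonreverting", "not_responsive")
  calls |>
    dplyr::count(label = factor(.data$label, levels = lv), .drop = FALSE) |>
    dplyr::mutate(label = as.character(.data$label))
}

#' Flag probes with an informative annotation
#'
#' The screening keeps only genes of known identity; a probe counts as known
#' when its annotation has a non-empty gene symbol that does not look like a
#' placeholder (LOC numbers, ESTs, hypothetical proteins).
#'
#' @param annotation Tibble from [read_annotation()].
#' @param unknown_pattern Regular expression matched (case-insensitively)
#'   against the gene symbol/title to flag placeholders.
#' @return The annotation with a logical `known` column added.
#' @export
flag_known_genes <- function(annotation,
                             unknown_pattern = "^(LOC[0-9]+|EST|MGC[0-9]+)$|hypothetical") {
  annotation |>
    dplyr::mutate(
      known = !is.na(.data$gene_symbol) & nzchar(.data$gene_symbol) &
        !grepl(unknown_pattern, .data$gene_symbol, ignore.case = TRUE) &
        !grepl("hypothetical", dplyr::coalesce(.data$gene_title, ""),
               ignore.case = TRUE)
    )
}

#' Volcano plot of a treatment's fold changes
#'
#' @param fc Fold-change tibble from [fold_change()].
#' @param screen Screen tibble from [screen_probes()] supplying the p-value
#'   axis (optional; without it the y axis is |log2 fold change| rank).
#' @param treatment Treatment to display (default `"Drago"`).
#' @param threshold Fold threshold drawn as vertical lines (default 5).
#' @return A ggplot object.
#' @export
plot_volcano <- function(fc, screen = NULL, treatment = "Drago", threshold = 5) {
  dat <- fc |>
    dplyr::filter(.data$treatment == !!treatment) |>
    dplyr::mutate(log2_ratio = log2(.data$ratio),
                  selected = abs(.data$fold_change) > threshold)
  if (!is.null(screen)) {
    dat <- dat |>
      dplyr::left_join(screen[c("probe_id", "p")], by = "probe_id") |>
      dplyr::mutate(y = -log10(.data$p))
    ylab <- "-log10 ANOVA p"
  } else {
    dat <- dat |> dplyr::mutate(y = abs(.data$log2_ratio))
    ylab <- "|log2 fold change|"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_ratio, y = .data$y,
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 (treatment mean / control mean)", y = ylab,
                  title = paste("Volcano screen:", group_display_name(treatment))) +
    ggplot2::theme_minimal()
}
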