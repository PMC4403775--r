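#' Treatment-group vocabulary
#'
#' The five treatment groups of the predator-exposure design: untreated
#' controls, eight-day continuous exposure to dragonfly larvae or larval
#' salamanders, and four-day exposure followed by four days of recovery after
#' removal of each predator. On-disk labels spell the removal groups
#' `MinusDrago` / `MinusSalam`; [group_display_name()] maps them to the
#' conventional minus-sign form.
#'
#' @format Character vector of the five valid group labels, in canonical order
#'   (control first).
#' @export
predation_groups <- c("Cont", "Drago", "Salam", "MinusDrago", "MinusSalam")

#' Display name for a treatment-group label
#'
#' @param group Character vector of group labels from [predation_groups].
#' @return Character vector with removal groups rendered as `-Drago` /
#'   `-Salam`.
#' @export
#' @examples
#' group_display_name(c("Cont", "MinusDrago"))
group_display_name <- function(group) {
  out <- as.character(group)
  out[out == "MinusDrago"] <- "-Drago"
  out[out == "MinusSalam"] <- "-Salam"
  out
}

#' Construct a probe-by-sample expression matrix
#'
#' The container every pipeline stage consumes: a numeric probes x samples
#' matrix of summarized signal values, a flag stating whether values are on
#' the log2 scale, and (optionally, after [join_design()]) the sample design.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Must have
#'   unique, non-empty rownames (probe IDs) and colnames (sample IDs). All
#'   values must be finite; linear-scale values must be non-negative.
#' @param is_log Logical flag; `TRUE` when `values` are log2-scale.
#' @param design Optional design tibble as returned by [read_design()],
#'   normally attached via [join_design()].
#' @return An `expression_matrix` object.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' expression_matrix(m)
expression_matrix <- function(values, is_log = FALSE, design = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (probes x samples)", call. = FALSE)
  }
  probe_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids) ||
      any(!nzchar(probe_ids)) || any(!nzchar(sample_ids))) {
    stop("`values` must have non-empty rownames (probes) and colnames (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    dups <- unique(probe_ids[duplicated(probe_ids)])
    stop("duplicate probe identifiers: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    dups <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample identifiers: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at probe '%s', sample '%s'",
                 probe_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  if (!is_log && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative linear-scale value at probe '%s', sample '%s'",
                 probe_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  if (!is.null(design)) {
    design <- validate_design(design)
    if (!setequal(design$sample_id, sample_ids) ||
        !identical(design$sample_id, sample_ids[match(design$sample_id, sample_ids)])) {
      # design must list exactly the matrix samples; order agreement is
      # enforced by join_design(), which reorders columns to design order
      missing <- setdiff(design$sample_id, sample_ids)
      if (length(missing)) {
        stop("design samples absent from matrix: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
    }
  }
  structure(
    list(values = values, is_log = isTRUE(is_log), design = design),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log) "log2" else "linear"))
  if (!is.null(x$design)) {
    sizes <- table(factor(x$design$group, levels = predation_groups))
    sizes <- sizes[sizes > 0]
    cat("  design: ", paste(sprintf("%s=%d", group_display_name(names(sizes)), sizes),
                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers
#'
#' @param x An `expression_matrix`.
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Long-format view of an expression matrix
#'
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per probe/sample cell (`probe_id`,
#'   `sample_id`, `signal`, plus `group` when a design is attached).
#' @method tidy expression_matrix
#' @export
tidy.expression_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$values, rownames = "probe_id") |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id", values_to = "signal")
  if (!is.null(x$design)) {
    out <- dplyr::left_join(out, x$design[c("sample_id", "group")], by = "sample_id")
  }
  out
}

validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop("design needs columns `sample_id` and `group`", call. = FALSE)
  }
  if (nrow(design) == 0) stop("no samples in design", call. = FALSE)
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  bad <- setdiff(unique(design$group), predation_groups)
  if (length(bad)) {
    stop("unknown group label(s) ", paste(sQuote(bad), collapse = ", "),
         "; valid labels: ", paste(predation_groups, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(design)) {
    design <- design |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(replicate = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  design[c("sample_id", "group", "replicate")]
}

#' Attach a design table to an expression matrix
#'
#' Restricts the matrix to the designed samples, reorders its columns to the
#' design order, and attaches the design. Matrix samples absent from the
#' design are dropped with a warning; a design sample missing from the matrix
#' is an error.
#'
#' @param x An `expression_matrix`.
#' @param design Design tibble (`sample_id`, `group`) as from [read_design()].
#' @return An `expression_matrix` restricted to the designed samples, columns
#'   in design order, with `$design` attached.
#' @export
join_design <- function(x, design) {
  stopifnot(inherits(x, "expression_matrix"))
  design <- validate_design(design)
  missing <- setdiff(design$sample_id, sample_ids(x))
  if (length(missing)) {
    stop("design sample(s) not present in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(sample_ids(x), design$sample_id)
  if (length(extra)) {
    warning("dropping ", length(extra), " sample(s) absent from design: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  expression_matrix(x$values[, design$sample_id, drop = FALSE],
                    is_log = x$is_log, design = design)
}

group_factor <- function(x) {
  if (is.null(x$design)) {
    stop("expression matrix has no design attached; call join_design() first",
         call. = FALSE)
  }
  factor(x$design$group, levels = intersect(predation_groups, x$design$group))
}
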