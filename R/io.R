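#' Read an expression matrix from disk
#'
#' Two dialects are supported. `"tsv"` is the canonical format: a
#' tab-delimited table whose header row holds sample IDs and whose first
#' column holds probe IDs. `"geo_series_matrix"` reads the GEO series-matrix
#' text dialect: metadata lines beginning with `!` are skipped, the data table
#' is delimited by `!series_matrix_table_begin` / `!series_matrix_table_end`,
#' and identifiers may be double-quoted.
#'
#' Missing or non-numeric cells are an error (the pipeline has no imputation
#' step); the error names the offending probe and sample.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"geo_series_matrix"`.
#' @param is_log Logical; declare whether the stored values are log2-scale.
#'   Deposited MAS5 matrices are typically linear, but the scale is a property
#'   of the upload, so the caller states it.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "geo_series_matrix"),
                                   is_log = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  if (dialect == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin\\s*$", lines)
    end <- grep("^!series_matrix_table_end\\s*$", lines)
    if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
      stop("malformed series-matrix file: table_begin/table_end markers not found",
           call. = FALSE)
    }
    lines <- lines[(begin + 1):(end - 1)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  unquote <- function(v) gsub('^"|"$', "", v)
  header <- unquote(fields[[1]])
  samples <- header[-1]
  n_col <- length(header)
  rows <- fields[-1]
  widths <- lengths(rows)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop(sprintf("row %d has %d fields, expected %d", bad + 1, widths[bad], n_col),
         call. = FALSE)
  }
  cells <- do.call(rbind, rows)
  probes <- unquote(cells[, 1])
  body <- unquote(cells[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value %s at probe '%s', sample '%s'",
                 sQuote(body[bad[1], bad[2]]), probes[bad[1]], samples[bad[2]]),
         call. = FALSE)
  }
  dimnames(vals) <- list(probes, samples)
  expression_matrix(vals, is_log = is_log)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression_matrix()]: values are written with full
#' precision so that a read of the written file reproduces the matrix
#' bit-exactly.
#'
#' @param x An `expression_matrix`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"geo_series_matrix"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "expression_matrix"))
  body <- format(x$values, digits = 17, trim = TRUE, scientific = TRUE)
  if (dialect == "tsv") {
    header <- paste(c("probe_id", sample_ids(x)), collapse = "\t")
    rows <- paste(probe_ids(x), apply(body, 1, paste, collapse = "\t"), sep = "\t")
    readr::write_lines(c(header, rows), path)
  } else {
    q <- function(v) paste0('"', v, '"')
    header <- paste(c(q("ID_REF"), q(sample_ids(x))), collapse = "\t")
    rows <- paste(q(probe_ids(x)), apply(body, 1, paste, collapse = "\t"), sep = "\t")
    readr::write_lines(c("!Series_title\t\"expression matrix export\"",
                         "!series_matrix_table_begin", header, rows,
                         "!series_matrix_table_end"), path)
  }
  invisible(path)
}

#' Read a sample design table
#'
#' A two-column delimited table (`sample_id`, `group`); group labels are
#' validated against the five-label treatment vocabulary (Cont, Drago, Salam,
#' MinusDrago, MinusSalam).
#'
#' @param path Path to a TSV/CSV file with columns `sample_id` and `group`.
#' @return A tibble with columns `sample_id`, `group`, `replicate`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) stop("no samples: design file is empty", call. = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(tab) == 0) stop("no samples: design file has a header but no rows",
                           call. = FALSE)
  validate_design(tab)
}

#' Read a probe annotation table
#'
#' @param path Path to a TSV/CSV with a `probe_id` column and any of
#'   `gene_symbol`, `gene_title`, `accession`. Unmapped probes (empty fields)
#'   are permitted.
#' @return A tibble with columns `probe_id`, `gene_symbol`, `gene_title`,
#'   `accession` (missing columns filled with `NA`).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!"probe_id" %in% names(tab)) {
    stop("annotation needs a `probe_id` column", call. = FALSE)
  }
  if (anyDuplicated(tab$probe_id)) stop("duplicate probe_id in annotation", call. = FALSE)
  for (col in c("gene_symbol", "gene_title", "accession")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab[c("probe_id", "gene_symbol", "gene_title", "accession")]
}
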