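# Expression tables are wide tibbles: a `feature_id` character column followed
# by one numeric column per sample, values on the log2 scale.

#' Read a tab-delimited expression matrix
#'
#' Reads a features x samples expression table: first column `feature_id`
#' (any header accepted, renamed on read), remaining columns one per sample,
#' numeric log2-scale values with `.` as the decimal separator.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @return A tibble with a `feature_id` column and one numeric column per
#'   sample, in file order.
#' @details Duplicate feature or sample identifiers, ragged rows and
#'   non-numeric body cells are errors naming the offending row or column.
#'   Empty cells and literal `NA` are read as missing; use
#'   [drop_incomplete_features()] before analysis.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2", "g1\t1.5\t2", "g2\t0\t-1"), tf)
#' read_expression(tf)
read_expression <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) abort("empty expression file")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_head <- length(cells[[1]])
  widths <- lengths(cells)
  if (any(widths != ncol_head)) {
    bad <- which(widths != ncol_head)[1]
    abort(sprintf(
      "ragged expression file: row %d has %d fields, header has %d",
      bad, widths[bad], ncol_head
    ))
  }
  sample_ids <- cells[[1]][-1]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf(
      "duplicated sample id in header: %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }
  body <- cells[-1]
  feature_ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(feature_ids)) {
    abort(sprintf(
      "duplicated feature id: %s",
      paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")
    ))
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    raw <- vapply(body, `[[`, character(1), j + 1)
    missing <- raw %in% c("", "NA")
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!missing & is.na(num))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric cell '%s' at feature '%s', sample '%s'",
        raw[bad[1]], feature_ids[bad[1]], sample_ids[j]
      ))
    }
    vals[, j] <- num
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- sample_ids
  dplyr::bind_cols(tibble::tibble(feature_id = feature_ids), out)
}

#' Write an expression table to TSV
#'
#' Values are written at full double precision so that a write/read
#' round trip reproduces them exactly.
#'
#' @param expr Expression tibble (see [read_expression()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects tab-separated columns `sample_id, age_days, replicate_id, group,
#' pair_id`; empty cells are allowed where a field does not apply (for a
#' time series, `group` and `pair_id`; for a paired cohort, `age_days` and
#' `replicate_id`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with those five columns (`age_days` numeric, the rest
#'   character).
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      age_days = readr::col_double(),
      replicate_id = readr::col_character(),
      group = readr::col_character(),
      pair_id = readr::col_character()
    )
  )
  if (anyDuplicated(meta$sample_id)) abort("duplicated sample_id in metadata")
  meta
}

#' Write sample metadata to TSV
#' @param meta Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV `probe_id<TAB>gene_id` (header optional, detected from the
#' first line). Each probe must map to exactly one gene.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("probe", first, ignore.case = TRUE)
  map <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("probe_id", "gene_id"),
    skip = 0, col_types = readr::cols(.default = readr::col_character())
  )
  names(map)[1:2] <- c("probe_id", "gene_id")
  if (anyDuplicated(map$probe_id)) {
    abort(sprintf(
      "probe mapped to more than one gene: %s",
      paste(unique(map$probe_id[duplicated(map$probe_id)]), collapse = ", ")
    ))
  }
  map[, c("probe_id", "gene_id")]
}

#' Read / write one-gene-per-line lists
#' @param path File path.
#' @return `read_gene_list()`: a character vector; `write_gene_list()`:
#'   `path`, invisibly.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  unique(x[nzchar(x)])
}

#' @rdname read_gene_list
#' @param genes Character vector of gene identifiers.
#' @export
write_gene_list <- function(genes, path) {
  readr::write_lines(genes, path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then one member per field.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors, with set
#'   descriptions in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) abort(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) abort("GMT sets must be named")
  descriptions <- descriptions %||% rep("", length(sets))
  lines <- mapply(
    function(nm, desc, members) paste(c(nm, desc, members), collapse = "\t"),
    names(sets), descriptions, sets
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Drop features with missing values
#'
#' Features carrying any missing value are removed before analysis; the count
#' removed is reported as a message.
#'
#' @param expr Expression tibble.
#' @return Filtered expression tibble.
#' @export
drop_incomplete_features <- function(expr) {
  validate_expression(expr, allow_na = TRUE)
  keep <- stats::complete.cases(expr)
  n_drop <- sum(!keep)
  if (n_drop > 0) inform(sprintf("dropped %d feature(s) with missing values", n_drop))
  expr[keep, , drop = FALSE]
}

# --- internal helpers --------------------------------------------------------

validate_expression <- function(expr, allow_na = FALSE) {
  if (!is.data.frame(expr)) abort("expression input must be a data frame")
  if (names(expr)[1] != "feature_id") abort("first column must be `feature_id`")
  if (ncol(expr) < 2) abort("expression table has no sample columns")
  if (anyDuplicated(expr$feature_id)) abort("duplicated feature_id")
  if (anyDuplicated(names(expr))) abort("duplicated sample id")
  num <- vapply(expr[-1], is.numeric, logical(1))
  if (!all(num)) abort(sprintf("non-numeric sample column: %s", names(expr)[-1][!num][1]))
  if (!allow_na) {
    vals <- as.matrix(expr[-1])
    if (any(!is.finite(vals))) abort("expression values must be finite; see drop_incomplete_features()")
  }
  invisible(expr)
}

# features x samples numeric matrix with dimnames
expr_matrix <- function(expr) {
  validate_expression(expr, allow_na = TRUE)
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$feature_id
  m
}

as_expression <- function(mat) {
  out <- tibble::as_tibble(as.data.frame(mat))
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(mat)), out)
}
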