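#' Expression matrices
#'
#' An expression matrix is a numeric matrix with probe sets (genes) as rows
#' and samples as columns; missing values are allowed.  `expression_matrix()`
#' validates a plain matrix and stamps the class; `read_expression_matrix()`
#' parses the tab-delimited export format common to microarray repositories
#' (header row of sample IDs, first column of probe-set IDs, `NA`/`na`/empty
#' cells for missing values).
#'
#' @param values numeric matrix with unique, non-empty rownames (probe IDs)
#'   and colnames (sample IDs).
#' @return An object of class `expression_matrix` (a numeric matrix).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    rmt_abort("`values` must be a numeric matrix", "rmtnet_malformed_input")
  probes <- rownames(values)
  samples <- colnames(values)
  if (is.null(probes) || is.null(samples))
    rmt_abort("expression matrix needs probe rownames and sample colnames",
              "rmtnet_malformed_input")
  if (anyDuplicated(probes))
    rmt_abort(sprintf("duplicate probe ID: %s",
                      probes[duplicated(probes)][1L]),
              "rmtnet_duplicate_identifier")
  if (anyDuplicated(samples))
    rmt_abort(sprintf("duplicate sample ID: %s",
                      samples[duplicated(samples)][1L]),
              "rmtnet_duplicate_identifier")
  if (any(is.infinite(values)))
    rmt_abort("expression values must be finite or missing",
              "rmtnet_malformed_input")
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @rdname expression_matrix
#' @param path path to a tab-delimited file: first row sample IDs, first
#'   column probe-set IDs.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path))
    rmt_abort(sprintf("file not found: %s", path), "rmtnet_io_error")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    rmt_abort("expression file needs a header row and at least one probe row",
              "rmtnet_malformed_input")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; pad to the tab count so trailing
  # missing cells survive
  n_fields <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  fields <- Map(function(f, w) c(f, rep("", w - length(f))),
                fields, n_fields)
  samples <- fields[[1L]]
  # tolerate an (empty or labelled) corner cell above the probe-ID column
  body <- fields[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L)
    rmt_abort("ragged rows: not all rows have the same number of fields",
              "rmtnet_malformed_input")
  if (widths[1L] == length(samples) + 1L) {
    # header has no corner cell
  } else if (widths[1L] == length(samples)) {
    samples <- samples[-1L]
  } else {
    rmt_abort("header width does not match data rows", "rmtnet_malformed_input")
  }
  probes <- vapply(body, `[[`, character(1L), 1L)
  cells <- lapply(body, function(f) f[-1L])
  parse_row <- function(f) {
    f <- trimws(f)
    miss <- f == "" | f == "NA" | f == "na"
    out <- suppressWarnings(as.numeric(f))
    if (any(is.na(out) & !miss))
      rmt_abort(sprintf("non-numeric cell: '%s'", f[is.na(out) & !miss][1L]),
                "rmtnet_malformed_input")
    out[miss] <- NA_real_
    out
  }
  values <- do.call(rbind, lapply(cells, parse_row))
  dimnames(values) <- list(probes, samples)
  expression_matrix(values)
}

#' @rdname expression_matrix
#' @param em an `expression_matrix`.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(em)), collapse = "\t"), con)
  body <- apply(unclass(em), 1L, function(v) {
    v <- ifelse(is.na(v), "NA", formatC(v, digits = 15, format = "g"))
    paste(v, collapse = "\t")
  })
  writeLines(paste(rownames(em), body, sep = "\t"), con)
  invisible(path)
}

#' Subset an expression matrix by probe and/or sample IDs
#'
#' Row and column order of the original matrix is preserved regardless of the
#' order in which IDs are requested; this keeps seeded perturbations
#' reproducible.
#'
#' @param em an `expression_matrix`.
#' @param probes,samples character vectors of IDs to keep, or `NULL` to keep
#'   all.
#' @return An `expression_matrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(em, probes = NULL, samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  keep_rows <- rownames(em)
  keep_cols <- colnames(em)
  if (!is.null(probes)) {
    unknown <- setdiff(probes, keep_rows)
    if (length(unknown))
      rmt_abort(sprintf("unknown probe ID: %s", unknown[1L]),
                "rmtnet_unknown_identifier")
    keep_rows <- keep_rows[keep_rows %in% probes]
  }
  if (!is.null(samples)) {
    unknown <- setdiff(samples, keep_cols)
    if (length(unknown))
      rmt_abort(sprintf("unknown sample ID: %s", unknown[1L]),
                "rmtnet_unknown_identifier")
    keep_cols <- keep_cols[keep_cols %in% samples]
  }
  values <- unclass(em)[keep_rows, keep_cols, drop = FALSE]
  expression_matrix(values)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}
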