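#' Read a DMET-style genotype table
#'
#' Parses the tabular layout exported by DMET Console: the first row holds
#' sample identifiers (first cell is a corner label such as `ProbeID`), each
#' subsequent row is one probe, and cells are diploid calls like `C/T` or
#' `NoCall`. Class labels come either from a second header line whose first
#' cell is `Class` (one label per sample), or from a two-column sidecar file
#' given as `class_file`. All cells are canonicalized on read; row and
#' column order are preserved.
#'
#' @param path Path to the genotype table.
#' @param dialect `"tsv"` or `"csv"`; default inferred from the file
#'   extension (`.csv` means csv, anything else tsv).
#' @param class_file Optional path to a two-column `sample_id<TAB>class`
#'   file (a `sample_id`/`class` header line is allowed and skipped).
#'   Required when the table has no `Class` line.
#' @return A [dmet_dataset].
#' @examples
#' tab <- system.file("extdata", "table1.tsv", package = "dmetr")
#' read_dmet(tab)
#' @export
read_dmet <- function(path, dialect = NULL, class_file = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "dmetr_io_error")
  }
  sep <- dialect_sep(dialect %||% infer_dialect(path))
  lines <- readr::read_lines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (!length(lines)) {
    abort("Empty file: no header row.", class = "dmetr_format_error")
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  if (n_col < 2) {
    abort("Header row must list at least one sample.",
          class = "dmetr_format_error")
  }
  samples <- header[-1]
  body_start <- 2L
  classes <- NULL
  if (length(fields) >= 2 && tolower(fields[[2]][1]) == "class") {
    check_row_width(fields[[2]], n_col, 2L)
    classes <- stats::setNames(fields[[2]][-1], samples)
    body_start <- 3L
  }
  if (is.null(classes)) {
    if (is.null(class_file)) {
      abort("No `Class` header line and no `class_file` given.",
            class = "dmetr_validation_error")
    }
    classes <- read_class_file(class_file)
    missing <- setdiff(samples, names(classes))
    if (length(missing)) {
      abort(paste0("Samples absent from class file: ",
                   paste(missing, collapse = ", ")),
            class = "dmetr_validation_error")
    }
    classes <- classes[samples]
  }
  body <- fields[seq_along(fields) >= body_start]
  for (i in seq_along(body)) {
    check_row_width(body[[i]], n_col, body_start + i - 1L)
  }
  probes <- vapply(body, `[[`, character(1), 1L)
  m <- matrix(NA_character_, length(body), length(samples),
              dimnames = list(probes, samples))
  for (i in seq_along(body)) m[i, ] <- body[[i]][-1]
  dmet_dataset(m, classes)
}

#' Write a dataset in DMET table layout
#'
#' Emits the sample header row, a `Class` label row, and one row per probe.
#' `read_dmet(write_dmet(x, path))` reproduces `x` exactly.
#'
#' @param x A [dmet_dataset].
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dmet <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- dialect_sep(dialect)
  rows <- c(
    paste(c("ProbeID", sample_ids(x)), collapse = sep),
    paste(c("Class", unname(x$classes)), collapse = sep),
    vapply(seq_len(nrow(x$calls)), function(i) {
      paste(c(probe_ids(x)[i], x$calls[i, ]), collapse = sep)
    }, character(1))
  )
  readr::write_lines(rows, path)
  invisible(path)
}

#' Read a sample-to-class sidecar file
#'
#' @param path Two-column delimited file `sample_id<TAB>class` (or comma
#'   separated); an optional header line `sample_id`, `class` is skipped.
#' @return Named character vector mapping sample ID to class.
#' @export
read_class_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "dmetr_io_error")
  }
  sep <- dialect_sep(infer_dialect(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1]][1]), "sample_id")) {
    fields <- fields[-1]
  }
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    abort(sprintf("Class file line %d does not have two fields.", bad[1]),
          class = "dmetr_format_error")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort("Duplicate sample IDs in class file.",
          class = "dmetr_validation_error")
  }
  stats::setNames(vapply(fields, `[[`, character(1), 2L), ids)
}

infer_dialect <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
}

dialect_sep <- function(dialect) {
  switch(dialect, tsv = "\t", csv = ",",
         abort(paste0("Unknown dialect: ", dialect),
               class = "dmetr_configuration_error"))
}

check_row_width <- function(row, n_col, line_no) {
  if (length(row) != n_col) {
    abort(sprintf("Ragged row at line %d: %d fields, expected %d.",
                  line_no, length(row), n_col),
          class = "dmetr_format_error")
  }
  invisible(TRUE)
}
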