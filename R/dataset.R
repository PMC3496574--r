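#' Construct a DMET genotype dataset
#'
#' Container for a probes-by-samples matrix of canonical genotype calls plus
#' one class label per sample. This is the object every analysis step
#' consumes; build it from a file with [read_dmet()], from simulation with
#' [simulate_dmet()], or directly from a character matrix.
#'
#' @param calls Character matrix (probes in rows, samples in columns) with
#'   rownames = probe IDs and colnames = sample IDs. Cells are raw or
#'   canonical genotype strings; they are canonicalized on construction.
#' @param classes Named character vector mapping every sample ID to a class
#'   label, or a data frame with columns `sample_id` and `class`.
#' @return An object of class `dmet_dataset`: a list with elements `calls`
#'   (canonical character matrix) and `classes` (named character vector in
#'   sample column order).
#' @examples
#' m <- matrix(c("C/C", "T/T", "C/T", "C/T"), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' d <- dmet_dataset(m, c(s1 = "case", s2 = "control"))
#' d
#' @export
dmet_dataset <- function(calls, classes) {
  if (!is.matrix(calls) || !is.character(calls)) {
    abort("`calls` must be a character matrix.", class = "dmetr_validation_error")
  }
  probe_ids <- rownames(calls)
  sample_ids <- colnames(calls)
  if (is.null(sample_ids) || (nrow(calls) > 0 && is.null(probe_ids))) {
    abort("`calls` must have probe rownames and sample colnames.",
          class = "dmetr_validation_error")
  }
  if (anyDuplicated(probe_ids)) {
    abort(paste0("Duplicate probe IDs: ",
                 paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", ")),
          class = "dmetr_validation_error")
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample IDs: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
          class = "dmetr_validation_error")
  }
  if (is.data.frame(classes)) {
    classes <- stats::setNames(as.character(classes$class),
                               as.character(classes$sample_id))
  }
  missing <- setdiff(sample_ids, names(classes))
  if (length(missing)) {
    abort(paste0("Samples without a class label: ",
                 paste(missing, collapse = ", ")),
          class = "dmetr_validation_error")
  }
  classes <- classes[sample_ids]
  if (length(calls)) {
    ctx <- paste0("probe ", rep(probe_ids, times = ncol(calls)),
                  ", sample ", rep(sample_ids, each = nrow(calls)))
    calls[] <- canonicalize_genotype(calls, context = ctx)
  }
  structure(list(calls = calls, classes = classes), class = "dmet_dataset")
}

#' @export
print.dmet_dataset <- function(x, ...) {
  cat(sprintf("<dmet_dataset> %d probes x %d samples\n",
              nrow(x$calls), ncol(x$calls)))
  tab <- table(x$classes)
  cat("classes:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                        collapse = ", "), "\n")
  if (nrow(x$calls)) {
    show <- x$calls[seq_len(min(4, nrow(x$calls))),
                    seq_len(min(6, ncol(x$calls))), drop = FALSE]
    print(show, quote = FALSE)
    if (nrow(x$calls) > 4 || ncol(x$calls) > 6) cat("...\n")
  }
  invisible(x)
}

#' Probe and sample accessors
#' @param x A `dmet_dataset`.
#' @return Character vector of IDs.
#' @export
probe_ids <- function(x) rownames(x$calls) %||% character()

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$calls)

#' @rdname probe_ids
#' @export
sample_classes <- function(x) x$classes

#' Restrict a dataset to a subset of probes
#'
#' @param x A `dmet_dataset`.
#' @param probes Character vector of probe IDs to keep, in the requested
#'   output order.
#' @return A `dmet_dataset` with only the requested probes.
#' @export
select_probes <- function(x, probes) {
  probes <- as.character(probes)
  missing <- setdiff(probes, probe_ids(x))
  if (length(missing)) {
    abort(paste0("Unknown probe IDs: ", paste(missing, collapse = ", ")),
          class = "dmetr_lookup_error")
  }
  dmet_dataset(x$calls[probes, , drop = FALSE], x$classes)
}

#' Long tidy view of a genotype dataset
#'
#' @param x A `dmet_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `probe_id`, `sample_id`,
#'   `genotype`, `class`.
#' @export
as_tibble.dmet_dataset <- function(x, ...) {
  tibble::tibble(
    probe_id = rep(probe_ids(x), times = ncol(x$calls)),
    sample_id = rep(sample_ids(x), each = nrow(x$calls)),
    genotype = as.vector(x$calls),
    class = rep(unname(x$classes), each = nrow(x$calls))
  )
}

#' Rebuild a dataset from its long tidy view
#'
#' Inverse of [as_tibble.dmet_dataset()]: pivots a long tibble with columns
#' `probe_id`, `sample_id`, `genotype`, `class` back into a `dmet_dataset`.
#' Probe and sample order follow first appearance.
#'
#' @param tbl Long-format data frame.
#' @return A `dmet_dataset`.
#' @export
as_dmet_dataset <- function(tbl) {
  probes <- unique(as.character(tbl$probe_id))
  samples <- unique(as.character(tbl$sample_id))
  m <- matrix(NA_character_, length(probes), length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(tbl$probe_id, probes), match(tbl$sample_id, samples))] <-
    tbl$genotype
  if (anyNA(m)) {
    abort("Long table does not cover every probe x sample cell.",
          class = "dmetr_validation_error")
  }
  cls <- tbl[!duplicated(tbl$sample_id), c("sample_id", "class")]
  dmet_dataset(m, stats::setNames(as.character(cls$class),
                                  as.character(cls$sample_id)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
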