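#' Integer-coded genotype heatmap matrix
#'
#' Encodes a genotype dataset as an integer matrix ready for heatmap
#' rendering: every genotype symbol observed anywhere in the dataset gets a
#' stable code 1..k (symbols in canonical allele order), `NoCall` is always
#' 0, and sample columns are grouped by class (classes in lexicographic
#' order, original sample order within a class). The legend makes the
#' coding a bijection, so [decode_heatmap()] reproduces the calls exactly.
#'
#' @param x A non-empty [dmet_dataset].
#' @return An object of class `dmet_coded`: list with `codes` (integer
#'   matrix, probe x sample dimnames), `legend` (tibble `code`, `symbol`,
#'   including the reserved `0 = NoCall` row) and `classes` (named vector
#'   in column order).
#' @export
encode_heatmap <- function(x) {
  if (nrow(x$calls) == 0 || ncol(x$calls) == 0) {
    abort("Cannot encode an empty dataset.", class = "dmetr_domain_error")
  }
  syms <- sort_genotypes(setdiff(unique(as.vector(x$calls)), nocall_token))
  ord <- order(unname(x$classes), method = "radix")
  calls <- x$calls[, ord, drop = FALSE]
  codes <- matrix(match(calls, syms), nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
  codes[is.na(codes)] <- 0L
  storage.mode(codes) <- "integer"
  structure(
    list(
      codes = codes,
      legend = tibble::tibble(code = c(0L, seq_along(syms)),
                              symbol = c(nocall_token, syms)),
      classes = x$classes[ord]
    ),
    class = "dmet_coded"
  )
}

#' @rdname encode_heatmap
#' @param coded A `dmet_coded` object.
#' @return `decode_heatmap()`: the [dmet_dataset] the coding represents
#'   (samples in the grouped class order).
#' @export
decode_heatmap <- function(coded) {
  stopifnot(inherits(coded, "dmet_coded"))
  lut <- stats::setNames(coded$legend$symbol, as.character(coded$legend$code))
  calls <- matrix(lut[as.character(coded$codes)],
                  nrow(coded$codes), ncol(coded$codes),
                  dimnames = dimnames(coded$codes))
  dmet_dataset(calls, coded$classes)
}

#' Per-probe genotype (or allele) frequency summary
#'
#' Within-class relative frequencies for every probe, the table behind the
#' frequency view of the analysis: NoCall cells are excluded from the
#' denominators, so frequencies per probe and class sum to 1 wherever the
#' class has at least one callable sample, and are `NA` (undefined) where
#' it has none. `by = "allele"` splits each diploid call into its two
#' alleles and reports per-allele frequencies instead.
#'
#' @param x A [dmet_dataset].
#' @param classes Character vector of class labels to summarise (default:
#'   all classes present).
#' @param by `"genotype"` (default) or `"allele"`.
#' @return A tibble `probe_id`, `class`, `symbol`, `count`, `n`, `freq`.
#' @export
frequency_summary <- function(x, classes = NULL, by = c("genotype", "allele")) {
  by <- match.arg(by)
  classes <- classes %||% sort(unique(unname(x$classes)), method = "radix")
  unknown <- setdiff(classes, x$classes)
  if (length(unknown)) {
    abort(paste0("Class not present in dataset: ",
                 paste(unknown, collapse = ", ")),
          class = "dmetr_configuration_error")
  }
  long <- as_tibble(x) |>
    dplyr::filter(.data$class %in% classes, .data$genotype != nocall_token)
  if (by == "allele") {
    long <- tibble::tibble(
      probe_id = rep(long$probe_id, 2),
      class = rep(long$class, 2),
      genotype = c(substr(long$genotype, 1, 1), substr(long$genotype, 3, 3))
    )
  }
  grid <- tidyr::expand_grid(probe_id = probe_ids(x), class = classes)
  counted <- long |>
    dplyr::count(.data$probe_id, .data$class, .data$genotype, name = "count") |>
    dplyr::group_by(.data$probe_id, .data$class) |>
    dplyr::mutate(n = sum(.data$count), freq = .data$count / .data$n) |>
    dplyr::ungroup()
  sym_order <- if (by == "allele") dmet_alleles else
    sort_genotypes(unique(counted$genotype))
  out <- grid |>
    dplyr::left_join(counted, by = c("probe_id", "class")) |>
    dplyr::rename(symbol = "genotype") |>
    dplyr::arrange(match(.data$probe_id, probe_ids(x)),
                   match(.data$class, classes),
                   match(.data$symbol, sym_order))
  out$n[is.na(out$n)] <- 0L
  out
}

#' Order an association results table for presentation
#'
#' @param results A `dmet_assoc` tibble (annotated or not).
#' @param sort `"p_value"` (raw p ascending, pre-filtered rows last, ties
#'   broken by probe ID then symbol) or `"probe_id"` (alphabetical).
#' @return The reordered tibble.
#' @export
render_results <- function(results, sort = c("p_value", "probe_id")) {
  sort <- match.arg(sort)
  sort_assoc(results, sort)
}

#' Write association results as TSV
#'
#' @param results A `dmet_assoc` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(tibble::as_tibble(unclass_assoc(results)), path,
                   progress = FALSE)
  invisible(path)
}

#' Write the coded heatmap matrix and its legend as TSV
#'
#' @param coded A `dmet_coded` object.
#' @param codes_path,legend_path Output paths for the integer matrix (with
#'   a `probe_id` first column and a `Class` header line mirroring the
#'   genotype table layout) and the code-to-symbol legend.
#' @return Invisibly, the two paths.
#' @export
write_heatmap <- function(coded, codes_path, legend_path) {
  rows <- c(
    paste(c("ProbeID", colnames(coded$codes)), collapse = "\t"),
    paste(c("Class", unname(coded$classes)), collapse = "\t"),
    vapply(seq_len(nrow(coded$codes)), function(i) {
      paste(c(rownames(coded$codes)[i], coded$codes[i, ]), collapse = "\t")
    }, character(1))
  )
  readr::write_lines(rows, codes_path)
  readr::write_tsv(coded$legend, legend_path, progress = FALSE)
  invisible(c(codes_path, legend_path))
}

#' Genotype heatmap
#'
#' ggplot2 tile plot of the integer-coded genotype matrix: samples grouped
#' by class on the x axis, probes on the y axis, one fill level per
#' genotype symbol (NoCall shown as grey).
#'
#' @param object A `dmet_coded` object (or a [dmet_dataset], which is
#'   encoded first).
#' @param max_probes Cap on the number of probes drawn (the first
#'   `max_probes` rows), keeping large matrices legible.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmet_coded <- function(object, max_probes = 100, ...) {
  codes <- object$codes[seq_len(min(nrow(object$codes), max_probes)), ,
                        drop = FALSE]
  lut <- stats::setNames(object$legend$symbol, as.character(object$legend$code))
  df <- tibble::tibble(
    probe_id = factor(rep(rownames(codes), times = ncol(codes)),
                      levels = rev(rownames(codes))),
    sample_id = factor(rep(colnames(codes), each = nrow(codes)),
                       levels = colnames(codes)),
    genotype = factor(lut[as.character(as.vector(codes))],
                      levels = object$legend$symbol)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$probe_id,
                                   fill = .data$genotype)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(drop = FALSE, na.value = "grey80") +
    ggplot2::labs(x = "sample (grouped by class)", y = "probe",
                  fill = "genotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @rdname autoplot.dmet_coded
#' @export
autoplot.dmet_dataset <- function(object, max_probes = 100, ...) {
  autoplot.dmet_coded(encode_heatmap(object), max_probes = max_probes, ...)
}

#' Volcano-style overview of an association scan
#'
#' @param object A `dmet_assoc` tibble.
#' @param alpha Significance level drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object: -log10 raw p-value per test, ordered by rank.
#' @export
autoplot.dmet_assoc <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(unclass_assoc(object)) |>
    dplyr::filter(!.data$prefiltered) |>
    dplyr::arrange(.data$p_raw) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = -log10(.data$p_raw))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "test rank", y = "-log10 raw p-value") +
    ggplot2::theme_minimal()
}
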