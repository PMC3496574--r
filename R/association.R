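#' Per-probe genotype contingency table for two classes
#'
#' Tabulates the canonical genotype symbols of one probe by sample class,
#' giving the 2xk table the association tests consume. Under the default
#' `"exclude"` policy NoCall cells are non-measurements and are dropped from
#' the table (their count per class is reported separately); under
#' `"as_category"` NoCall forms its own category.
#'
#' @param x A [dmet_dataset].
#' @param probe Probe ID.
#' @param class_a,class_b The two class labels to compare.
#' @param nocall_policy `"exclude"` (default) or `"as_category"`.
#' @return An object of class `dmet_contingency`: list with `probe_id`,
#'   `classes`, `categories` (canonical order), `counts` (2xk matrix, rows
#'   = classes), `n_excluded_nocall` (per class), and `degenerate` (TRUE
#'   when a class has no callable sample at this probe).
#' @examples
#' d <- read_dmet(system.file("extdata", "table1.tsv", package = "dmetr"))
#' build_contingency(d, "Probe1", "A", "B")
#' @export
build_contingency <- function(x, probe, class_a, class_b,
                              nocall_policy = c("exclude", "as_category")) {
  nocall_policy <- match.arg(nocall_policy)
  check_classes(x, class_a, class_b)
  if (!probe %in% probe_ids(x)) {
    abort(paste0("Unknown probe ID: ", probe), class = "dmetr_lookup_error")
  }
  calls <- x$calls[probe, ]
  cls <- unname(x$classes)
  out_counts <- out_excl <- NULL
  per_class <- lapply(c(class_a, class_b), function(cl) calls[cls == cl])
  nc <- vapply(per_class, function(v) sum(v == nocall_token), integer(1))
  if (nocall_policy == "exclude") {
    per_class <- lapply(per_class, function(v) v[v != nocall_token])
  }
  categories <- sort_genotypes(unique(unlist(per_class)))
  counts <- rbind(
    tabulate(factor(per_class[[1]], levels = categories), length(categories)),
    tabulate(factor(per_class[[2]], levels = categories), length(categories))
  )
  dimnames(counts) <- list(c(class_a, class_b), categories)
  degenerate <- any(rowSums(counts) == 0)
  if (degenerate && nocall_policy == "exclude") {
    warn(sprintf("Probe %s: a class has no callable sample; its table row is empty.",
                 probe))
  }
  structure(
    list(probe_id = probe, classes = c(class_a, class_b),
         categories = categories, counts = counts,
         n_excluded_nocall = stats::setNames(nc, c(class_a, class_b)),
         degenerate = degenerate),
    class = "dmet_contingency"
  )
}

#' @export
print.dmet_contingency <- function(x, ...) {
  cat(sprintf("<dmet_contingency> probe %s (%s vs %s)\n", x$probe_id,
              x$classes[1], x$classes[2]))
  print(x$counts)
  if (any(x$n_excluded_nocall > 0)) {
    cat("NoCall excluded:",
        paste(sprintf("%s=%d", names(x$n_excluded_nocall),
                      x$n_excluded_nocall), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Frequency-difference pre-filter
#'
#' The optional optimization that skips the exact test for probes whose
#' between-class genotype frequency profiles barely differ: a probe is
#' tested only when the largest absolute difference in within-class
#' relative genotype frequency exceeds `threshold`. A threshold of 0 keeps
#' every probe showing any difference at all. A probe whose table has an
#' empty class row has undefined frequencies and is marked untestable.
#'
#' @param contingency A `dmet_contingency` from [build_contingency()].
#' @param threshold Fraction in \[0, 1\].
#' @return `TRUE` (test the probe) or `FALSE`; when `FALSE` because a class
#'   row is empty, the result carries attribute `reason = "untestable"`.
#' @export
prefilter_probe <- function(contingency, threshold) {
  stopifnot(inherits(contingency, "dmet_contingency"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    abort("`threshold` must be a fraction in [0, 1].",
          class = "dmetr_domain_error")
  }
  rs <- rowSums(contingency$counts)
  if (any(rs == 0)) {
    return(structure(FALSE, reason = "untestable"))
  }
  freq <- contingency$counts / rs
  max(abs(freq[1, ] - freq[2, ])) > threshold
}

#' Bonferroni family-wise correction
#'
#' `min(1, m * p)` for each p-value, over an explicit universe of `m`
#' performed tests (which may exceed the length of `p`).
#'
#' @param p Vector of raw p-values in (0, 1].
#' @param m Number of tests in the correction universe; must be at least
#'   `length(p)`.
#' @return Adjusted p-values, input order preserved.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  check_pvalues(p)
  if (length(p) == 0) return(numeric())
  if (m < length(p)) {
    abort("`m` must be >= length(p).", class = "dmetr_domain_error")
  }
  p.adjust(p, method = "bonferroni", n = m)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values: for sorted p(1) <= ... <= p(m),
#' q(i) = min over j >= i of min(1, m p(j) / j), returned in input order.
#'
#' @param p Vector of raw p-values in (0, 1].
#' @return Adjusted values, input order preserved; empty input gives an
#'   empty vector.
#' @export
adjust_fdr <- function(p) {
  check_pvalues(p)
  if (length(p) == 0) return(numeric())
  p.adjust(p, method = "BH")
}

check_pvalues <- function(p) {
  if (length(p) && (any(is.na(p)) || any(p <= 0) || any(p > 1))) {
    abort("p-values must lie in (0, 1].", class = "dmetr_domain_error")
  }
  invisible(p)
}

#' Case-control association scan over all probes
#'
#' The analysis engine: for every probe, compares the genotype distribution
#' between two sample classes with an exact Fisher test. In `per_symbol`
#' mode (the default, matching how DMET-style findings are reported) each
#' genotype symbol observed at a probe gets its own 2x2 test of symbol vs
#' all other symbols against class; in `omnibus` mode each probe gets a
#' single exact 2xk test over its full genotype distribution. An optional
#' pre-filter skips probes whose between-class frequency difference does
#' not exceed a threshold; multiple-testing corrections are computed over
#' the number of tests actually performed.
#'
#' @param x A [dmet_dataset].
#' @param class_a,class_b The two class labels to compare (must differ and
#'   both be present).
#' @param mode `"per_symbol"` or `"omnibus"`.
#' @param correction Which adjusted p-value downstream reporting should
#'   treat as primary: `"none"`, `"bonferroni"` or `"fdr"`. All three
#'   columns are always computed.
#' @param prefilter `NULL` (disabled, the default: every probe is tested)
#'   or a frequency-difference threshold in \[0, 1\].
#' @param nocall_policy `"exclude"` or `"as_category"`; see
#'   [build_contingency()].
#' @param sort `"p_value"` (default; ties broken by probe ID then symbol)
#'   or `"probe_id"`.
#' @param max_tables Capacity bound for omnibus enumeration, passed to
#'   [fisher_exact_rxc()].
#' @return A tibble of class `dmet_assoc`, one row per test, with columns
#'   `probe_id`, `symbol` (genotype symbol, or `"omnibus"`), `categories`
#'   (comma-joined category labels of the tested table), `counts_a`,
#'   `counts_b` (comma-joined counts per category; in per-symbol mode the
#'   two categories are the symbol and the rest), `p_raw`, `p_bonferroni`,
#'   `p_fdr`, `prefiltered`. Pre-filtered probes are retained with
#'   `prefiltered = TRUE` and no p-values. Attributes record the options
#'   and the correction universe `m_tests`.
#' @examples
#' d <- read_dmet(system.file("extdata", "table1.tsv", package = "dmetr"))
#' dmet_analyze(d, "A", "B")
#' @export
dmet_analyze <- function(x, class_a, class_b,
                         mode = c("per_symbol", "omnibus"),
                         correction = c("none", "bonferroni", "fdr"),
                         prefilter = NULL,
                         nocall_policy = c("exclude", "as_category"),
                         sort = c("p_value", "probe_id"),
                         max_tables = 1e6) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  nocall_policy <- match.arg(nocall_policy)
  sort <- match.arg(sort)
  check_classes(x, class_a, class_b)
  if (nrow(x$calls) < 1) {
    abort("Dataset has no probes.", class = "dmetr_validation_error")
  }
  cnt <- genotype_count_table(x, class_a, class_b, nocall_policy)
  per_probe <- cnt |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      tot_a = sum(.data$count_a), tot_b = sum(.data$count_b),
      max_diff = if (sum(.data$count_a) == 0 || sum(.data$count_b) == 0) {
        NA_real_
      } else {
        max(abs(.data$count_a / sum(.data$count_a) -
                  .data$count_b / sum(.data$count_b)))
      },
      .groups = "drop"
    )
  if (is.null(prefilter)) {
    per_probe$tested <- TRUE
  } else {
    if (!is.numeric(prefilter) || prefilter < 0 || prefilter > 1) {
      abort("`prefilter` must be NULL or a fraction in [0, 1].",
            class = "dmetr_domain_error")
    }
    per_probe$tested <- !is.na(per_probe$max_diff) &
      per_probe$max_diff > prefilter
  }
  # a probe with no callable sample at all has no testable table
  per_probe$tested <- per_probe$tested & (per_probe$tot_a + per_probe$tot_b > 0)
  cnt <- dplyr::left_join(cnt, per_probe, by = "probe_id")

  if (mode == "per_symbol") {
    res <- cnt |>
      dplyr::transmute(
        probe_id = .data$probe_id,
        symbol = .data$genotype,
        categories = paste0(.data$genotype, ",rest"),
        counts_a = paste0(.data$count_a, ",", .data$tot_a - .data$count_a),
        counts_b = paste0(.data$count_b, ",", .data$tot_b - .data$count_b),
        a = .data$count_a, ra = .data$tot_a - .data$count_a,
        b = .data$count_b, rb = .data$tot_b - .data$count_b,
        tested = .data$tested
      )
    key <- paste(res$a, res$ra, res$b, res$rb, sep = ";")
    res$p_raw <- lookup_pvalues(
      key[res$tested],
      function(kk) {
        v <- as.numeric(strsplit(kk, ";", fixed = TRUE)[[1]])
        fisher_exact_2x2(matrix(v, 2, 2, byrow = TRUE))
      },
      res$tested, nrow(res)
    )
    res <- res[, c("probe_id", "symbol", "categories",
                   "counts_a", "counts_b", "tested", "p_raw")]
  } else {
    res <- cnt |>
      dplyr::group_by(.data$probe_id) |>
      dplyr::summarise(
        symbol = "omnibus",
        categories = paste(.data$genotype, collapse = ","),
        counts_a = paste(.data$count_a, collapse = ","),
        counts_b = paste(.data$count_b, collapse = ","),
        tested = .data$tested[1],
        .groups = "drop"
      )
    key <- paste(res$counts_a, res$counts_b, sep = ";")
    res$p_raw <- lookup_pvalues(
      key[res$tested],
      function(kk) {
        halves <- strsplit(kk, ";", fixed = TRUE)[[1]]
        a <- as.numeric(strsplit(halves[1], ",", fixed = TRUE)[[1]])
        b <- as.numeric(strsplit(halves[2], ",", fixed = TRUE)[[1]])
        fisher_exact_rxc(rbind(a, b), max_tables = max_tables)
      },
      res$tested, nrow(res)
    )
  }

  m_tests <- sum(res$tested)
  res$p_bonferroni <- NA_real_
  res$p_fdr <- NA_real_
  if (m_tests > 0) {
    res$p_bonferroni[res$tested] <-
      adjust_bonferroni(res$p_raw[res$tested], m = m_tests)
    res$p_fdr[res$tested] <- adjust_fdr(res$p_raw[res$tested])
  }
  res$prefiltered <- !res$tested
  res$tested <- NULL

  res <- sort_assoc(res, sort)
  structure(
    tibble::new_tibble(res, class = "dmet_assoc"),
    class_a = class_a, class_b = class_b, mode = mode,
    correction = correction, prefilter = prefilter,
    nocall_policy = nocall_policy, m_tests = m_tests
  )
}

# Per probe x genotype counts for the two classes, zero-filled, categories
# in canonical order within each probe.
genotype_count_table <- function(x, class_a, class_b, nocall_policy) {
  long <- as_tibble(x) |>
    dplyr::filter(.data$class %in% c(class_a, class_b))
  if (nocall_policy == "exclude") {
    long <- dplyr::filter(long, .data$genotype != nocall_token)
  }
  all_syms <- sort_genotypes(unique(long$genotype))
  counts <- long |>
    dplyr::count(.data$probe_id, .data$class, .data$genotype) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c(class_a, class_b)) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  empty_probes <- setdiff(probe_ids(x), counts$probe_id)
  if (length(empty_probes)) {
    filler <- tibble::tibble(probe_id = empty_probes, genotype = nocall_token)
    filler[[class_a]] <- 0L
    filler[[class_b]] <- 0L
    counts <- dplyr::bind_rows(counts, filler)
  }
  counts |>
    dplyr::transmute(
      probe_id = .data$probe_id,
      genotype = .data$genotype,
      count_a = .data[[class_a]],
      count_b = .data[[class_b]]
    ) |>
    dplyr::arrange(match(.data$probe_id, probe_ids(x)),
                   match(.data$genotype, all_syms))
}

# Evaluate an expensive scalar function once per distinct key.
lookup_pvalues <- function(keys, fn, tested, n_out) {
  out <- rep(NA_real_, n_out)
  if (length(keys)) {
    uk <- unique(keys)
    vals <- vapply(uk, fn, numeric(1))
    out[tested] <- vals[match(keys, uk)]
  }
  out
}

sort_assoc <- function(res, sort) {
  if (sort == "p_value") {
    res[order(res$p_raw, res$probe_id, res$symbol, na.last = TRUE,
              method = "radix"), ]
  } else {
    res[order(res$probe_id, res$symbol, method = "radix"), ]
  }
}

check_classes <- function(x, class_a, class_b) {
  if (identical(class_a, class_b)) {
    abort("`class_a` and `class_b` must differ.",
          class = "dmetr_configuration_error")
  }
  for (cl in c(class_a, class_b)) {
    if (!cl %in% x$classes) {
      abort(paste0("Class not present in dataset: ", cl),
            class = "dmetr_configuration_error")
    }
  }
  invisible(TRUE)
}

#' Tidy and summarise an association scan
#'
#' @param x A `dmet_assoc` tibble from [dmet_analyze()].
#' @param ... Unused.
#' @return `tidy()`: the result rows as a plain tibble. `glance()`: a
#'   one-row tibble summarising the scan (probes, tests performed,
#'   correction universe, pre-filtered count, minimum raw p, discoveries at
#'   alpha = 0.05 under the scan's primary correction).
#' @export
tidy.dmet_assoc <- function(x, ...) {
  tibble::as_tibble(unclass_assoc(x))
}

#' @rdname tidy.dmet_assoc
#' @export
glance.dmet_assoc <- function(x, ...) {
  corr <- attr(x, "correction")
  pcol <- switch(corr, none = x$p_raw, bonferroni = x$p_bonferroni,
                 fdr = x$p_fdr)
  tibble::tibble(
    n_probes = dplyr::n_distinct(x$probe_id),
    n_tests = attr(x, "m_tests"),
    n_prefiltered = sum(x$prefiltered),
    min_p_raw = if (any(!is.na(x$p_raw))) min(x$p_raw, na.rm = TRUE) else NA_real_,
    n_sig_05 = sum(pcol < 0.05, na.rm = TRUE),
    mode = attr(x, "mode"),
    correction = corr,
    class_a = attr(x, "class_a"),
    class_b = attr(x, "class_b")
  )
}

unclass_assoc <- function(x) {
  attrs <- c("class_a", "class_b", "mode", "correction", "prefilter",
             "nocall_policy", "m_tests")
  for (a in attrs) attr(x, a) <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
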