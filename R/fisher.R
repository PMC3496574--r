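#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional p-value: with all margins fixed, sums the
#' hypergeometric point probabilities of every 2x2 table whose probability
#' is less than or equal to the observed table's (the standard
#' "probability" definition of the two-sided test). Point probabilities are
#' compared with a relative tie tolerance of 1e-9 so that tables tied with
#' the observed one in exact arithmetic are included despite floating-point
#' rounding.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows = classes, columns = genotype category vs rest).
#' @return The two-sided p-value, in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)) # 1/3
#' @export
fisher_exact_2x2 <- function(table) {
  table <- check_count_table(table, ncol = 2)
  r1 <- sum(table[1, ])
  c1 <- sum(table[, 1])
  n <- sum(table)
  if (n < 1) abort("Table total must be >= 1.", class = "dmetr_domain_error")
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  a <- max(0, r1 - (n - c1)):min(r1, c1)
  log_num <- lchoose(c1, a) + lchoose(n - c1, r1 - a)
  log_obs <- log_num[a == table[1, 1]]
  keep <- log_num <= log_obs + log1p(1e-9)
  min(1, sum(exp(log_num[keep] - lchoose(n, r1))))
}

#' Exact conditional test for a 2xk table
#'
#' Omnibus extension of [fisher_exact_2x2()]: enumerates every 2xk table
#' with the observed row and column margins (multivariate hypergeometric
#' null) and sums the point probabilities less than or equal to the observed
#' table's, with the same 1e-9 relative tie tolerance. Reduces exactly to
#' the 2x2 test when k = 2; a single-category table (k = 1) has no freedom
#' and returns 1. Columns whose total count is zero carry no information and
#' are dropped before testing.
#'
#' @param table 2xk matrix of non-negative integer counts.
#' @param max_tables Enumeration capacity bound; if the number of candidate
#'   tables (product of column-margin + 1) exceeds it, a capacity error is
#'   raised suggesting the per-genotype 2x2 mode.
#' @return The exact p-value, in (0, 1].
#' @examples
#' fisher_exact_rxc(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)) # 1/3 again
#' @export
fisher_exact_rxc <- function(table, max_tables = 1e6) {
  table <- check_count_table(table, ncol = NULL)
  table <- table[, colSums(table) > 0, drop = FALSE]
  n <- sum(table)
  if (n < 1) abort("Table total must be >= 1.", class = "dmetr_domain_error")
  k <- ncol(table)
  r1 <- sum(table[1, ])
  if (k <= 1 || r1 == 0 || r1 == n) return(1)
  cs <- colSums(table)
  if (prod(cs + 1) > max_tables) {
    abort(sprintf(
      "2x%d enumeration would visit > %g tables; use the per-genotype (per_symbol) mode instead.",
      k, max_tables
    ), class = "dmetr_capacity_error")
  }
  # enumerate first-row fill vectors a with 0 <= a_j <= cs_j, sum(a) = r1
  rows <- matrix(0L, 1, 0)
  sums <- 0L
  for (j in seq_len(k - 1)) {
    vals <- 0:cs[j]
    rows <- rows[rep(seq_len(nrow(rows)), each = length(vals)), , drop = FALSE]
    rows <- cbind(rows, rep(vals, times = nrow(rows) / length(vals)))
    sums <- rowSums(rows)
    tail_cap <- sum(cs[(j + 1):k])
    ok <- sums <= r1 & sums + tail_cap >= r1
    rows <- rows[ok, , drop = FALSE]
  }
  last <- r1 - rowSums(rows)
  rows <- cbind(rows, last)
  keep_valid <- last >= 0 & last <= cs[k]
  rows <- rows[keep_valid, , drop = FALSE]
  log_num <- rowSums(lchoose(matrix(cs, nrow(rows), k, byrow = TRUE), rows))
  obs_log <- sum(lchoose(cs, table[1, ]))
  keep <- log_num <= obs_log + log1p(1e-9)
  min(1, sum(exp(log_num[keep] - lchoose(n, r1))))
}

check_count_table <- function(table, ncol = 2) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (nrow(table) != 2 || (!is.null(ncol) && ncol(table) != ncol)) {
    abort(sprintf("Expected a 2x%s count table.", ncol %||% "k"),
          class = "dmetr_domain_error")
  }
  if (any(is.na(table)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-8)) {
    abort("Counts must be non-negative integers.",
          class = "dmetr_domain_error")
  }
  storage.mode(table) <- "double"
  round(table)
}
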