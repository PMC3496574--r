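# Independent exact oracles and code-built fixtures.
#
# The oracles recompute Fisher p-values by brute-force enumeration using
# only exact integer arithmetic: every hypergeometric point-probability
# numerator is an integer bounded by choose(n, r1) (<= choose(30, 15) ~
# 1.55e8 at the sizes tested), far below 2^53, so base-R choose() products,
# comparisons and sums are exact — equivalent to rational arithmetic with
# the common denominator choose(n, r1).

fisher_oracle_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  a <- max(0, r1 - (n - c1)):min(r1, c1)
  num <- choose(c1, a) * choose(n - c1, r1 - a)
  obs <- num[a == tab[1, 1]]
  sum(num[num <= obs]) / choose(n, r1)
}

fisher_oracle_2xk <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  cs <- colSums(tab); r1 <- sum(tab[1, ]); n <- sum(tab)
  if (ncol(tab) <= 1 || r1 == 0 || r1 == n) return(1)
  grid <- as.matrix(do.call(expand.grid, lapply(cs, function(cj) 0:cj)))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  num <- apply(grid, 1, function(a) prod(choose(cs, a)))
  obs <- prod(choose(cs, tab[1, ]))
  sum(num[num <= obs]) / choose(n, r1)
}

# brute-force Benjamini-Hochberg straight from the step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  q
}

# all 2x2 tables with total n between 1 and nmax
all_2x2_tables <- function(nmax) {
  g <- expand.grid(a = 0:nmax, b = 0:nmax, c = 0:nmax, d = 0:nmax)
  g <- g[rowSums(g) >= 1 & rowSums(g) <= nmax, ]
  lapply(seq_len(nrow(g)), function(i) {
    matrix(as.numeric(g[i, ]), 2, 2, byrow = TRUE)
  })
}

all_2x3_tables <- function(nmax) {
  g <- expand.grid(a = 0:nmax, b = 0:nmax, c = 0:nmax,
                   d = 0:nmax, e = 0:nmax, f = 0:nmax)
  g <- g[rowSums(g) >= 1 & rowSums(g) <= nmax, ]
  lapply(seq_len(nrow(g)), function(i) {
    matrix(as.numeric(g[i, ]), 2, 3, byrow = TRUE)
  })
}

# The worked four-probe, four-sample example dataset, built in code.
table1_dataset <- function() {
  m <- matrix(c(
    "C/C", "C/C", "T/T", "T/T",
    "G/C", "C/C", "-/T", "A/A",
    "C/T", "C/T", "C/T", "C/T",
    "G/G", "A/G", "G/G", "G/G"
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("Probe", 1:4), paste0("Subject", 1:4)))
  dmet_dataset(m, c(Subject1 = "A", Subject2 = "A",
                    Subject3 = "B", Subject4 = "B"))
}

table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "dmetr")
}

cli_path <- function() {
  system.file("cli", "dmet.R", package = "dmetr")
}

run_cli <- function(args) {
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(cli_path(), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
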