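test_that("contingency tables tabulate genotypes by class in canonical order", {
  d <- table1_dataset()
  ct1 <- build_contingency(d, "Probe1", "A", "B")
  expect_equal(ct1$categories, c("C/C", "T/T"))
  expect_equal(unname(ct1$counts), matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  ct3 <- build_contingency(d, "Probe3", "A", "B")
  expect_equal(ct3$categories, "C/T")
  expect_equal(unname(ct3$counts), matrix(c(2, 2), 2, 1))
  expect_error(build_contingency(d, "nope", "A", "B"),
               class = "dmetr_lookup_error")
})

test_that("NoCall policy controls exclusion vs its own category", {
  m <- matrix(c("C/C", "NoCall", "C/T", "C/T"), 1, 4,
              dimnames = list("P1", paste0("s", 1:4)))
  d <- dmet_dataset(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  ct <- build_contingency(d, "P1", "A", "B")
  expect_equal(rowSums(ct$counts), c(A = 1, B = 2))   # n_A - 1 after exclusion
  expect_equal(unname(ct$n_excluded_nocall), c(1L, 0L))
  ct2 <- build_contingency(d, "P1", "A", "B", nocall_policy = "as_category")
  expect_true(nocall_token %in% ct2$categories)
  expect_equal(rowSums(ct2$counts), c(A = 2, B = 2))
  # all-NoCall class is degenerate but representable
  m2 <- matrix(c("NoCall", "NoCall", "C/T", "C/C"), 1, 4,
               dimnames = list("P1", paste0("s", 1:4)))
  d2 <- dmet_dataset(m2, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  expect_warning(ct3 <- build_contingency(d2, "P1", "A", "B"),
                 "no callable")
  expect_true(ct3$degenerate)
})

test_that("the pre-filter keeps probes whose frequency profiles differ enough", {
  d <- table1_dataset()
  expect_true(prefilter_probe(build_contingency(d, "Probe1", "A", "B"), 0.5))
  expect_false(prefilter_probe(build_contingency(d, "Probe3", "A", "B"), 0))
  flat <- structure(list(probe_id = "x", classes = c("A", "B"),
                         categories = c("g1", "g2"),
                         counts = matrix(c(1, 1, 1, 1), 2, byrow = TRUE),
                         n_excluded_nocall = c(A = 0L, B = 0L),
                         degenerate = FALSE),
                    class = "dmet_contingency")
  expect_false(prefilter_probe(flat, 0))
  empty_row <- flat
  empty_row$counts <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  verdict <- prefilter_probe(empty_row, 0)
  expect_false(verdict)
  expect_equal(attr(verdict, "reason"), "untestable")
})

test_that("Bonferroni scales by the test universe and caps at 1", {
  expect_equal(adjust_bonferroni(1e-5, m = 1936), 0.01936)
  expect_equal(adjust_bonferroni(0.01, m = 1936), 1)
  expect_equal(adjust_bonferroni(0.2), 0.2)  # m = 1, single test
  expect_error(adjust_bonferroni(c(0.1, 0.2), m = 1),
               class = "dmetr_domain_error")
})

test_that("BH agrees with its step-up definition and ordering properties hold", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_identical(adjust_fdr(numeric()), numeric())
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    bh <- adjust_fdr(p)
    bonf <- adjust_bonferroni(p)
    expect_equal(bh, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh >= p - 1e-15) && all(bh <= 1))
    expect_true(all(bonf >= p - 1e-15) && all(bonf <= 1))
    expect_true(all(bh <= bonf + 1e-12))
    # both corrections preserve the raw ranking
    expect_equal(order(bh, p), order(p, p))
  }
})

test_that("the worked four-probe example analyzes as derived by enumeration", {
  d <- table1_dataset()
  res <- dmet_analyze(d, "A", "B", sort = "p_value")
  expect_s3_class(res, "dmet_assoc")
  # Probe1's perfectly separated genotypes lead the ranking at p = 1/3
  expect_equal(res$probe_id[1], "Probe1")
  p1 <- res[res$probe_id == "Probe1" & res$symbol == "C/C", ]
  expect_equal(p1$p_raw, 1 / 3, tolerance = 1e-9)
  # identically distributed Probe3 is uninformative
  p3 <- res[res$probe_id == "Probe3", ]
  expect_equal(p3$p_raw, 1)
  # and is pre-filtered at any threshold when the optimization is on
  res_f <- dmet_analyze(d, "A", "B", prefilter = 0)
  expect_true(res_f$prefiltered[res_f$probe_id == "Probe3"])
  expect_true(all(is.na(res_f$p_raw[res_f$prefiltered])))
  expect_false(any(res_f$prefiltered[res_f$probe_id == "Probe1"]))
})

test_that("corrections use the number of tests actually performed", {
  d <- table1_dataset()
  res <- dmet_analyze(d, "A", "B")
  m <- attr(res, "m_tests")
  expect_equal(m, sum(!res$prefiltered))
  tested <- !res$prefiltered
  expect_equal(res$p_bonferroni[tested],
               pmin(1, m * res$p_raw[tested]))
  res_f <- dmet_analyze(d, "A", "B", prefilter = 0.9)
  m_f <- attr(res_f, "m_tests")
  expect_lt(m_f, m)
  tested_f <- !res_f$prefiltered
  expect_equal(res_f$p_bonferroni[tested_f],
               pmin(1, m_f * res_f$p_raw[tested_f]))
})

test_that("omnibus mode tests the full genotype distribution once per probe", {
  d <- table1_dataset()
  res <- dmet_analyze(d, "A", "B", mode = "omnibus")
  expect_equal(nrow(res), 4)
  expect_true(all(res$symbol == "omnibus"))
  p1 <- res[res$probe_id == "Probe1", ]
  expect_equal(p1$p_raw, 1 / 3, tolerance = 1e-9)  # 2x2 table, same as per-symbol
  expect_equal(res$p_raw[res$probe_id == "Probe3"], 1)
  # cross-check a multi-category probe against the enumeration oracle
  p2 <- res[res$probe_id == "Probe2", ]
  tab <- rbind(as.numeric(strsplit(p2$counts_a, ",")[[1]]),
               as.numeric(strsplit(p2$counts_b, ",")[[1]]))
  expect_equal(p2$p_raw, fisher_oracle_2xk(tab), tolerance = 1e-9)
})

test_that("raising the pre-filter threshold never enlarges the tested set", {
  sim <- simulate_dmet(m_null = 120, m_assoc = 8, n_a = 10, n_b = 10,
                       separation = 0.6, nocall_rate = 0.05, seed = 3)
  tested_at <- function(thr) {
    res <- dmet_analyze(sim$dataset, "A", "B", prefilter = thr)
    unique(res$probe_id[!res$prefiltered])
  }
  sets <- lapply(c(0, 0.2, 0.4, 0.8), tested_at)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("probe order does not leak across probes", {
  sim <- simulate_dmet(m_null = 40, m_assoc = 2, n_a = 6, n_b = 6, seed = 9)
  d <- sim$dataset
  set.seed(1)
  perm <- sample(probe_ids(d))
  res1 <- dmet_analyze(d, "A", "B", sort = "probe_id")
  res2 <- dmet_analyze(select_probes(d, perm), "A", "B", sort = "probe_id")
  expect_equal(tidy(res1), tidy(res2))
})

test_that("configuration errors are raised for bad class selections", {
  d <- table1_dataset()
  expect_error(dmet_analyze(d, "A", "A"), class = "dmetr_configuration_error")
  expect_error(dmet_analyze(d, "A", "Z"), class = "dmetr_configuration_error")
})

test_that("tidy and glance summarise a scan", {
  d <- table1_dataset()
  res <- dmet_analyze(d, "A", "B", correction = "fdr")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "dmet_assoc"))
  g <- glance(res)
  expect_equal(g$n_probes, 4)
  expect_equal(g$n_tests, attr(res, "m_tests"))
  expect_equal(g$min_p_raw, 1 / 3, tolerance = 1e-9)
  expect_equal(g$correction, "fdr")
})
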