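test_that("heatmap coding is a bijection with NoCall reserved as zero", {
  m <- matrix(c("C/C", "NoCall", "T/T", "C/T",
                "G/C", "C/C", "-/T", "A/A"), 2, 4, byrow = TRUE,
              dimnames = list(c("P1", "P2"), paste0("s", 1:4)))
  d <- dmet_dataset(m, c(s1 = "B", s2 = "A", s3 = "B", s4 = "A"))
  coded <- encode_heatmap(d)
  expect_equal(coded$legend$symbol[coded$legend$code == 0], nocall_token)
  expect_equal(coded$legend$code, 0:(nrow(coded$legend) - 1))
  # legend symbols in canonical allele order, "-" allele first
  expect_equal(coded$legend$symbol[-1],
               sort_genotypes(setdiff(unique(as.vector(d$calls)), nocall_token)))
  expect_equal(unname(coded$codes["P1", "s2"]), 0L)
  # columns grouped by class, classes alphabetical, original order within
  expect_equal(colnames(coded$codes), c("s2", "s4", "s1", "s3"))
  back <- decode_heatmap(coded)
  expect_identical(back$calls, d$calls[, colnames(coded$codes)])
  expect_identical(unname(back$classes[sample_ids(d)]), unname(d$classes))
})

test_that("full-dataset encode/decode round-trips the worked example", {
  d <- table1_dataset()
  coded <- encode_heatmap(d)
  expect_equal(coded$legend$symbol,
               c(nocall_token, "-/T", "A/A", "A/G", "C/C", "C/G", "C/T",
                 "G/G", "T/T"))
  back <- decode_heatmap(coded)
  expect_identical(back$calls[, sample_ids(d)], d$calls)
  one <- dmet_dataset(matrix("C/C", 1, 1, dimnames = list("P", "s")),
                      c(s = "A"))
  c1 <- encode_heatmap(one)
  expect_equal(dim(c1$codes), c(1L, 1L))
  expect_equal(nrow(c1$legend), 2)  # NoCall + the single observed symbol
  empty <- dmet_dataset(matrix(character(), 0, 1,
                               dimnames = list(NULL, "s")), c(s = "A"))
  expect_error(encode_heatmap(empty), class = "dmetr_domain_error")
})

test_that("frequency summaries are within-class, NoCall-free and sum to one", {
  d <- table1_dataset()
  fs <- frequency_summary(d, classes = c("A", "B"))
  p1a <- fs[fs$probe_id == "Probe1" & fs$class == "A", ]
  expect_equal(p1a$symbol, "C/C")
  expect_equal(p1a$freq, 1)
  p1b <- fs[fs$probe_id == "Probe1" & fs$class == "B", ]
  expect_equal(p1b$symbol, "T/T")
  expect_equal(p1b$freq, 1)
  p3 <- fs[fs$probe_id == "Probe3", ]
  expect_equal(p3$freq, c(1, 1))
  sums <- fs |>
    dplyr::filter(!is.na(freq)) |>
    dplyr::group_by(probe_id, class) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # a half/half probe
  m <- matrix(c("C/C", "C/T", "T/T", "T/T"), 1, 4,
              dimnames = list("P1", paste0("s", 1:4)))
  dd <- dmet_dataset(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  f2 <- frequency_summary(dd, classes = c("A", "B"))
  expect_equal(f2$freq[f2$class == "A"], c(0.5, 0.5))
  # all-NoCall class at a probe reports undefined frequencies
  m2 <- matrix(c("NoCall", "NoCall", "C/C", "C/C"), 1, 4,
               dimnames = list("P1", paste0("s", 1:4)))
  d2 <- dmet_dataset(m2, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  f3 <- frequency_summary(d2, classes = c("A", "B"))
  expect_true(is.na(f3$freq[f3$class == "A"]))
  expect_equal(f3$n[f3$class == "A"], 0)
})

test_that("allele-level frequencies split diploid calls", {
  d <- table1_dataset()
  fa <- frequency_summary(d, classes = c("A", "B"), by = "allele")
  p1a <- fa[fa$probe_id == "Probe1" & fa$class == "A", ]
  expect_equal(p1a$symbol, "C")
  expect_equal(p1a$freq, 1)
  p3 <- fa[fa$probe_id == "Probe3" & fa$class == "A", ]
  expect_equal(p3$symbol, c("C", "T"))
  expect_equal(p3$freq, c(0.5, 0.5))
})

test_that("results render deterministically under both sort orders", {
  d <- table1_dataset()
  res <- dmet_analyze(d, "A", "B")
  by_p <- render_results(res, sort = "p_value")
  expect_equal(by_p$probe_id[1], "Probe1")
  by_id <- render_results(res, sort = "probe_id")
  expect_equal(by_id$probe_id, sort(by_id$probe_id))
  expect_error(render_results(res, sort = "banana"))
  # empty results render to an empty (header-only) table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res[0, ], path)
  expect_equal(length(readr::read_lines(path)), 1)
  write_results(by_p, path)
  reread <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(reread$probe_id, by_p$probe_id)
  expect_equal(reread$p_raw, by_p$p_raw, tolerance = 1e-12)
})

test_that("heatmap TSV export mirrors the coded matrix and legend", {
  d <- table1_dataset()
  coded <- encode_heatmap(d)
  codes_path <- withr::local_tempfile(fileext = ".tsv")
  legend_path <- withr::local_tempfile(fileext = ".tsv")
  write_heatmap(coded, codes_path, legend_path)
  lines <- readr::read_lines(codes_path)
  expect_equal(length(lines), 2 + nrow(coded$codes))
  expect_match(lines[2], "^Class\t")
  legend <- readr::read_tsv(legend_path, show_col_types = FALSE)
  expect_equal(legend$symbol, coded$legend$symbol)
})

test_that("autoplot returns ggplot objects for datasets and scans", {
  d <- table1_dataset()
  expect_s3_class(autoplot(d), "ggplot")
  expect_s3_class(autoplot(encode_heatmap(d)), "ggplot")
  expect_s3_class(autoplot(dmet_analyze(d, "A", "B")), "ggplot")
})
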