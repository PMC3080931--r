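test_that("expression_matrix validates its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  x <- expression_matrix(m, c(s1 = "treated", s2 = "control"))
  expect_s3_class(x, "mir_expr")
  expect_equal(dim(x), c(2L, 2L))

  dup <- m; rownames(dup) <- c("p1", "p1")
  expect_error(expression_matrix(dup, c("treated", "control")), "duplicate")
  expect_error(expression_matrix(m, c(s1 = "treated", s2 = "exposed")),
               "unknown group")
  expect_error(expression_matrix(m, c(s1 = "treated", s2 = "treated")),
               "non-empty")
  neg <- m; neg[2, 1] <- -1
  expect_error(expression_matrix(neg, c("treated", "control")),
               "probe 'p2', sample 's1'")
  expect_error(expression_matrix(m, c(s1 = "treated")), "no group label")
})

test_that("expression TSV write/read round trip is the identity", {
  vals <- matrix(abs(rnorm(12, 100, 40)), 4, 3,
                 dimnames = list(sprintf("probe-%d", 1:4), c("a", "b", "c")))
  x <- expression_matrix(vals, c(a = "treated", b = "control", c = "control"))
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, mp, sp, extra = "seed=1")
  y <- read_expression(mp, sp)
  expect_equal(y$values, x$values, tolerance = 1e-11)
  expect_identical(y$group, x$group)
  expect_identical(colnames(y$values), colnames(x$values))
  # provenance comment present and skipped by the reader
  expect_match(readLines(mp, n = 1), "^# mirperm")
})

test_that("expression reader reports row/column context on bad input", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "p1\t1\t2", "p2\tlow\t4"), mp)
  writeLines(c("sample_id\tgroup", "s1\ttreated", "s2\tcontrol"), sp)
  expect_error(read_expression(mp, sp), "column 's1'.*row 2.*'p2'")

  writeLines(c("probe_id\ts1\ts2", "p1\t1\t2"), mp)
  writeLines(c("sample_id\tgroup", "s1\ttreated"), sp)
  expect_error(read_expression(mp, sp), "missing matrix column\\(s\\): s2")
})

test_that("GMT reader filters to the universe and handles dialect quirks", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tzz1\tzz2",
               "setA\tdesc2\tg2"), gmt)
  expect_warning(
    expect_message(cc <- read_gene_sets(gmt, paste0("g", 1:5)), "dropped"),
    "duplicate gene set name 'setA'")
  expect_named(cc$sets, "setA")        # setB empty after filter -> dropped
  expect_identical(cc$sets$setA, "g2") # last definition wins
  writeLines(c("good\td\tg1", "bad_line_without_genes\td"), gmt)
  expect_error(read_gene_sets(gmt, paste0("g", 1:5)), "line 2")
})

test_that("GMT write/read round trip preserves sets", {
  sets <- list(alpha = c("g1", "g3"), beta = c("g2", "g4", "g5"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, gmt)
  cc <- read_gene_sets(gmt, paste0("g", 1:5))
  expect_identical(cc$sets, sets)
})

test_that("target table and assay series round trip with validation", {
  tt <- data.frame(mirna_id = c("m1", "m1", "m2"),
                   gene_id = c("g1", "g2", "g1"),
                   score = c(80.25, 10, 99.5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_target_table(tt, p)
  expect_equal(read_target_table(p), tt, tolerance = 1e-11)
  expect_error(validate_target_table(rbind(tt, tt[1, ])), "duplicate")
  bad <- tt; bad$score[1] <- 101
  expect_error(write_target_table(bad, p), "\\[0, 100\\]")

  ser <- data.frame(condition = rep(c("treated", "control"), each = 2),
                    replicate_id = paste0("r", 1:4),
                    value = c(1.5, 2.5, 3.5, 4.5))
  write_assay_series(ser, p)
  expect_equal(read_assay_series(p), ser, tolerance = 1e-11)
  bad <- ser; bad$condition[1] <- "mock"
  write_assay_series(bad, p)
  expect_error(read_assay_series(p), "unknown assay condition")
})

test_that("series-matrix reader parses the GEO text layout", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_series_matrix_fixture(p)
  x <- read_series_matrix(p, c(S1 = "treated", S2 = "control"))
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(unname(x$values["probe-1", ]), c(10.5, 12))  # quotes stripped
  expect_equal(unname(x$values["probe-2", "S2"]), 31.5)

  write_series_matrix_fixture(p, drop_end_marker = TRUE)
  expect_error(read_series_matrix(p, c(S1 = "treated", S2 = "control")),
               "table markers")
})

test_that("the bundled synthetic series-matrix example loads and filters", {
  f <- system.file("extdata", "synthetic_series_matrix.txt",
                   package = "mirperm", mustWork = TRUE)
  grp <- setNames(rep(c("treated", "control"), each = 3),
                  c("T1", "T2", "T3", "C1", "C2", "C3"))
  x <- read_series_matrix(f, grp)
  expect_equal(dim(x), c(4L, 6L))
  filt <- filter_background(x, 30)
  expect_false("probe-00003" %in% rownames(filt$expr$values))
  expect_equal(filt$report$n_retained_records, 3)
})
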