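test_that("expression reader round-trips a hand-written fixture and normalises symbols", {
  paths <- write_tiny_files()
  ds <- read_expression(paths$matrix, paths$labels)
  expect_equal(dim(ds), c(3L, 4L))
  expect_setequal(unique(ds$labels), c("case", "control"))
  # lowercase tp53 is uppercased
  expect_true("TP53" %in% rownames(ds$values))
  expect_equal(unname(ds$values["TP53", ]), c(1, 2, 3, 4))

  # write/read round trip
  dir <- withr::local_tempdir()
  write_expression(ds, file.path(dir, "m.tsv"), file.path(dir, "l.tsv"))
  ds2 <- read_expression(file.path(dir, "m.tsv"), file.path(dir, "l.tsv"))
  expect_equal(ds2$values, ds$values)
  expect_equal(ds2$labels, ds$labels)
})

test_that("expression reader rejects malformed input with informative errors", {
  dir <- withr::local_tempdir()
  lpath <- file.path(dir, "l.tsv")
  writeLines(c("s1\tcase", "s2\tcontrol"), lpath)

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("gene\ts1\ts2", "GLI2\t1\t2", "GLI2\t3\t4"), dup)
  expect_error(read_expression(dup, lpath), "GLI2")

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("gene\ts1\ts2", "TP53\t1\tx"), bad)
  expect_error(read_expression(bad, lpath), "row 1.*column 3|non-numeric")

  mism <- file.path(dir, "ok.tsv")
  writeLines(c("gene\ts1\ts2\ts3", "TP53\t1\t2\t3"), mism)
  expect_error(read_expression(mism, lpath), "missing")
})

test_that("GMT reader parses sets, deduplicates members, and flags bad lines", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("A\tdesc a\tg1\tg2\tg3", "B\tdesc b\tg4\tg4\tg5"), gmt)
  coll <- read_gmt(gmt)
  expect_equal(length(coll), 2L)
  expect_equal(vapply(coll$sets, length, 1L), c(A = 3L, B = 2L))
  expect_equal(coll$sets$B, c("G4", "G5"))  # dedup + uppercase

  bad <- file.path(dir, "bad.gmt")
  writeLines(c("A\tdesc\tg1", "NAME\tdesc"), bad)
  expect_error(read_gmt(bad), "line 2")
  dupnm <- file.path(dir, "dup.gmt")
  writeLines(c("A\td\tg1", "A\td\tg2"), dupnm)
  expect_error(read_gmt(dupnm), "duplicate")

  # round trip
  write_gmt(coll, file.path(dir, "rt.gmt"))
  coll2 <- read_gmt(file.path(dir, "rt.gmt"))
  expect_equal(coll2$sets, coll$sets)
})

test_that("regulon tables round-trip and validate mode/weight ranges", {
  regs <- regulon_set(rep(c("TF1", "TF2"), each = 3),
                      c("A", "B", "C", "D", "E", "F"),
                      c(0.8, -0.3, 0, 1, -1, 0.123456789012),
                      c(1, 0.5, 0.25, 1, 0.9, 0.0001))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "regs.tsv")
  write_regulon_table(regs, path)
  back <- read_regulon_table(path)
  expect_equal(nrow(back), 6L)
  expect_equal(back$mode, regs$mode, tolerance = 1e-9)
  expect_equal(back$weight, regs$weight, tolerance = 1e-9)
  expect_equal(back$tf, regs$tf)

  # empty set round-trips as a header-only file
  write_regulon_table(regulon_set(), path)
  expect_equal(nrow(read_regulon_table(path)), 0L)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("tf\ttarget\tmode\tweight", "TF1\tA\t1.5\t0.5"), bad)
  expect_error(read_regulon_table(bad), "mode")
  writeLines(c("tf\ttarget\tmode\tweight", "TF1\tA\t0.5\t0"), bad)
  expect_error(read_regulon_table(bad), "weight")
})

test_that("random small regulon sets survive a write/read cycle unchanged", {
  set.seed(7)
  dir <- withr::local_tempdir()
  for (rep in 1:10) {
    n <- sample(1:20, 1)
    tfs <- sample(sprintf("TF%02d", 1:5), n, replace = TRUE)
    tg <- sprintf("T%03d", sample(900, n))
    regs <- regulon_set(tfs, tg, runif(n, -1, 1), runif(n, 0.01, 1))
    path <- file.path(dir, "r.tsv")
    write_regulon_table(regs, path)
    back <- read_regulon_table(path)
    expect_equal(back$tf, regs$tf)
    expect_equal(back$target, regs$target)
    expect_equal(back$mode, regs$mode, tolerance = 1e-9)
    expect_equal(back$weight, regs$weight, tolerance = 1e-9)
  }
})

test_that("SIF export labels edges by mode sign with zero treated as activation", {
  regs <- regulon_set(c("TF1", "TF1", "TF1"), c("A", "B", "C"),
                      c(0.8, -0.3, 0), c(1, 0.5, 0.2))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "net.sif")
  export_sif(regs, path)
  lines <- readLines(path)
  expect_equal(sort(lines), sort(c("TF1\tactivates\tA",
                                   "TF1\trepresses\tB",
                                   "TF1\tactivates\tC")))
  export_sif(regulon_set(), path)
  expect_equal(length(readLines(path)), 0L)
})
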