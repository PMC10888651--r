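makeGct <- function(nr = 3, nc = 2, seed = 1) {
  set.seed(seed)
  mat <- matrix(round(rnorm(nr * nc), 4), nr, nc,
                dimnames = list(sprintf("g%02d", seq_len(nr)),
                                sprintf("s%02d", seq_len(nc))))
  GctMatrix(mat)
}

test_that("GCT 1.2 write/read round-trips ids, values and header lines", {
  m <- makeGct(3, 2)
  f <- withr::local_tempfile(fileext = ".gct")
  writeGct(m, f, dialect = "gct1.2")
  lines <- readLines(f)
  expect_identical(lines[1], "#1.2")
  expect_identical(lines[2], "3\t2")
  back <- readGct(f)
  expect_identical(dimnames(values2d(back)), dimnames(values2d(m)))
  expect_equal(values2d(back), values2d(m), tolerance = 1e-9)
  # write(read(f)) is byte-identical to f for a canonical fixture
  f2 <- withr::local_tempfile(fileext = ".gct")
  writeGct(back, f2, dialect = "gct1.2")
  expect_identical(readLines(f2), lines)
})

test_that("NaN values are written as NA and re-read as missing", {
  m <- makeGct(4, 3)
  mat <- values2d(m)
  mat[2, 2] <- NaN
  mat[4, 1] <- NA
  m <- GctMatrix(mat)
  for (d in c("gct1.2", "gct1.3", "tsv")) {
    f <- withr::local_tempfile()
    writeGct(m, f, dialect = d)
    expect_false(any(grepl("NaN", readLines(f))))
    back <- readGct(f, dialect = d)
    expect_true(is.na(values2d(back)[2, 2]))
    expect_true(is.na(values2d(back)[4, 1]))
  }
})

test_that("GCT 1.3 captures row and column metadata", {
  m <- GctMatrix(matrix(1:6 / 2, 3, 2,
                        dimnames = list(c("a", "b", "c"), c("x", "y"))),
                 rowMeta = data.frame(symbol = c("A1", "B1", "C1")),
                 colMeta = data.frame(cell = c("MCF7", "PC3"),
                                      dose = c(1.5, 2.5)))
  f <- withr::local_tempfile(fileext = ".gct")
  writeGct(m, f, dialect = "gct1.3")
  expect_identical(readLines(f)[1:2], c("#1.3", "3\t2\t1\t2"))
  back <- readGct(f)
  expect_identical(names(rowMeta(back)), "symbol")
  expect_identical(rowMeta(back)$symbol, c("A1", "B1", "C1"))
  expect_identical(colMeta(back)$cell, c("MCF7", "PC3"))
  expect_equal(colMeta(back)$dose, c(1.5, 2.5))
  expect_equal(values2d(back), values2d(m))
})

test_that("round-trip is losslessly canonical for generated matrices", {
  for (seed in 1:5) {
    m <- makeGct(7, 4, seed = seed)
    for (d in c("gct1.2", "gct1.3", "tsv")) {
      f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
      writeGct(m, f1, dialect = d)
      writeGct(readGct(f1, dialect = d), f2, dialect = d)
      expect_identical(readLines(f2), readLines(f1))
    }
  }
})

test_that("malformed GCT inputs are rejected with the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("#1.2", "oops\t2", "NAME\tDescription\ts1\ts2"), f)
  expect_error(readGct(f, dialect = "gct1.2"), "line 2")
  writeLines(c("#9.9", "2\t2"), f)
  expect_error(readGct(f, dialect = "gct1.2"), "line 1")
  # ragged data row
  writeLines(c("#1.2", "2\t2", "NAME\tDescription\ts1\ts2",
               "g1\tna\t1\t2", "g2\tna\t1"), f)
  expect_error(readGct(f), "line 5")
  # duplicate row ids
  writeLines(c("#1.2", "2\t2", "NAME\tDescription\ts1\ts2",
               "g1\tna\t1\t2", "g1\tna\t3\t4"), f)
  expect_error(readGct(f), "duplicate row id")
})

test_that("GMT reader parses, deduplicates and validates", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc one\tg1\tg2\tg3\tg4\tg5",
               "S2\tdesc two\tg1\tg1\tg2"), f)
  sets <- readGmt(f)
  expect_identical(length(sets), 2L)
  expect_identical(geneSets(sets)$S1, sprintf("g%d", 1:5))
  expect_identical(geneSets(sets)$S2, c("g1", "g2"))  # repeated member once
  # 12-line fixture -> 12 sets
  writeLines(sprintf("SET%02d\td\tg1\tg2", 1:12), f)
  expect_identical(length(readGmt(f)), 12L)
  # fewer than 3 fields is malformed
  writeLines(c("S1\tdesc\tg1", "S2\tonlydesc"), f)
  expect_error(readGmt(f), "line 2")
})

test_that("GMT write/read round-trips byte-identically", {
  sets <- GeneSetCollection(list(A = c("g1", "g2"), B = c("g9", "g3", "g2")),
                            descriptions = c("first", "second"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeGmt(sets, f1)
  writeGmt(readGmt(f1), f2)
  expect_identical(readLines(f2), readLines(f1))
})

test_that("metadata tables validate required columns and landmark flags", {
  f <- withr::local_tempfile(fileext = ".tsv")
  si <- data.frame(sig_id = c("s1", "s2"), pert_id = c("p1", "p2"),
                   pert_iname = c("a", "b"), pert_type = "trt_cp",
                   cell_id = c("MCF7", "PC3"))
  write.table(si, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readMetadataTable(f, requiredColumns = c("sig_id", "pert_id",
                                                  "pert_iname", "pert_type",
                                                  "cell_id"))
  expect_identical(nrow(tab), 2L)
  write.table(si[, setdiff(names(si), "cell_id")], f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readMetadataTable(f, requiredColumns = names(si)), "cell_id")
  gi <- data.frame(pr_gene_id = c("g1", "g2", "g3"), pr_is_lm = c(1, 0, 1),
                   pr_is_bing = c(1, 1, 0))
  write.table(gi, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readMetadataTable(f, requiredColumns = c("pr_gene_id", "pr_is_lm"))
  expect_identical(tab$pr_is_lm, c(TRUE, FALSE, TRUE))
  expect_identical(tab$pr_is_bing, c(TRUE, TRUE, FALSE))
})

test_that("compendium directory round-trips through write/read", {
  cmp <- simulateCompendium(nLandmark = 10, nNonlandmark = 20,
                            compounds = data.frame(pert_id = c("P1", "P2"),
                                                   pert_iname = c("a", "b")),
                            cellIds = "MCF7", profilesPerPair = 2, seed = 4)
  d <- withr::local_tempdir()
  writeCompendium(cmp$compendium, d)
  back <- readCompendium(d)
  expect_equal(zscores(back), zscores(cmp$compendium), tolerance = 1e-9)
  expect_identical(sigInfo(back)$pert_id, sigInfo(cmp$compendium)$pert_id)
  expect_identical(geneInfo(back)$pr_is_lm, geneInfo(cmp$compendium)$pr_is_lm)
})
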