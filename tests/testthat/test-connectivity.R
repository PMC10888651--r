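test_that("enrichment score matches hand-worked extreme and small cases", {
  ranking <- sprintf("g%02d", 1:10)
  expect_equal(esScore("g10", ranking), -1)          # single gene at the bottom
  expect_equal(esScore("g01", ranking), 0.9)         # single gene on top: 1 - 1/10
  expect_equal(esScore(c("g01", "g02"), ranking), 0.8)
  expect_error(esScore(character(), ranking), "non-empty")
  expect_error(esScore("zz", ranking), "absent")
})

test_that("enrichment score equals the brute-force a/b maxima and stays bounded", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(20:200, 1)
    ranking <- sample(sprintf("r%04d", 1:n))
    geneSet <- sample(ranking, sample(1:15, 1))
    es <- esScore(geneSet, ranking)
    expect_identical(es, bruteForceES(geneSet, ranking))
    expect_gte(es, -1)
    expect_lte(es, 1)
  }
})

test_that("reversing the ranking flips an extreme set between top and bottom", {
  set.seed(42)
  for (i in 1:20) {
    n <- 50
    ranking <- sample(sprintf("r%03d", 1:n))
    topSet <- ranking[1:5]
    expect_gt(esScore(topSet, ranking), 0)
    expect_lt(esScore(topSet, rev(ranking)), 0)
  }
})

test_that("WTCS combines opposite-sign scores and nulls same-sign pairs", {
  expect_equal(wtcs(1, -1), 1)
  expect_equal(wtcs(0.8, 0.5), 0)
  expect_equal(wtcs(0.8, -0.6), 0.7)
  expect_equal(wtcs(-0.4, 0.2), -0.3)
  expect_equal(wtcs(0, 0), 0)
})

test_that("NCS normalizes by same-sign mean magnitude within a cell line", {
  rec <- data.frame(cell_id = c("A", "A", "A", "B"),
                    wtcs = c(0.2, 0.4, -0.3, 0.5))
  out <- normalizeNcs(rec)
  expect_equal(out$ncs[1:2], c(2 / 3, 4 / 3))
  expect_equal(out$ncs[3], -1)   # lone negative record normalizes to -1
  expect_equal(out$ncs[4], 1)    # lone positive record in its own group
  allZero <- normalizeNcs(data.frame(cell_id = "A", wtcs = c(0, 0)))
  expect_equal(allZero$ncs, c(0, 0))
})

test_that("tau is the signed percentile of |NCS| in the reference bank", {
  bank <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  expect_equal(tauScore(2, bank), 100)
  expect_equal(tauScore(0.05, bank), 0)
  expect_equal(tauScore(0.75, bank), 70)   # exceeds exactly 7 of 10
  expect_equal(tauScore(-0.75, bank), -70)
  expect_error(tauScore(1, numeric()), "non-empty")
  # monotone in |ncs| for a fixed bank
  taus <- vapply(seq(0, 2, by = 0.1), tauScore, numeric(1), referenceNcs = bank)
  expect_true(all(diff(abs(taus)) >= 0))
})

test_that("a planted compound is recovered at connectivity rank 1", {
  for (seed in 1:3) {
    sc <- plantedScenario(seed, nLandmark = 150, nNonlandmark = 850,
                          nTags = 100)
    conn <- queryCompendium(sc$signature, sc$compendium)
    expect_identical(conn$pert_id[1], sc$planted)
    expect_true(all(abs(conn$tau) <= 100))
    expect_identical(conn$connected, abs(conn$tau) > 90)
  }
})

test_that("null compendia rarely flag connections", {
  frac <- vapply(1:10, function(seed) {
    cmp <- simulateCompendium(nLandmark = 100, nNonlandmark = 400,
      compounds = data.frame(pert_id = sprintf("P%02d", 1:50),
                             pert_iname = sprintf("c%02d", 1:50)),
      cellIds = "MCF7", profilesPerPair = 1, seed = seed)
    genes <- rownames(cmp$compendium)
    set.seed(seed + 500)
    tags <- sample(genes, 100)
    sig <- GeneSignature(upTags = tags[1:50], downTags = tags[51:100],
                         signatureId = "null_query")
    conn <- queryCompendium(sig, cmp$compendium)
    mean(tapply(conn$connected, conn$pert_id, any))
  }, numeric(1))
  expect_lte(mean(frac), 0.15)
})

test_that("queries with no overlapping tags are rejected, partial overlap logged", {
  cmp <- simulateCompendium(nLandmark = 20, nNonlandmark = 30,
                            profilesPerPair = 1, seed = 3)
  sig <- GeneSignature(upTags = c("absent1", "absent2"),
                       downTags = "absent3", signatureId = "qx")
  expect_error(suppressMessages(queryCompendium(sig, cmp$compendium)),
               "no signature tag overlaps")
  sigPartial <- GeneSignature(upTags = c("g00001", "absent1"),
                              downTags = "g00002", signatureId = "qy")
  expect_message(queryCompendium(sigPartial, cmp$compendium), "dropped")
})

test_that("topK keeps k rows by tau with deterministic tie-breaking", {
  tab <- data.frame(query_id = "q", sig_id = sprintf("s%02d", 1:50),
                    pert_id = sprintf("P%02d", 1:50),
                    pert_iname = sprintf("c%02d", 1:50),
                    cell_id = "A", es_up = 0, es_down = 0, wtcs = 0,
                    ncs = seq(1.5, 0.5, length.out = 50),
                    tau = c(rep(99, 2), seq(95, 0, length.out = 48)),
                    connected = FALSE)
  expect_identical(nrow(topK(tab)), 10L)          # default k = 10
  expect_identical(nrow(topK(tab[1:4, ], 10)), 4L)
  # tie on tau broken by |ncs| descending
  tie <- tab[1:2, ]
  tie$ncs <- c(0.7, 1.4)
  expect_identical(topK(tie, 1)$pert_id, "P02")
  expect_error(topK(tab, 0), "positive")
})

test_that("the heatmap matrix assembles top hits with NA for unscored pairs", {
  mkTab <- function(q, perts, taus, cell = "A") {
    data.frame(query_id = q, sig_id = paste0(perts, "_s"), pert_id = perts,
               pert_iname = perts, cell_id = cell, es_up = 0, es_down = 0,
               wtcs = 0, ncs = taus / 100, tau = taus, connected = taus > 90)
  }
  shared <- heatmapMatrix(list(q1 = mkTab("q1", c("P1", "P2"), c(95, 50)),
                               q2 = mkTab("q2", c("P1", "P2"), c(40, 91))))
  expect_false(anyNA(values2d(shared)))
  expect_identical(colMeta(shared)$signature, c("q1", "q2"))
  disjoint <- heatmapMatrix(list(q1 = mkTab("q1", "P1", 95),
                                 q2 = mkTab("q2", "P2", 91)))
  expect_identical(dim(values2d(disjoint)), c(2L, 2L))
  expect_identical(sum(is.na(values2d(disjoint))), 2L)
  # planted scenario: the planted compound's row holds the matrix maximum
  sc <- plantedScenario(5, nLandmark = 150, nNonlandmark = 850, nTags = 100)
  conn <- queryCompendium(sc$signature, sc$compendium)
  hm <- values2d(heatmapMatrix(list(q1 = conn)))
  expect_identical(rownames(hm)[which(hm == max(hm, na.rm = TRUE),
                                      arr.ind = TRUE)[1]], sc$planted)
})

test_that("an external touchstone bank drives the tau percentile", {
  sc <- plantedScenario(9, nLandmark = 100, nNonlandmark = 400, nTags = 60)
  genes <- rownames(sc$compendium)
  set.seed(99)
  rand <- lapply(1:5, function(i) {
    tags <- sample(genes, 80)
    GeneSignature(upTags = tags[1:40], downTags = tags[41:80],
                  signatureId = sprintf("rand%d", i))
  })
  bank <- buildTouchstone(sc$compendium, rand)
  expect_identical(sort(names(bank)),
                   sort(unique(sigInfo(sc$compendium)$cell_id)))
  conn <- queryCompendium(sc$signature, sc$compendium, touchstone = bank)
  expect_identical(conn$pert_id[1], sc$planted)
  expect_equal(conn$tau[1], 100)  # planted |ncs| beats every random reference
})
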