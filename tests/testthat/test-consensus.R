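makeSubsetScenario <- function(z, pertOfColumn, upTags, downTags,
                               queryId = "q1") {
  colnames(z) <- sprintf("sig_%02d", seq_len(ncol(z)))
  si <- data.frame(sig_id = colnames(z), pert_id = pertOfColumn,
                   pert_iname = pertOfColumn, pert_type = "trt_cp",
                   cell_id = "MCF7", stringsAsFactors = FALSE)
  gi <- data.frame(pr_gene_id = rownames(z), pr_gene_symbol = rownames(z),
                   pr_is_lm = 1L, pr_is_bing = 1L, stringsAsFactors = FALSE)
  list(ref = ReferenceCompendium(z, si, gi),
       sig = GeneSignature(upTags = upTags, downTags = downTags,
                           signatureId = queryId))
}

test_that("compendium subsetting filters profiles and landmark genes", {
  cmp <- simulateCompendium(nLandmark = 50, nNonlandmark = 150,
    compounds = data.frame(pert_id = sprintf("P%d", 1:5),
                           pert_iname = sprintf("c%d", 1:5)),
    cellIds = sprintf("CELL%02d", 1:10), profilesPerPair = 2, seed = 6)
  ref <- cmp$compendium
  sub <- subsetCompendium(ref, pertIds = c("P1", "P3"))
  expect_identical(nrow(sub), 50L)  # landmark rows only
  expect_true(all(geneInfo(sub)$pr_is_lm))
  expect_identical(sort(unique(sigInfo(sub)$pert_id)), c("P1", "P3"))
  # selecting nine of ten cell lines keeps exactly those nine
  nine <- sprintf("CELL%02d", 1:9)
  subCells <- subsetCompendium(ref, cellIds = nine, landmarkOnly = FALSE)
  expect_identical(sort(unique(sigInfo(subCells)$cell_id)), nine)
  expect_identical(nrow(subCells), 200L)
  expect_error(subsetCompendium(ref, pertIds = "NOPE"), "pert_id")
  expect_error(subsetCompendium(ref, cellIds = "NOPE"), "cell_id")
})

test_that("the 70% direction-consensus boundary is inclusive", {
  # one up tag positive in 10/10, 7/10 and 6/10 profiles respectively
  z <- rbind(gA = rep(1, 10),
             gB = c(rep(1, 7), rep(-1, 3)),
             gC = c(rep(1, 6), rep(-1, 4)))
  sc <- makeSubsetScenario(z, rep("P1", 10), upTags = c("gA", "gB", "gC"),
                           downTags = character())
  out <- consensusSelect(sc$sig, sc$ref)
  expect_identical(sort(out$gene_id), c("gA", "gB"))
  expect_equal(out$support_fraction[out$gene_id == "gA"], 1.0)
  expect_equal(out$support_fraction[out$gene_id == "gB"], 0.7)
  expect_false("gC" %in% out$gene_id)
})

test_that("a zero z-score supports neither direction", {
  z <- rbind(gU = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
             gD = c(-1, -1, -1, -1, -1, -1, -1, 0, 0, 0))
  sc <- makeSubsetScenario(z, rep("P1", 10), upTags = "gU", downTags = "gD")
  out <- consensusSelect(sc$sig, sc$ref)
  expect_false("gU" %in% out$gene_id)     # only 3/10 strictly positive
  expect_identical(out$gene_id, "gD")     # 7/10 strictly negative
})

test_that("consensus selection matches the brute-force counting oracle", {
  set.seed(55)
  for (i in 1:500) {
    nGenes <- 20; nProf <- 12
    z <- matrix(rnorm(nGenes * nProf), nGenes, nProf,
                dimnames = list(sprintf("g%02d", 1:nGenes), NULL))
    z[sample(length(z), 5)] <- 0
    pert <- sample(c("P1", "P2", "P3"), nProf, replace = TRUE)
    up <- sample(rownames(z), 5)
    dn <- sample(setdiff(rownames(z), up), 5)
    frac <- sample(c(0.5, 0.7, 0.9), 1)
    sc <- makeSubsetScenario(z, pert, up, dn)
    mine <- consensusSelect(sc$sig, sc$ref, minDirectionFraction = frac)
    oracle <- bruteForceConsensus(z, up, dn, pert, frac)
    key <- function(d) sort(paste(d$pert_id, d$gene_id, d$direction,
                                  round(d$support_fraction, 10)))
    expect_identical(key(mine), key(oracle))
  }
})

test_that("lowering the consensus fraction never drops a retained gene", {
  set.seed(77)
  z <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  sc <- makeSubsetScenario(z, rep(c("P1", "P2"), each = 5),
                           upTags = rownames(z)[1:8],
                           downTags = rownames(z)[9:16])
  strict <- consensusSelect(sc$sig, sc$ref, minDirectionFraction = 0.8)
  loose <- consensusSelect(sc$sig, sc$ref, minDirectionFraction = 0.6)
  expect_true(all(paste(strict$pert_id, strict$gene_id) %in%
                    paste(loose$pert_id, loose$gene_id)))
  # retained genes always come from the signature tags present in the rows
  expect_true(all(loose$gene_id %in% c(upTags(sc$sig), downTags(sc$sig))))
  expect_true(all(loose$gene_id %in% rownames(z)))
})

test_that("pooled mode computes support across all profiles at once", {
  z <- rbind(gU = c(rep(1, 6), rep(-1, 4)))
  sc <- makeSubsetScenario(z, rep(c("P1", "P2"), each = 5),
                           upTags = "gU", downTags = character())
  pooled <- consensusSelect(sc$sig, sc$ref, minDirectionFraction = 0.6,
                            mode = "pooled")
  expect_identical(pooled$pert_id, "all")
  expect_equal(pooled$support_fraction, 0.6)
  perCompound <- consensusSelect(sc$sig, sc$ref, minDirectionFraction = 0.6)
  # P1 profiles are 5/5 positive, P2 only 1/5
  expect_identical(perCompound$pert_id, "P1")
})

test_that("signature tags absent from the subset rows are skipped with a note", {
  z <- rbind(gA = rep(1, 4))
  sc <- makeSubsetScenario(z, rep("P1", 4), upTags = c("gA", "missing"),
                           downTags = character())
  expect_message(out <- consensusSelect(sc$sig, sc$ref), "skipped")
  expect_identical(out$gene_id, "gA")
})
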