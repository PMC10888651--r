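# Independent brute-force oracles and small fixture builders. These stay
# loop-based and deliberately naive so they cannot share code paths with the
# package implementations they check.

# KS-type enrichment score: explicit loop over the a/b maxima.
bruteForceES <- function(geneSet, ranking) {
  n <- length(ranking)
  v <- sort(match(geneSet, ranking))
  t <- length(v)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

# Benjamini-Hochberg step-up evaluated from its definition:
# q(i) = min over j with p(j) >= p(i) of min(1, m * p(j) / rank(j)).
bruteForceBH <- function(p) {
  m <- length(p)
  r <- integer(m)
  r[order(p)] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i])
    min(1, min(m * p[j] / r[j]))
  }, numeric(1))
}

# Direction-consensus selection by explicit counting.
bruteForceConsensus <- function(z, upTags, downTags, pertOfColumn, frac) {
  rows <- list()
  for (pid in unique(pertOfColumn)) {
    cols <- which(pertOfColumn == pid)
    for (g in upTags) {
      if (!g %in% rownames(z)) next
      cnt <- 0
      for (cc in cols) if (z[g, cc] > 0) cnt <- cnt + 1
      if (cnt / length(cols) >= frac)
        rows[[length(rows) + 1L]] <- data.frame(
          pert_id = pid, gene_id = g, direction = "up",
          support_fraction = cnt / length(cols), stringsAsFactors = FALSE)
    }
    for (g in downTags) {
      if (!g %in% rownames(z)) next
      cnt <- 0
      for (cc in cols) if (z[g, cc] < 0) cnt <- cnt + 1
      if (cnt / length(cols) >= frac)
        rows[[length(rows) + 1L]] <- data.frame(
          pert_id = pid, gene_id = g, direction = "down",
          support_fraction = cnt / length(cols), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pert_id = character(), gene_id = character(),
                      direction = character(), support_fraction = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of every
# size-k draw from a universe of size N in which elements 1..m form the set.
enumHyperP <- function(N, m, k, x) {
  draws <- utils::combn(N, k)
  mean(colSums(draws <= m) >= x)
}

# Random DEG table; logFC rounded to force ties.
randomDegTable <- function(n, seed) {
  set.seed(seed)
  data.frame(gene_id = sprintf("r%05d", sample.int(99999, n)),
             logFC = round(stats::rnorm(n, sd = 2), 1),
             t = 0, p = stats::runif(n, 0, 0.01),
             q = stats::runif(n, 0, 0.049), stringsAsFactors = FALSE)
}

# A DEG table with a given number of significant up/down genes, logFC
# magnitudes descending in gene order.
plantedDegTable <- function(nUp, nDown) {
  data.frame(
    gene_id = sprintf("d%05d", seq_len(nUp + nDown)),
    logFC = c(seq(5, 1, length.out = nUp), seq(-1, -5, length.out = nDown)),
    t = 0, p = 1e-4, q = 1e-3, stringsAsFactors = FALSE)
}

# Two planted blocks of dataset vectors with within-block correlation ~0.8.
twoBlockVectors <- function(seed, nGenes = 200, perBlock = 4) {
  set.seed(seed)
  m1 <- stats::rnorm(nGenes)
  m2 <- stats::rnorm(nGenes)
  mk <- function(m) sqrt(0.8) * m + sqrt(0.2) * stats::rnorm(nGenes)
  v <- cbind(replicate(perBlock, mk(m1)), replicate(perBlock, mk(m2)))
  colnames(v) <- c(sprintf("A%d", seq_len(perBlock)),
                   sprintf("B%d", seq_len(perBlock)))
  v
}

# Small compendium with one planted compound for recovery checks.
plantedScenario <- function(seed, nLandmark = 978, nNonlandmark = 1022,
                            nTags = 150, profilesPerPair = 1) {
  nGenes <- nLandmark + nNonlandmark
  genes <- sprintf("g%05d", seq_len(nGenes))
  set.seed(seed + 10000)
  tags <- sample(genes, 2 * nTags)
  sig <- GeneSignature(upTags = tags[seq_len(nTags)],
                       downTags = tags[nTags + seq_len(nTags)],
                       signatureId = "q1")
  cmp <- simulateCompendium(
    querySignatures = list(sig), nLandmark = nLandmark,
    nNonlandmark = nNonlandmark, profilesPerPair = profilesPerPair,
    plantedConnections = data.frame(query_id = "q1",
                                    pert_id = "BRD-S000007",
                                    strength = 1,
                                    stringsAsFactors = FALSE),
    seed = seed)
  list(signature = sig, compendium = cmp$compendium,
       planted = "BRD-S000007")
}
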