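#' Simulate a two-group expression experiment with planted DE genes
#'
#' Generates a log2-scale expression matrix of \code{nGenes} genes over
#' \code{nPerGroup} control and \code{nPerGroup} treated samples. Each gene
#' has a Gaussian baseline (mean 7, sd 1 across genes, mimicking log2
#' microarray intensities) plus i.i.d. Gaussian residual noise of sd
#' \code{noiseSd}; \code{nUp} planted genes are shifted by
#' \code{+effectSize} and \code{nDown} by \code{-effectSize} in the treated
#' group. Output is bit-reproducible under a fixed \code{seed}.
#'
#' @param nGenes number of genes.
#' @param nPerGroup samples per group (>= 3).
#' @param nUp,nDown number of planted up-/down-regulated genes
#'   (\code{nUp + nDown <= nGenes}).
#' @param effectSize mean log2 shift of planted genes in the treated group.
#' @param noiseSd residual standard deviation (log2 units).
#' @param seed integer RNG seed.
#' @param geneIds optional gene identifiers (default \code{g00001...}).
#' @return A list with \code{experiment}
#'   (\linkS4class{ExpressionExperiment}) and \code{truth}, a data.frame of
#'   planted gene ids and their direction (\code{up}/\code{down}).
#' @export
simulateExperiment <- function(nGenes = 5000, nPerGroup = 3, nUp = 400,
                               nDown = 400, effectSize = 2, noiseSd = 0.3,
                               seed = 1, geneIds = NULL) {
  stopIfNot(nUp + nDown <= nGenes,
            "nUp + nDown (%d) exceeds nGenes (%d)", nUp + nDown, nGenes)
  stopIfNot(nPerGroup >= 3, "at least 3 samples per group are required")
  geneIds <- geneIds %||% sprintf("g%05d", seq_len(nGenes))
  stopIfNot(length(geneIds) == nGenes, "geneIds must have length nGenes")
  withSeed(seed, {
    baseline <- stats::rnorm(nGenes, mean = 7, sd = 1)
    n <- 2L * nPerGroup
    mat <- baseline + matrix(stats::rnorm(nGenes * n, sd = noiseSd), nGenes, n)
    de <- sample.int(nGenes, nUp + nDown)
    upIdx <- de[seq_len(nUp)]
    downIdx <- de[nUp + seq_len(nDown)]
    treated <- nPerGroup + seq_len(nPerGroup)
    mat[upIdx, treated] <- mat[upIdx, treated] + effectSize
    mat[downIdx, treated] <- mat[downIdx, treated] - effectSize
    dimnames(mat) <- list(geneIds,
                          c(sprintf("ctrl_%d", seq_len(nPerGroup)),
                            sprintf("trt_%d", seq_len(nPerGroup))))
    groups <- rep(c("control", "treated"), each = nPerGroup)
    truth <- data.frame(
      gene_id = c(geneIds[upIdx], geneIds[downIdx]),
      direction = rep(c("up", "down"), c(nUp, nDown)),
      stringsAsFactors = FALSE)
    list(experiment = ExpressionExperiment(mat, groups), truth = truth)
  })
}

#' Simulate a CMap-style reference compendium with planted connections
#'
#' Generates a genes x profiles z-score matrix with sig_info/gene_info
#' metadata emulating the GSE92742 level-5 layout: \code{nLandmark}
#' landmark genes (flag \code{pr_is_lm}) inside a larger gene space, one
#' profile per (compound, cell line, replicate). Background z-scores are
#' i.i.d. standard normal. For each planted connection of strength
#' \code{s}, the compound's profiles add \code{+s*delta} to the query
#' signature's up tags and \code{-s*delta} to its down tags, so the planted
#' compound is coherently connected to that query with known strength.
#'
#' @param querySignatures list of \linkS4class{GeneSignature} objects
#'   referenced by \code{plantedConnections}; their tags must lie in the
#'   compendium gene space.
#' @param nLandmark number of landmark genes (default 978, the L1000
#'   landmark space).
#' @param nNonlandmark number of additional inferred genes (default 11350,
#'   for a 12328-gene space).
#' @param compounds data.frame with \code{pert_id}, \code{pert_iname}; by
#'   default 20 synthetic compounds.
#' @param cellIds cell line identifiers (default 3).
#' @param profilesPerPair replicate profiles per (compound, cell) pair.
#' @param plantedConnections data.frame with \code{query_id},
#'   \code{pert_id}, \code{strength} in [0, 1]; NULL for a null compendium.
#' @param delta z-score shift at strength 1 (default 3).
#' @param seed integer RNG seed.
#' @param geneIds optional gene identifiers; the first \code{nLandmark} are
#'   flagged landmark.
#' @return A list with \code{compendium}
#'   (\linkS4class{ReferenceCompendium}) and \code{truth} (the planted
#'   connection table).
#' @export
simulateCompendium <- function(querySignatures = list(), nLandmark = 978,
                               nNonlandmark = 11350, compounds = NULL,
                               cellIds = c("A375", "MCF7", "PC3"),
                               profilesPerPair = 3, plantedConnections = NULL,
                               delta = 3, seed = 1, geneIds = NULL) {
  nGenes <- nLandmark + nNonlandmark
  geneIds <- geneIds %||% sprintf("g%05d", seq_len(nGenes))
  stopIfNot(length(geneIds) == nGenes,
            "geneIds must have length nLandmark + nNonlandmark")
  compounds <- compounds %||% data.frame(
    pert_id = sprintf("BRD-S%06d", seq_len(20)),
    pert_iname = sprintf("cmpd-%02d", seq_len(20)),
    stringsAsFactors = FALSE)
  stopIfNot(!anyDuplicated(compounds$pert_id), "pert_ids must be unique")
  sigIds <- vapply(querySignatures, signatureId, character(1))
  if (!is.null(plantedConnections)) {
    stopIfNot(all(plantedConnections$pert_id %in% compounds$pert_id),
              "plantedConnections references unknown pert_id(s)")
    stopIfNot(all(plantedConnections$query_id %in% sigIds),
              "plantedConnections references unknown query_id(s)")
    stopIfNot(all(plantedConnections$strength >= 0 &
                    plantedConnections$strength <= 1),
              "strength must lie in [0, 1]")
  }
  grid <- expand.grid(rep = seq_len(profilesPerPair), cell_id = cellIds,
                      pert_id = compounds$pert_id, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  nProf <- nrow(grid)
  sig_info <- data.frame(
    sig_id = sprintf("%s_%s_%d", grid$pert_id, grid$cell_id, grid$rep),
    pert_id = grid$pert_id,
    pert_iname = compounds$pert_iname[match(grid$pert_id, compounds$pert_id)],
    pert_type = "trt_cp",
    cell_id = grid$cell_id,
    stringsAsFactors = FALSE)
  withSeed(seed, {
    z <- matrix(stats::rnorm(nGenes * nProf), nGenes, nProf,
                dimnames = list(geneIds, sig_info$sig_id))
    gene_info <- data.frame(
      pr_gene_id = geneIds,
      pr_gene_symbol = geneIds,
      pr_is_lm = as.integer(seq_len(nGenes) <= nLandmark),
      pr_is_bing = as.integer(seq_len(nGenes) <= nLandmark |
                                stats::runif(nGenes) < 0.5),
      stringsAsFactors = FALSE)
    if (!is.null(plantedConnections)) {
      for (i in seq_len(nrow(plantedConnections))) {
        pc <- plantedConnections[i, ]
        sig <- querySignatures[[match(pc$query_id, sigIds)]]
        cols <- which(sig_info$pert_id == pc$pert_id)
        shift <- pc$strength * delta
        up <- intersect(upTags(sig), geneIds)
        dn <- intersect(downTags(sig), geneIds)
        z[up, cols] <- z[up, cols] + shift
        z[dn, cols] <- z[dn, cols] - shift
      }
    }
    truth <- plantedConnections %||%
      data.frame(query_id = character(), pert_id = character(),
                 strength = numeric(), stringsAsFactors = FALSE)
    list(compendium = ReferenceCompendium(z, sig_info, gene_info),
         truth = truth)
  })
}

#' Simulate a pathway gene-set collection
#'
#' Draws \code{nSets} random gene sets from a gene universe, optionally
#' planting one set with exactly a supplied gene list so downstream
#' enrichment has a known positive.
#'
#' @param nSets number of random sets.
#' @param setSizeRange integer range (min, max) of set sizes.
#' @param universe character vector of gene ids to draw from.
#' @param planted optional \code{list(set_id =, genes =)}; the planted set
#'   is appended verbatim.
#' @param seed integer RNG seed.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
simulatePathways <- function(nSets = 12, setSizeRange = c(10, 50), universe,
                             planted = NULL, seed = 1) {
  stopIfNot(length(universe) > 0, "gene universe must be non-empty")
  stopIfNot(setSizeRange[2] <= length(universe),
            "set sizes cannot exceed the universe size")
  withSeed(seed, {
    sizes <- sample(seq(setSizeRange[1], setSizeRange[2]), nSets,
                    replace = TRUE)
    genes <- lapply(sizes, function(s) sample(universe, s))
    names(genes) <- sprintf("SET_%03d", seq_len(nSets))
    desc <- rep("random set", nSets)
    if (!is.null(planted)) {
      genes[[planted$set_id]] <- unique(as.character(planted$genes))
      desc <- c(desc, "planted set")
    }
    GeneSetCollection(genes, descriptions = desc)
  })
}
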