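#' Pearson correlation between dataset signature vectors
#'
#' @param vectors numeric genes x datasets matrix: one column of
#'   gene-level values (e.g. consensus-gene logFC) per dataset, on a shared
#'   gene set.
#' @return Symmetric Pearson correlation matrix with unit diagonal.
#' @export
signatureCorrelation <- function(vectors) {
  stopIfNot(is.matrix(vectors) && ncol(vectors) >= 2L,
            "at least two dataset vectors are required")
  stopIfNot(nrow(vectors) >= 2L, "shared gene set must have >= 2 genes")
  sds <- apply(vectors, 2, stats::sd)
  bad <- which(sds == 0 | is.na(sds))
  if (length(bad))
    stop("constant vector(s), correlation undefined: ",
         paste(colnames(vectors)[bad] %||% bad, collapse = ", "),
         call. = FALSE)
  stats::cor(vectors)
}

#' Ward hierarchical clustering of dataset signature vectors
#'
#' Standardizes each dataset vector, computes Euclidean distances and
#' applies Ward variance-minimization linkage. When \code{nClusters} is
#' omitted, the tree is cut at the largest gap between consecutive merge
#' heights.
#'
#' @param vectors numeric genes x datasets matrix (>= 2 datasets).
#' @param nClusters optional number of clusters.
#' @return A list of class \code{wardClustering} with \code{labels} (named
#'   cluster assignment), \code{merge}, \code{heights}, \code{nClusters}
#'   and the underlying \code{hclust} object.
#' @export
wardCluster <- function(vectors, nClusters = NULL) {
  stopIfNot(is.matrix(vectors) && ncol(vectors) >= 2L,
            "at least two dataset vectors are required")
  std <- apply(vectors, 2, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) v - mean(v) else (v - mean(v)) / s
  })
  hc <- stats::hclust(stats::dist(t(std)), method = "ward.D2")
  h <- hc$height
  k <- if (!is.null(nClusters)) {
    stopIfNot(nClusters >= 1 && nClusters <= ncol(vectors),
              "nClusters out of range")
    nClusters
  } else if (length(h) == 1L) {
    2L
  } else {
    # cut where consecutive merge heights jump the most
    ncol(vectors) - which.max(diff(h))
  }
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, merge = hc$merge, heights = h,
                 nClusters = k, hclust = hc),
            class = "wardClustering")
}

#' @export
print.wardClustering <- function(x, ...) {
  cat(sprintf("Ward clustering: %d datasets in %d cluster(s)\n",
              length(x$labels), x$nClusters))
  print(x$labels)
  invisible(x)
}

#' Hypergeometric pathway enrichment of a gene list
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of the overlap between
#' a query gene list and each gene set, within a gene universe:
#' \code{p = P[X >= overlap]} with
#' \code{X ~ Hypergeometric(universe, set, query)}. q-values are
#' Benjamini-Hochberg across the tested sets; significance is called at
#' \code{q < qCutoff}. Sets are intersected with the universe first; query
#' genes outside the universe are dropped with a message.
#'
#' @param query character vector of genes (non-empty after restriction to
#'   the universe).
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param universe character vector of background genes.
#' @param qCutoff significance cutoff on q (default 0.05).
#' @return data.frame with columns \code{set_id}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{universe_size}, \code{p},
#'   \code{q}, \code{significant}, sorted by ascending p.
#' @export
hypergeomEnrich <- function(query, sets, universe, qCutoff = 0.05) {
  stopifnot(is(sets, "GeneSetCollection"))
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    message(sprintf("%d query gene(s) outside the universe, dropped",
                    length(outside)))
  query <- intersect(query, universe)
  stopIfNot(length(query) > 0L, "query gene list is empty")
  N <- length(universe); k <- length(query)
  memb <- lapply(geneSets(sets), intersect, universe)
  out <- data.frame(
    set_id = names(memb),
    overlap = vapply(memb, function(g) length(intersect(g, query)), integer(1)),
    set_size = lengths(memb),
    query_size = k,
    universe_size = N,
    stringsAsFactors = FALSE)
  out$p <- stats::phyper(out$overlap - 1, out$set_size, N - out$set_size, k,
                         lower.tail = FALSE)
  out$q <- benjaminiHochberg(out$p)
  out$significant <- out$q < qCutoff
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway-by-compound significance matrix
#'
#' Summarizes per-compound enrichment results into a matrix whose rows are
#' every pathway significant for at least one compound; an entry holds the
#' overlap gene count when that (pathway, compound) pair is significant and
#' NA otherwise.
#'
#' @param enrichments named list of enrichment tables from
#'   \code{\link{hypergeomEnrich}} (names = compound ids).
#' @param qCutoff significance cutoff on q (default 0.05).
#' @return A \linkS4class{GctMatrix} (pathways x compounds); zero rows when
#'   nothing is significant.
#' @export
compoundPathwayMatrix <- function(enrichments, qCutoff = 0.05) {
  stopIfNot(length(enrichments) >= 1L, "at least one compound is required")
  sig <- lapply(enrichments, function(e) e[e$q < qCutoff, , drop = FALSE])
  paths <- unique(unlist(lapply(sig, `[[`, "set_id"))) %||% character()
  mat <- matrix(NA_real_, length(paths), length(enrichments),
                dimnames = list(paths, names(enrichments)))
  for (cmpd in names(enrichments)) {
    e <- sig[[cmpd]]
    if (nrow(e)) mat[e$set_id, cmpd] <- e$overlap
  }
  GctMatrix(mat)
}
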