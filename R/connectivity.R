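#' Kolmogorov-Smirnov-type enrichment score of a gene set in a ranked profile
#'
#' Classic unweighted connectivity-map statistic. With \eqn{n} ranked genes,
#' a set of size \eqn{t} occupying ascending rank positions \eqn{V(j)},
#' \deqn{a = \max_j (j/t - V(j)/n), \quad b = \max_j (V(j)/n - (j-1)/t),}
#' the score is \eqn{a} if \eqn{a > b} and \eqn{-b} otherwise. Positive
#' scores mean the set concentrates at the top of the ranking (the most
#' up-regulated end), negative at the bottom; the score lies in [-1, 1].
#'
#' @param geneSet character vector of gene ids (non-empty, all present in
#'   the ranking).
#' @param ranking character vector of all gene ids ordered by descending
#'   z-score.
#' @return The enrichment score, a single number in [-1, 1].
#' @export
esScore <- function(geneSet, ranking) {
  stopIfNot(length(geneSet) >= 1L, "gene set must be non-empty")
  v <- match(geneSet, ranking)
  stopIfNot(!anyNA(v), "gene set contains ids absent from the ranking")
  esFromPositions(sort(v), length(ranking))
}

# Core a/b maxima on sorted ascending rank positions.
esFromPositions <- function(v, n) {
  t <- length(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Combined two-sided connectivity score (WTCS)
#'
#' Averages the up-set and down-set enrichment scores when they disagree in
#' sign (a coherent connection: up tags high and down tags low, or the
#' reverse) and returns 0 when both point the same way (incoherent).
#'
#' @param esUp,esDown enrichment scores in [-1, 1]; use 0 for a direction
#'   that has no tags.
#' @return \code{(esUp - esDown)/2} if the signs differ, else 0.
#' @export
wtcs <- function(esUp, esDown) {
  if (sign(esUp) != sign(esDown)) (esUp - esDown) / 2 else 0
}

#' Cell-line normalization of connectivity scores (NCS)
#'
#' Within each cell-line group, rescales WTCS by the mean magnitude of the
#' same-sign scores of that group, so scores are comparable across cell
#' lines: \code{ncs = wtcs / mean(|wtcs| of same-sign records)}. Zero stays
#' zero; an all-zero group keeps NCS 0.
#'
#' @param records data.frame with columns \code{cell_id} and \code{wtcs}.
#' @return \code{records} with an added \code{ncs} column.
#' @export
normalizeNcs <- function(records) {
  stopIfNot(all(c("cell_id", "wtcs") %in% names(records)),
            "records need cell_id and wtcs columns")
  ncs <- numeric(nrow(records))
  for (cell in unique(records$cell_id)) {
    idx <- which(records$cell_id == cell)
    w <- records$wtcs[idx]
    pos <- w > 0; neg <- w < 0
    if (any(pos)) ncs[idx[pos]] <- w[pos] / mean(w[pos])
    if (any(neg)) ncs[idx[neg]] <- w[neg] / mean(abs(w[neg]))
  }
  records$ncs <- ncs
  records
}

#' Tau percentile connectivity score
#'
#' Places a normalized connectivity score within a reference distribution:
#' \code{tau = sign(ncs) * 100 * fraction of reference |NCS| values strictly
#' below |ncs|}. Strong connections therefore approach +/-100 and weak ones
#' 0.
#'
#' @param ncs normalized connectivity score of the record.
#' @param referenceNcs non-empty numeric vector of reference NCS values for
#'   the same cell line (the touchstone bank).
#' @return tau in [-100, 100].
#' @export
tauScore <- function(ncs, referenceNcs) {
  stopIfNot(length(referenceNcs) >= 1L,
            "reference NCS distribution must be non-empty")
  sign(ncs) * 100 * sum(abs(referenceNcs) < abs(ncs)) / length(referenceNcs)
}

# Score one signature against every profile: per-profile ES/WTCS, NCS within
# cell lines, then one representative per (pert_id, cell_id).
scoreSignature <- function(sig, ref, aggregate = c("max_abs", "median")) {
  aggregate <- match.arg(aggregate)
  genes <- rownames(ref)
  up <- upTags(sig); dn <- downTags(sig)
  upIdx <- match(up, genes); upIdx <- upIdx[!is.na(upIdx)]
  dnIdx <- match(dn, genes); dnIdx <- dnIdx[!is.na(dnIdx)]
  dropped <- c(up = length(up) - length(upIdx),
               down = length(dn) - length(dnIdx))
  if (sum(dropped) > 0)
    message(sprintf("query '%s': %d up and %d down tag(s) absent from the reference, dropped",
                    signatureId(sig), dropped["up"], dropped["down"]))
  stopIfNot(length(upIdx) + length(dnIdx) > 0L,
            "no signature tag overlaps the reference gene space")
  z <- zscores(ref)
  n <- length(genes)
  si <- sigInfo(ref)
  nProf <- ncol(z)
  esUp <- esDn <- w <- numeric(nProf)
  pos <- integer(n)
  for (j in seq_len(nProf)) {
    ord <- order(-z[, j], genes, method = "radix")  # ties: gene id lexicographic
    pos[ord] <- seq_len(n)
    eu <- if (length(upIdx)) esFromPositions(sort(pos[upIdx]), n) else 0
    ed <- if (length(dnIdx)) esFromPositions(sort(pos[dnIdx]), n) else 0
    esUp[j] <- if (length(upIdx)) eu else NA_real_
    esDn[j] <- if (length(dnIdx)) ed else NA_real_
    w[j] <- wtcs(eu, ed)
  }
  rec <- data.frame(query_id = signatureId(sig), sig_id = si$sig_id,
                    pert_id = si$pert_id, pert_iname = si$pert_iname,
                    cell_id = si$cell_id, es_up = esUp, es_down = esDn,
                    wtcs = w, stringsAsFactors = FALSE)
  rec <- normalizeNcs(rec)
  collapseReplicates(rec, aggregate)
}

# One representative row per (pert_id, cell_id): the profile with maximum
# |ncs| (ties: first by sig_id), or the middle-|ncs| profile for "median".
collapseReplicates <- function(rec, aggregate) {
  key <- paste(rec$pert_id, rec$cell_id, sep = "\r")
  rec <- rec[order(key, rec$sig_id), , drop = FALSE]
  key <- paste(rec$pert_id, rec$cell_id, sep = "\r")
  pick <- vapply(split(seq_len(nrow(rec)), key), function(idx) {
    a <- abs(rec$ncs[idx])
    if (aggregate == "max_abs") idx[which.max(a)]
    else idx[order(a)][ceiling(length(idx) / 2)]
  }, integer(1))
  out <- rec[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a touchstone bank of reference NCS distributions
#'
#' Scores a set of (typically random) signatures against the compendium and
#' stores, per cell line, the collapsed NCS values of every
#' query-versus-compound comparison. This bank is the reference
#' distribution against which \code{\link{tauScore}} percentiles later
#' queries.
#'
#' @param ref a \linkS4class{ReferenceCompendium}.
#' @param signatures list of \linkS4class{GeneSignature} objects.
#' @param aggregate replicate aggregator, as in
#'   \code{\link{queryCompendium}}.
#' @return Named list: cell_id -> numeric vector of NCS values.
#' @export
buildTouchstone <- function(ref, signatures, aggregate = "max_abs") {
  banks <- list()
  for (sig in signatures) {
    rec <- scoreSignature(sig, ref, aggregate)
    for (cell in unique(rec$cell_id))
      banks[[cell]] <- c(banks[[cell]], rec$ncs[rec$cell_id == cell])
  }
  banks
}

#' Score a query signature against a reference compendium
#'
#' The local connectivity engine. For every reference profile it computes
#' the up- and down-set enrichment scores and their combination (WTCS),
#' normalizes within cell lines (NCS), collapses replicate profiles of each
#' (compound, cell line) pair to one representative, assigns each
#' representative a tau percentile against the touchstone bank (or, when no
#' bank is supplied, against the query's own representatives within the
#' same cell line), and flags connections at \code{|tau| > tauCutoff}.
#' Signature tags absent from the reference gene space are dropped with a
#' message; a query with no overlapping tags in either direction is an
#' error.
#'
#' @param sig a \linkS4class{GeneSignature}.
#' @param ref a \linkS4class{ReferenceCompendium}.
#' @param touchstone optional bank from \code{\link{buildTouchstone}}.
#' @param tauCutoff connection threshold on |tau| (default 90).
#' @param aggregate replicate aggregator: \code{"max_abs"} (default,
#'   representative with maximum |NCS|) or \code{"median"}.
#' @return A connectivity table: data.frame with columns \code{query_id},
#'   \code{sig_id}, \code{pert_id}, \code{pert_iname}, \code{cell_id},
#'   \code{es_up}, \code{es_down}, \code{wtcs}, \code{ncs}, \code{tau},
#'   \code{connected}, sorted by descending tau (ties: descending |NCS|,
#'   then pert_id).
#' @export
queryCompendium <- function(sig, ref, touchstone = NULL, tauCutoff = 90,
                            aggregate = c("max_abs", "median")) {
  aggregate <- match.arg(aggregate)
  rec <- scoreSignature(sig, ref, aggregate)
  tau <- numeric(nrow(rec))
  for (cell in unique(rec$cell_id)) {
    idx <- which(rec$cell_id == cell)
    bank <- touchstone[[cell]] %||% rec$ncs[idx]
    tau[idx] <- vapply(rec$ncs[idx], tauScore, numeric(1),
                       referenceNcs = bank)
  }
  rec$tau <- tau
  rec$connected <- abs(rec$tau) > tauCutoff
  rec <- rec[order(-rec$tau, -abs(rec$ncs), rec$pert_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Select the top of a connectivity table
#'
#' First \code{k} rows by descending tau; ties broken by descending |NCS|,
#' then pert_id. Shorter tables are returned whole.
#'
#' @param table connectivity table from \code{\link{queryCompendium}}.
#' @param k number of rows to keep (default 10).
#' @return The top-k connectivity table.
#' @export
topK <- function(table, k = 10) {
  stopIfNot(length(k) == 1L && !is.na(k) && k >= 1, "k must be a positive count")
  out <- table[order(-table$tau, -abs(table$ncs), table$pert_id), ,
               drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Assemble a heatmap-ready tau matrix from per-query top hits
#'
#' Rows are the union of top-k compounds over all queries; columns are the
#' (query, cell line) pairs present in any top list; entries are tau, NA
#' where a pair was not scored into a query's top list. Column metadata
#' carries the signature and cell-line labels.
#'
#' @param tables named list of connectivity tables (names = query ids),
#'   typically already passed through \code{\link{topK}}.
#' @param k rows kept per table before assembly (default 10).
#' @return A \linkS4class{GctMatrix} (compounds x query-cell pairs) with
#'   \code{colMeta} columns \code{signature} and \code{cell_id}.
#' @export
heatmapMatrix <- function(tables, k = 10) {
  stopIfNot(length(tables) >= 1L, "at least one connectivity table is required")
  tops <- lapply(tables, topK, k = k)
  all <- do.call(rbind, tops)
  compounds <- unique(unlist(lapply(tops, `[[`, "pert_id")))
  cols <- unique(all[, c("query_id", "cell_id")])
  colIds <- paste(cols$query_id, cols$cell_id, sep = ":")
  mat <- matrix(NA_real_, length(compounds), nrow(cols),
                dimnames = list(compounds, colIds))
  for (i in seq_len(nrow(all))) {
    ci <- paste(all$query_id[i], all$cell_id[i], sep = ":")
    mat[all$pert_id[i], ci] <- all$tau[i]
  }
  GctMatrix(mat, colMeta = data.frame(signature = cols$query_id,
                                      cell_id = cols$cell_id,
                                      stringsAsFactors = FALSE))
}
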