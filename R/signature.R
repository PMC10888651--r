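#' Build a query gene signature from a filtered DEG table
#'
#' Sorts the DEGs by base-two log fold change and takes both ends: the up
#' tags are the first \code{maxPerDirection} genes with positive logFC in
#' descending order, the down tags the first \code{maxPerDirection} genes
#' with negative logFC in ascending order (most down-regulated first).
#' Genes with logFC exactly 0 belong to neither list. An optional
#' allowed-gene list (the BING-equivalent query space) is applied either
#' after top-k selection (default, so lists may end up shorter than the
#' cap) or before it.
#'
#' @param degs filtered DEG table (see \code{\link{filterDegs}}).
#' @param maxPerDirection cap per direction (default 150).
#' @param maxTotal overall tag cap (default 300); must be at least
#'   \code{2 * maxPerDirection}.
#' @param allowedGenes optional character vector restricting the query
#'   space; deduplicated.
#' @param allowedFilterOrder \code{"after_selection"} (default) or
#'   \code{"before_selection"}.
#' @param signatureId identifier for the resulting signature.
#' @return A \linkS4class{GeneSignature}.
#' @export
buildSignature <- function(degs, maxPerDirection = 150, maxTotal = 300,
                           allowedGenes = NULL,
                           allowedFilterOrder = c("after_selection",
                                                  "before_selection"),
                           signatureId = "query") {
  allowedFilterOrder <- match.arg(allowedFilterOrder)
  stopIfNot(2 * maxPerDirection <= maxTotal,
            "maxTotal (%d) must be at least twice maxPerDirection (%d)",
            maxTotal, maxPerDirection)
  if (!is.null(allowedGenes)) allowedGenes <- unique(allowedGenes)
  ord <- order(-degs$logFC, degs$q, degs$gene_id)
  degs <- degs[ord, , drop = FALSE]
  if (allowedFilterOrder == "before_selection" && !is.null(allowedGenes))
    degs <- degs[degs$gene_id %in% allowedGenes, , drop = FALSE]
  up <- degs$gene_id[degs$logFC > 0]
  dn <- degs[degs$logFC < 0, , drop = FALSE]
  # most negative logFC first; ties broken as for up (ascending q, gene id)
  down <- dn$gene_id[order(dn$logFC, dn$q, dn$gene_id)]
  up <- utils::head(up, maxPerDirection)
  down <- utils::head(down, maxPerDirection)
  if (allowedFilterOrder == "after_selection" && !is.null(allowedGenes)) {
    up <- up[up %in% allowedGenes]
    down <- down[down %in% allowedGenes]
  }
  GeneSignature(upTags = up, downTags = down, signatureId = signatureId)
}

#' Write / read a gene signature text file
#'
#' Two-block text format mirroring a tag-list upload: an optional
#' \code{#id<TAB>name} line, a \code{>UP} header followed by one up tag per
#' line, then a \code{>DOWN} header and the down tags. The round-trip is
#' lossless.
#'
#' @param sig a \linkS4class{GeneSignature}.
#' @param path file path.
#' @return \code{writeSignature}: \code{path}, invisibly;
#'   \code{readSignature}: a \linkS4class{GeneSignature}.
#' @export
writeSignature <- function(sig, path) {
  stopifnot(is(sig, "GeneSignature"))
  lines <- c(paste0("#id\t", signatureId(sig)),
             ">UP", upTags(sig), ">DOWN", downTags(sig))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  id <- "query"
  if (length(lines) && startsWith(lines[1], "#id\t")) {
    id <- sub("^#id\t", "", lines[1])
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  iUp <- which(lines == ">UP")
  iDown <- which(lines == ">DOWN")
  if (length(iUp) != 1L || length(iDown) != 1L || iDown < iUp)
    stop("malformed signature file: expected one >UP block then one >DOWN block",
         call. = FALSE)
  up <- if (iDown > iUp + 1L) lines[(iUp + 1L):(iDown - 1L)] else character()
  down <- if (iDown < length(lines)) lines[(iDown + 1L):length(lines)]
    else character()
  GeneSignature(upTags = up, downTags = down, signatureId = id)
}
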