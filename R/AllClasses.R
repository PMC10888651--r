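#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Dense annotated matrix (GCT-style)
#'
#' In-memory image of a GCT file: a numeric genes-by-columns matrix with
#' unique row and column identifiers plus optional keyed row/column
#' annotation tables (the GCT 1.3 metadata blocks).
#'
#' @slot mat numeric matrix with unique, non-empty dimnames.
#' @slot rowMeta data.frame of per-row annotations (0 rows when absent).
#' @slot colMeta data.frame of per-column annotations (0 rows when absent).
#' @export
setClass("GctMatrix",
  representation(mat = "matrix", rowMeta = "data.frame", colMeta = "data.frame"))

setValidity("GctMatrix", function(object) {
  m <- object@mat
  if ((nrow(m) > 0L && is.null(rownames(m))) ||
      (ncol(m) > 0L && is.null(colnames(m))))
    return("matrix must have row and column names")
  if (anyDuplicated(rownames(m))) return("duplicate row ids")
  if (anyDuplicated(colnames(m))) return("duplicate column ids")
  if (nrow(object@rowMeta) != 0L && nrow(object@rowMeta) != nrow(m))
    return("rowMeta rows must match matrix rows")
  if (nrow(object@colMeta) != 0L && nrow(object@colMeta) != ncol(m))
    return("colMeta rows must match matrix columns")
  TRUE
})

#' Construct a GctMatrix
#'
#' @param mat numeric matrix with dimnames.
#' @param rowMeta,colMeta optional annotation data.frames (one row per
#'   matrix row/column).
#' @return A \linkS4class{GctMatrix}.
#' @export
GctMatrix <- function(mat, rowMeta = NULL, colMeta = NULL) {
  new("GctMatrix", mat = mat,
      rowMeta = rowMeta %||% data.frame(),
      colMeta = colMeta %||% data.frame())
}

setMethod("show", "GctMatrix", function(object) {
  cat(sprintf("GctMatrix: %d rows x %d columns\n",
              nrow(object@mat), ncol(object@mat)))
  if (ncol(object@rowMeta))
    cat("  rowMeta:", paste(names(object@rowMeta), collapse = ", "), "\n")
  if (ncol(object@colMeta))
    cat("  colMeta:", paste(names(object@colMeta), collapse = ", "), "\n")
})

#' Two-group expression experiment
#'
#' A \linkS4class{SummarizedExperiment} carrying a log2 expression matrix and
#' a per-sample \code{group} factor with levels \code{control}/\code{treated};
#' validity requires unique gene ids and at least three samples per group.
#'
#' @export
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

setValidity("ExpressionExperiment", function(object) {
  if (!"group" %in% names(colData(object)))
    return("colData must contain a 'group' column")
  g <- colData(object)$group
  if (!all(g %in% c("control", "treated")))
    return("group labels must be 'control' or 'treated'")
  if (any(table(factor(g, c("control", "treated"))) < 3L))
    return("at least 3 samples per group are required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("gene ids must be present and unique")
  TRUE
})

#' Construct an ExpressionExperiment
#'
#' @param mat log2 expression matrix, genes x samples, with dimnames.
#' @param groups character vector (length \code{ncol(mat)}) of
#'   \code{"control"}/\code{"treated"} labels.
#' @return An \linkS4class{ExpressionExperiment}.
#' @export
ExpressionExperiment <- function(mat, groups) {
  se <- SummarizedExperiment(
    assays = list(exprs = mat),
    colData = DataFrame(group = as.character(groups),
                        row.names = colnames(mat)))
  new("ExpressionExperiment", se)
}

setMethod("show", "ExpressionExperiment", function(object) {
  g <- table(colData(object)$group)
  cat(sprintf("ExpressionExperiment: %d genes, %d samples (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s=%d", names(g), g), collapse = ", ")))
})

#' Reference compendium of perturbation z-score profiles
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{zscores} holds
#' level-5-style differential z-scores (genes x profiles), whose colData is
#' the sig_info table (\code{sig_id}, \code{pert_id}, \code{pert_iname},
#' \code{pert_type}, \code{cell_id}) and whose rowData is the gene_info table
#' (\code{pr_gene_id}, \code{pr_gene_symbol}, \code{pr_is_lm},
#' \code{pr_is_bing}).
#'
#' @export
setClass("ReferenceCompendium", contains = "SummarizedExperiment")

setValidity("ReferenceCompendium", function(object) {
  need_c <- c("sig_id", "pert_id", "pert_iname", "pert_type", "cell_id")
  miss <- setdiff(need_c, names(colData(object)))
  if (length(miss))
    return(paste("sig_info is missing column(s):", paste(miss, collapse = ", ")))
  need_r <- c("pr_gene_id", "pr_is_lm")
  miss <- setdiff(need_r, names(rowData(object)))
  if (length(miss))
    return(paste("gene_info is missing column(s):", paste(miss, collapse = ", ")))
  if (!identical(as.character(colData(object)$sig_id), colnames(object)))
    return("sig_info sig_id must match profile column ids, in order")
  if (!is.logical(rowData(object)$pr_is_lm))
    return("pr_is_lm must be logical")
  TRUE
})

#' Construct a ReferenceCompendium
#'
#' @param zscores numeric genes x profiles matrix with dimnames; columns are
#'   profile (signature) ids matching \code{sigInfo$sig_id}.
#' @param sigInfo per-profile metadata data.frame with at least
#'   \code{sig_id}, \code{pert_id}, \code{pert_iname}, \code{pert_type},
#'   \code{cell_id}.
#' @param geneInfo per-gene metadata data.frame with at least
#'   \code{pr_gene_id} and a logical (or 0/1) \code{pr_is_lm} landmark flag.
#' @return A \linkS4class{ReferenceCompendium}.
#' @export
ReferenceCompendium <- function(zscores, sigInfo, geneInfo) {
  sigInfo <- as.data.frame(sigInfo)
  geneInfo <- as.data.frame(geneInfo)
  for (fl in intersect(c("pr_is_lm", "pr_is_bing"), names(geneInfo))) {
    v <- geneInfo[[fl]]
    geneInfo[[fl]] <- if (is.logical(v)) v else as.integer(v) != 0L
  }
  ord <- match(colnames(zscores), sigInfo$sig_id)
  if (anyNA(ord))
    stop("every profile column needs a sig_info row", call. = FALSE)
  se <- SummarizedExperiment(
    assays = list(zscores = zscores),
    colData = DataFrame(sigInfo[ord, , drop = FALSE], row.names = colnames(zscores)),
    rowData = DataFrame(geneInfo, row.names = rownames(zscores)))
  new("ReferenceCompendium", se)
}

setMethod("show", "ReferenceCompendium", function(object) {
  cat(sprintf(
    "ReferenceCompendium: %d genes (%d landmark) x %d profiles, %d compounds, %d cell lines\n",
    nrow(object), sum(rowData(object)$pr_is_lm), ncol(object),
    length(unique(colData(object)$pert_id)),
    length(unique(colData(object)$cell_id))))
})

#' Query gene signature
#'
#' Ordered, disjoint lists of the most up- and most down-regulated genes of a
#' treatment response (most extreme first), used as the query of the
#' connectivity engine.
#'
#' @slot signatureId single identifier string.
#' @slot upTags character vector, most up-regulated first.
#' @slot downTags character vector, most down-regulated first.
#' @export
setClass("GeneSignature",
  representation(signatureId = "character", upTags = "character",
                 downTags = "character"))

setValidity("GeneSignature", function(object) {
  if (length(object@signatureId) != 1L || is.na(object@signatureId))
    return("signatureId must be a single string")
  if (anyDuplicated(object@upTags)) return("duplicate up tags")
  if (anyDuplicated(object@downTags)) return("duplicate down tags")
  if (length(intersect(object@upTags, object@downTags)))
    return("up and down tags must be disjoint")
  TRUE
})

#' Construct a GeneSignature
#'
#' @param upTags,downTags ordered character vectors of gene ids (most
#'   extreme first); must be disjoint.
#' @param signatureId identifier for the signature.
#' @return A \linkS4class{GeneSignature}.
#' @export
GeneSignature <- function(upTags = character(), downTags = character(),
                          signatureId = "query") {
  new("GeneSignature", signatureId = signatureId,
      upTags = as.character(upTags), downTags = as.character(downTags))
}

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s': %d up tags, %d down tags\n",
              object@signatureId, length(object@upTags),
              length(object@downTags)))
})

#' Gene set collection (GMT-style)
#'
#' @slot setIds unique set identifiers.
#' @slot descriptions one description per set.
#' @slot genes list of character vectors of member genes (deduplicated).
#' @export
setClass("GeneSetCollection",
  representation(setIds = "character", descriptions = "character",
                 genes = "list"))

setValidity("GeneSetCollection", function(object) {
  if (anyDuplicated(object@setIds)) return("set ids must be unique")
  if (length(object@setIds) != length(object@genes) ||
      length(object@setIds) != length(object@descriptions))
    return("setIds, descriptions and genes must have equal length")
  if (any(vapply(object@genes, anyDuplicated, integer(1)) > 0L))
    return("members must be deduplicated within a set")
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param genes named list of character vectors (names are set ids); members
#'   are deduplicated.
#' @param descriptions optional character vector of set descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(genes, descriptions = NULL) {
  genes <- lapply(genes, function(g) unique(as.character(g)))
  new("GeneSetCollection",
      setIds = names(genes) %||% character(),
      descriptions = as.character(descriptions %||% rep("", length(genes))),
      genes = unname(genes))
}

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets, median size %s\n",
              length(object@setIds),
              if (length(object@genes))
                stats::median(lengths(object@genes)) else "NA"))
})

setMethod("length", "GeneSetCollection", function(x) length(x@setIds))
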