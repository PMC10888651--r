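#' Accessors
#'
#' Accessor generics for the package's S4 containers: matrix values and
#' annotation tables of a \linkS4class{GctMatrix}, tag lists of a
#' \linkS4class{GeneSignature}, z-scores and metadata of a
#' \linkS4class{ReferenceCompendium}, and members of a
#' \linkS4class{GeneSetCollection}.
#'
#' @param x the object.
#' @return The corresponding component (matrix, data.frame, character
#'   vector or list).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("values2d", function(x) standardGeneric("values2d"))
#' @rdname accessors
#' @export
setMethod("values2d", "GctMatrix", function(x) x@mat)

#' @rdname accessors
#' @export
setGeneric("rowMeta", function(x) standardGeneric("rowMeta"))
#' @rdname accessors
#' @export
setMethod("rowMeta", "GctMatrix", function(x) x@rowMeta)

#' @rdname accessors
#' @export
setGeneric("colMeta", function(x) standardGeneric("colMeta"))
#' @rdname accessors
#' @export
setMethod("colMeta", "GctMatrix", function(x) x@colMeta)

#' @rdname accessors
#' @export
setGeneric("signatureId", function(x) standardGeneric("signatureId"))
#' @rdname accessors
#' @export
setMethod("signatureId", "GeneSignature", function(x) x@signatureId)

#' @rdname accessors
#' @export
setGeneric("upTags", function(x) standardGeneric("upTags"))
#' @rdname accessors
#' @export
setMethod("upTags", "GeneSignature", function(x) x@upTags)

#' @rdname accessors
#' @export
setGeneric("downTags", function(x) standardGeneric("downTags"))
#' @rdname accessors
#' @export
setMethod("downTags", "GeneSignature", function(x) x@downTags)

#' @rdname accessors
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))
#' @rdname accessors
#' @export
setMethod("zscores", "ReferenceCompendium",
          function(x) SummarizedExperiment::assay(x, "zscores"))

#' @rdname accessors
#' @export
setGeneric("sigInfo", function(x) standardGeneric("sigInfo"))
#' @rdname accessors
#' @export
setMethod("sigInfo", "ReferenceCompendium",
          function(x) as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
#' @rdname accessors
#' @export
setMethod("geneInfo", "ReferenceCompendium",
          function(x) as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) {
  out <- x@genes
  names(out) <- x@setIds
  out
})

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))
#' @rdname accessors
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) {
  out <- x@descriptions
  names(out) <- x@setIds
  out
})
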