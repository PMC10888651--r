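#' Subset a reference compendium by compound, cell line and landmark status
#'
#' Restricts profiles to those matching every supplied selector
#' (\code{pert_id}, \code{pert_iname}, \code{cell_id}; a NULL selector
#' passes everything) and, when \code{landmarkOnly}, restricts genes to the
#' landmark rows (\code{pr_is_lm}). Selections that empty an axis raise an
#' error naming it.
#'
#' @param ref a \linkS4class{ReferenceCompendium}.
#' @param pertIds,pertInames,cellIds optional character selectors.
#' @param landmarkOnly keep only landmark genes (default TRUE).
#' @return The subsetted \linkS4class{ReferenceCompendium}.
#' @export
subsetCompendium <- function(ref, pertIds = NULL, pertInames = NULL,
                             cellIds = NULL, landmarkOnly = TRUE) {
  stopifnot(is(ref, "ReferenceCompendium"))
  si <- sigInfo(ref)
  keep <- rep(TRUE, ncol(ref))
  if (!is.null(pertIds)) {
    miss <- setdiff(pertIds, si$pert_id)
    stopIfNot(length(miss) == 0L, "pert_id(s) not present in compendium: %s",
              paste(miss, collapse = ", "))
    keep <- keep & si$pert_id %in% pertIds
  }
  if (!is.null(pertInames)) {
    miss <- setdiff(pertInames, si$pert_iname)
    stopIfNot(length(miss) == 0L, "pert_iname(s) not present in compendium: %s",
              paste(miss, collapse = ", "))
    keep <- keep & si$pert_iname %in% pertInames
  }
  if (!is.null(cellIds)) {
    miss <- setdiff(cellIds, si$cell_id)
    stopIfNot(length(miss) == 0L, "cell_id(s) not present in compendium: %s",
              paste(miss, collapse = ", "))
    keep <- keep & si$cell_id %in% cellIds
  }
  stopIfNot(any(keep), "profile selection is empty (no matching columns)")
  rows <- if (landmarkOnly) geneInfo(ref)$pr_is_lm else rep(TRUE, nrow(ref))
  stopIfNot(any(rows), "gene selection is empty (no landmark rows)")
  ref[rows, keep]
}

#' Select genes coherently modulated by query and compound
#'
#' For each compound of the (already subsetted) compendium, an up tag of the
#' query signature is retained when its z-score is positive in at least
#' \code{minDirectionFraction} of the compound's profiles; symmetrically a
#' down tag needs a negative z-score in that fraction. A z-score of exactly
#' 0 supports neither direction. Tags absent from the subset's gene rows
#' are skipped (counted in a message). With \code{mode = "pooled"} the
#' support is computed once across all profiles of the subset instead of
#' per compound.
#'
#' @param sig a \linkS4class{GeneSignature}.
#' @param refSubset a \linkS4class{ReferenceCompendium}, typically from
#'   \code{\link{subsetCompendium}}.
#' @param minDirectionFraction support threshold in (0, 1]; default 0.70
#'   (gene kept when coherent in at least 70\% of samples).
#' @param mode \code{"per_compound"} (default) or \code{"pooled"}.
#' @return data.frame with columns \code{query_id}, \code{pert_id},
#'   \code{gene_id}, \code{direction}, \code{support_fraction}; one row per
#'   retained (compound, gene).
#' @export
consensusSelect <- function(sig, refSubset, minDirectionFraction = 0.70,
                            mode = c("per_compound", "pooled")) {
  mode <- match.arg(mode)
  stopIfNot(minDirectionFraction > 0 && minDirectionFraction <= 1,
            "minDirectionFraction must lie in (0, 1]")
  stopIfNot(ncol(refSubset) > 0L, "compendium subset is empty")
  genes <- rownames(refSubset)
  up <- upTags(sig); dn <- downTags(sig)
  missing <- sum(!(up %in% genes)) + sum(!(dn %in% genes))
  if (missing > 0)
    message(sprintf("query '%s': %d signature tag(s) absent from the subset rows, skipped",
                    signatureId(sig), missing))
  up <- up[up %in% genes]
  dn <- dn[dn %in% genes]
  z <- zscores(refSubset)
  si <- sigInfo(refSubset)
  groups <- if (mode == "per_compound")
    split(seq_len(ncol(z)), si$pert_id) else list(all = seq_len(ncol(z)))
  out <- lapply(names(groups), function(pid) {
    cols <- groups[[pid]]
    supUp <- if (length(up))
      rowMeans(z[up, cols, drop = FALSE] > 0) else numeric()
    supDn <- if (length(dn))
      rowMeans(z[dn, cols, drop = FALSE] < 0) else numeric()
    keepU <- supUp >= minDirectionFraction
    keepD <- supDn >= minDirectionFraction
    n <- sum(keepU) + sum(keepD)
    data.frame(query_id = rep(signatureId(sig), n), pert_id = rep(pid, n),
               gene_id = c(up[keepU], dn[keepD]),
               direction = rep(c("up", "down"), c(sum(keepU), sum(keepD))),
               support_fraction = unname(c(supUp[keepU], supDn[keepD])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
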