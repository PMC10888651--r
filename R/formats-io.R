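#' Read a GCT / TSV dense matrix file
#'
#' Parses the tab-separated GCT 1.2 (\code{#1.2} version line) and GCT 1.3
#' (\code{#1.3}) dialects, or a plain TSV matrix with a header row. GCT 1.3
#' row/column metadata blocks are captured as annotation data.frames. Any of
#' \code{NA}/\code{NaN}/empty is read as missing.
#'
#' @param path file to read.
#' @param dialect \code{"auto"} (default, from the version line) or one of
#'   \code{"gct1.2"}, \code{"gct1.3"}, \code{"tsv"}.
#' @return A \linkS4class{GctMatrix}.
#' @export
readGct <- function(path, dialect = c("auto", "gct1.2", "gct1.3", "tsv")) {
  dialect <- match.arg(dialect)
  stopIfNot(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  stopIfNot(length(lines) >= 1L, "empty file: %s", path)
  if (dialect == "auto") {
    dialect <- if (identical(lines[1], "#1.2")) "gct1.2"
      else if (identical(lines[1], "#1.3")) "gct1.3"
      else "tsv"
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "tsv") return(parseTsvMatrix(fields))
  expect <- if (dialect == "gct1.2") "#1.2" else "#1.3"
  stopIfNot(identical(lines[1], expect),
            "malformed GCT header at line 1: expected '%s', got '%s'",
            expect, lines[1])
  dims <- suppressWarnings(as.integer(fields[[2]]))
  if (dialect == "gct1.2") {
    stopIfNot(length(dims) == 2L && !anyNA(dims),
              "malformed GCT dimension line at line 2")
    parseGct12(fields, dims)
  } else {
    stopIfNot(length(dims) == 4L && !anyNA(dims),
              "malformed GCT dimension line at line 2")
    parseGct13(fields, dims)
  }
}

parseGct12 <- function(fields, dims) {
  nr <- dims[1]; nc <- dims[2]
  hdr <- fields[[3]]
  stopIfNot(length(hdr) == nc + 2L,
            "malformed GCT column header at line 3: expected %d fields, got %d",
            nc + 2L, length(hdr))
  colIds <- hdr[-(1:2)]
  stopIfNot(length(fields) >= nr + 3L, "GCT truncated: expected %d data rows", nr)
  rowIds <- character(nr); desc <- character(nr)
  mat <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    f <- fields[[i + 3L]]
    stopIfNot(length(f) == nc + 2L, "ragged GCT data row at line %d", i + 3L)
    rowIds[i] <- f[1]; desc[i] <- f[2]
    mat[i, ] <- parseValues(f[-(1:2)])
  }
  checkUniqueIds(rowIds, colIds)
  dimnames(mat) <- list(rowIds, colIds)
  GctMatrix(mat, rowMeta = data.frame(Description = desc,
                                      stringsAsFactors = FALSE))
}

parseGct13 <- function(fields, dims) {
  nr <- dims[1]; nc <- dims[2]; nrm <- dims[3]; ncm <- dims[4]
  hdr <- fields[[3]]
  stopIfNot(length(hdr) == 1L + nrm + nc,
            "malformed GCT column header at line 3: expected %d fields, got %d",
            1L + nrm + nc, length(hdr))
  rmNames <- if (nrm) hdr[2:(1 + nrm)] else character()
  colIds <- hdr[(2 + nrm):(1 + nrm + nc)]
  colMeta <- data.frame(row.names = seq_len(nc))
  for (k in seq_len(ncm)) {
    f <- fields[[3L + k]]
    stopIfNot(length(f) == 1L + nrm + nc,
              "ragged GCT column-metadata row at line %d", 3L + k)
    colMeta[[f[1]]] <- utils::type.convert(f[(2 + nrm):(1 + nrm + nc)],
                                           as.is = TRUE)
  }
  rowIds <- character(nr)
  rowMeta <- data.frame(row.names = seq_len(nr))
  for (nm in rmNames) rowMeta[[nm]] <- rep(NA_character_, nr)
  mat <- matrix(NA_real_, nr, nc)
  off <- 3L + ncm
  stopIfNot(length(fields) >= off + nr, "GCT truncated: expected %d data rows", nr)
  for (i in seq_len(nr)) {
    f <- fields[[off + i]]
    stopIfNot(length(f) == 1L + nrm + nc, "ragged GCT data row at line %d", off + i)
    rowIds[i] <- f[1]
    if (nrm) for (k in seq_len(nrm)) rowMeta[[rmNames[k]]][i] <- f[1 + k]
    mat[i, ] <- parseValues(f[(2 + nrm):(1 + nrm + nc)])
  }
  for (nm in rmNames)
    rowMeta[[nm]] <- utils::type.convert(rowMeta[[nm]], as.is = TRUE)
  checkUniqueIds(rowIds, colIds)
  dimnames(mat) <- list(rowIds, colIds)
  GctMatrix(mat, rowMeta = rowMeta, colMeta = colMeta)
}

parseTsvMatrix <- function(fields) {
  hdr <- fields[[1]]
  stopIfNot(length(hdr) >= 2L, "malformed TSV header at line 1")
  colIds <- hdr[-1]
  nr <- length(fields) - 1L
  rowIds <- character(nr)
  mat <- matrix(NA_real_, nr, length(colIds))
  for (i in seq_len(nr)) {
    f <- fields[[i + 1L]]
    stopIfNot(length(f) == length(colIds) + 1L, "ragged TSV row at line %d", i + 1L)
    rowIds[i] <- f[1]
    mat[i, ] <- parseValues(f[-1])
  }
  checkUniqueIds(rowIds, colIds)
  dimnames(mat) <- list(rowIds, colIds)
  GctMatrix(mat)
}

checkUniqueIds <- function(rowIds, colIds) {
  if (anyDuplicated(rowIds))
    stop("duplicate row id(s): ",
         paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colIds))
    stop("duplicate column id(s): ",
         paste(unique(colIds[duplicated(colIds)]), collapse = ", "),
         call. = FALSE)
}

#' Write a GCT / TSV dense matrix file
#'
#' Inverse of \code{\link{readGct}}: emits standard-conformant GCT 1.2 or
#' 1.3, or a plain TSV matrix. Missing values are written as \code{NA};
#' numeric values are written at full double precision so a read/write
#' round-trip is lossless.
#'
#' @param m a \linkS4class{GctMatrix}.
#' @param path output file.
#' @param dialect one of \code{"gct1.2"} (default), \code{"gct1.3"},
#'   \code{"tsv"}. GCT 1.2 keeps only a \code{Description} row-annotation
#'   column (filled with \code{"na"} when absent); GCT 1.3 writes all
#'   row/column annotations.
#' @return \code{path}, invisibly.
#' @export
writeGct <- function(m, path, dialect = c("gct1.2", "gct1.3", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(is(m, "GctMatrix"))
  mat <- m@mat
  nr <- nrow(mat); nc <- ncol(mat)
  lines <- switch(dialect,
    "gct1.2" = {
      desc <- if ("Description" %in% names(m@rowMeta))
        as.character(m@rowMeta$Description) else rep("na", nr)
      c("#1.2",
        paste(nr, nc, sep = "\t"),
        paste(c("NAME", "Description", colnames(mat)), collapse = "\t"),
        vapply(seq_len(nr), function(i)
          paste(c(rownames(mat)[i], desc[i], formatValues(mat[i, ])),
                collapse = "\t"), character(1)))
    },
    "gct1.3" = {
      rm <- m@rowMeta; cm <- m@colMeta
      nrm <- ncol(rm); ncm <- ncol(cm)
      hdr <- paste(c("id", names(rm), colnames(mat)), collapse = "\t")
      cmLines <- vapply(seq_len(ncm), function(k)
        paste(c(names(cm)[k], rep("na", nrm), as.character(cm[[k]])),
              collapse = "\t"), character(1))
      dataLines <- vapply(seq_len(nr), function(i) {
        rmv <- if (nrm) vapply(seq_len(nrm),
                               function(k) as.character(rm[[k]][i]),
                               character(1)) else character()
        paste(c(rownames(mat)[i], rmv, formatValues(mat[i, ])), collapse = "\t")
      }, character(1))
      c("#1.3", paste(nr, nc, nrm, ncm, sep = "\t"), hdr, cmLines, dataLines)
    },
    "tsv" = {
      c(paste(c("id", colnames(mat)), collapse = "\t"),
        vapply(seq_len(nr), function(i)
          paste(c(rownames(mat)[i], formatValues(mat[i, ])), collapse = "\t"),
          character(1)))
    })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: set id, description, then member genes.
#' Duplicate members within a line are collapsed; empty lines are skipped.
#'
#' @param path GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineNo <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", lineNo[bad[1]]),
         call. = FALSE)
  ids <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- ids
  GeneSetCollection(genes,
                    descriptions = vapply(fields, `[`, character(1), 2))
}

#' Write a GMT gene-set file
#'
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path) {
  stopifnot(is(sets, "GeneSetCollection"))
  lines <- vapply(seq_along(sets@setIds), function(i)
    paste(c(sets@setIds[i], sets@descriptions[i], sets@genes[[i]]),
          collapse = "\t"), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a metadata TSV (sig_info / gene_info conventions)
#'
#' Reads a tab-separated annotation table with a header row and validates
#' that the required columns are present. The GSE92742-convention 0/1 flag
#' columns \code{pr_is_lm} and \code{pr_is_bing} are converted to logical
#' when present.
#'
#' @param path TSV file with header.
#' @param requiredColumns character vector of column names that must exist.
#' @return A data.frame.
#' @export
readMetadataTable <- function(path, requiredColumns = character()) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(requiredColumns, names(tab))
  if (length(miss))
    stop("metadata table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (fl in intersect(c("pr_is_lm", "pr_is_bing"), names(tab)))
    tab[[fl]] <- as.logical(as.integer(tab[[fl]]))
  tab
}

#' Read/write a reference compendium directory
#'
#' A compendium on disk is a directory holding \code{zscores.gct} (GCT text),
#' \code{sig_info.tsv} and \code{gene_info.tsv}.
#'
#' @param dir directory path.
#' @return \code{readCompendium}: a \linkS4class{ReferenceCompendium};
#'   \code{writeCompendium}: \code{dir}, invisibly.
#' @export
readCompendium <- function(dir) {
  stopIfNot(dir.exists(dir), "compendium directory not found: %s", dir)
  g <- readGct(file.path(dir, "zscores.gct"))
  si <- readMetadataTable(file.path(dir, "sig_info.tsv"),
    requiredColumns = c("sig_id", "pert_id", "pert_iname", "pert_type",
                        "cell_id"))
  gi <- readMetadataTable(file.path(dir, "gene_info.tsv"),
    requiredColumns = c("pr_gene_id", "pr_is_lm"))
  ord <- match(rownames(values2d(g)), gi$pr_gene_id)
  stopIfNot(!anyNA(ord), "gene_info does not cover every matrix gene")
  ReferenceCompendium(values2d(g), si, gi[ord, , drop = FALSE])
}

#' @param ref a \linkS4class{ReferenceCompendium}.
#' @rdname readCompendium
#' @export
writeCompendium <- function(ref, dir) {
  stopifnot(is(ref, "ReferenceCompendium"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGct(GctMatrix(zscores(ref)), file.path(dir, "zscores.gct"))
  writeTsv(sigInfo(ref), file.path(dir, "sig_info.tsv"))
  gi <- geneInfo(ref)
  for (fl in intersect(c("pr_is_lm", "pr_is_bing"), names(gi)))
    gi[[fl]] <- as.integer(gi[[fl]])
  writeTsv(gi, file.path(dir, "gene_info.tsv"))
  invisible(dir)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
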