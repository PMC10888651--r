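#' Pipeline configuration
#'
#' Assembles the configuration driving \code{\link{runPipeline}}. Every
#' analysis default equals the workflow's canonical thresholds: DEG q-value
#' cutoff 0.05, 150 tags per direction / 300 total, top-10 compound
#' selection, connection threshold |tau| > 90, 70\% direction-consensus
#' fraction, enrichment q cutoff 0.05, landmark-only consensus space.
#'
#' @param experiments list of experiment entries, each a list with
#'   \code{name}, \code{expression} (GCT/TSV matrix path) and
#'   \code{groups} (TSV with columns \code{sample_id}, \code{group}).
#' @param reference compendium directory (see \code{\link{readCompendium}}).
#' @param pathways optional GMT file for enrichment.
#' @param outDir output directory.
#' @param normalize quantile-normalize expression matrices first.
#' @param degMethod differential-expression method.
#' @param qCutoff,maxPerDirection,maxTotal,allowedFilterOrder,k,tauCutoff
#'   stage parameters (see the stage functions).
#' @param minDirectionFraction,consensusMode,landmarkOnly,enrichCutoff
#'   stage parameters (see the stage functions).
#' @param cellIds optional cell-line selection for the consensus subset
#'   (default: all cell lines of the reference).
#' @param useBingFilter restrict signature tags to the reference's BING
#'   gene space (\code{pr_is_bing}).
#' @param seed integer seed recorded in the manifest.
#' @return A named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(experiments, reference, pathways = NULL,
                           outDir = "sigconn_out", normalize = TRUE,
                           degMethod = "moderated_t", qCutoff = 0.05,
                           maxPerDirection = 150, maxTotal = 300,
                           allowedFilterOrder = "after_selection",
                           k = 10, tauCutoff = 90,
                           minDirectionFraction = 0.70,
                           consensusMode = "per_compound",
                           landmarkOnly = TRUE, enrichCutoff = 0.05,
                           cellIds = NULL, useBingFilter = TRUE, seed = 1) {
  cfg <- mget(names(formals()), envir = environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @return \code{readPipelineConfig}: a \code{pipelineConfig};
#'   \code{writePipelineConfig}: \code{path}, invisibly.
#' @export
readPipelineConfig <- function(path) {
  stopIfNot(file.exists(path), "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @param cfg a \code{pipelineConfig}.
#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

withStage <- function(stage, code) {
  tryCatch(code, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

readExperiment <- function(entry) {
  g <- readGct(entry$expression)
  grp <- readMetadataTable(entry$groups,
                           requiredColumns = c("sample_id", "group"))
  mat <- values2d(g)
  ord <- match(colnames(mat), grp$sample_id)
  stopIfNot(!anyNA(ord), "groups table does not cover every sample")
  ExpressionExperiment(mat, grp$group[ord])
}

#' Run the full signature-connectivity workflow
#'
#' Executes the five workflow steps end to end for every configured
#' experiment: differential expression and DEG filtering, signature
#' construction, connectivity scoring against the reference compendium,
#' top-k compound selection, consensus gene extraction on the
#' landmark-subsetted compendium, then correlation/Ward clustering of the
#' dataset vectors (when >= 2 experiments) and hypergeometric pathway
#' enrichment of the per-compound consensus genes (when a GMT is
#' configured). All stage outputs are written as text tables under
#' \code{cfg$outDir} together with a JSON run manifest (package version,
#' seed, input MD5 hashes, per-stage row counts, top compound per query).
#' Outputs are byte-identical on rerun with the same configuration. Any
#' stage failure aborts with the stage name and cause.
#'
#' @param cfg a \code{pipelineConfig} (or path to a YAML config).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(vapply(cfg$experiments, `[[`, character(1), "expression"),
              vapply(cfg$experiments, `[[`, character(1), "groups"))
  manifest <- list(
    package = "sigconn",
    version = as.character(utils::packageVersion("sigconn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = cfg[c("qCutoff", "maxPerDirection", "maxTotal", "k",
                       "tauCutoff", "minDirectionFraction", "enrichCutoff")],
    stages = list())

  ref <- withStage("connect", {
    stopIfNot(!is.null(cfg$reference) && dir.exists(cfg$reference),
              "reference directory not found: %s", cfg$reference %||% "<unset>")
    readCompendium(cfg$reference)
  })
  inputs <- c(inputs, file.path(cfg$reference,
                                c("zscores.gct", "sig_info.tsv",
                                  "gene_info.tsv")))
  if (!is.null(cfg$pathways)) inputs <- c(inputs, cfg$pathways)
  manifest$input_md5 <- as.list(tools::md5sum(inputs))
  allowed <- if (isTRUE(cfg$useBingFilter) &&
                   "pr_is_bing" %in% names(geneInfo(ref)))
    rownames(ref)[geneInfo(ref)$pr_is_bing] else NULL

  degTables <- list(); signatures <- list()
  for (ex in cfg$experiments) {
    nm <- ex$name
    expr <- withStage("deg", readExperiment(ex))
    degs <- withStage("deg", {
      if (isTRUE(cfg$normalize)) {
        mat <- quantileNormalize(SummarizedExperiment::assay(expr))
        expr <- ExpressionExperiment(mat,
          SummarizedExperiment::colData(expr)$group)
      }
      fitDifferential(expr, method = cfg$degMethod)
    })
    filt <- filterDegs(degs, cfg$qCutoff)
    writeTsv(filt, file.path(cfg$outDir, paste0("degs_", nm, ".tsv")))
    sig <- withStage("signature",
      buildSignature(filt, maxPerDirection = cfg$maxPerDirection,
                     maxTotal = cfg$maxTotal, allowedGenes = allowed,
                     allowedFilterOrder = cfg$allowedFilterOrder,
                     signatureId = nm))
    writeSignature(sig, file.path(cfg$outDir, paste0("signature_", nm, ".txt")))
    degTables[[nm]] <- filt
    signatures[[nm]] <- sig
    manifest$stages$deg[[nm]] <- list(n_deg = nrow(filt),
                                      n_up = length(upTags(sig)),
                                      n_down = length(downTags(sig)))
  }

  connTables <- list(); topTables <- list()
  for (nm in names(signatures)) {
    conn <- withStage("connect",
      queryCompendium(signatures[[nm]], ref, tauCutoff = cfg$tauCutoff))
    writeTsv(conn, file.path(cfg$outDir, paste0("connectivity_", nm, ".tsv")))
    top <- topK(conn, cfg$k)
    connTables[[nm]] <- conn
    topTables[[nm]] <- top
    manifest$stages$connect[[nm]] <- list(
      n_records = nrow(conn), n_connected = sum(conn$connected),
      top_pert_id = top$pert_id[1], top_tau = top$tau[1])
  }
  writeGct(heatmapMatrix(topTables, k = cfg$k),
           file.path(cfg$outDir, "heatmap_tau.gct"), dialect = "gct1.3")

  consensus <- list()
  for (nm in names(signatures)) {
    cons <- withStage("consensus", {
      sub <- subsetCompendium(ref,
        pertIds = unique(topTables[[nm]]$pert_id),
        pertInames = unique(topTables[[nm]]$pert_iname),
        cellIds = cfg$cellIds, landmarkOnly = cfg$landmarkOnly)
      consensusSelect(signatures[[nm]], sub,
                      minDirectionFraction = cfg$minDirectionFraction,
                      mode = cfg$consensusMode)
    })
    consensus[[nm]] <- cons
    manifest$stages$consensus[[nm]] <- list(n_genes = nrow(cons))
  }
  writeTsv(do.call(rbind, consensus), file.path(cfg$outDir, "consensus.tsv"))

  if (length(signatures) >= 2L) {
    withStage("cluster", {
      genes <- sort(unique(unlist(lapply(consensus, `[[`, "gene_id"))))
      if (length(genes) >= 2L) {
        vectors <- vapply(names(degTables), function(nm) {
          v <- stats::setNames(rep(0, length(genes)), genes)
          d <- degTables[[nm]]
          hit <- intersect(genes, d$gene_id)
          v[hit] <- d$logFC[match(hit, d$gene_id)]
          v
        }, numeric(length(genes)))
        cl <- wardCluster(vectors)
        corr <- tryCatch(signatureCorrelation(vectors), error = function(e) NULL)
        jsonlite::write_json(
          list(labels = as.list(cl$labels), n_clusters = cl$nClusters,
               heights = cl$heights,
               correlation = if (is.null(corr)) NULL else as.data.frame(corr)),
          file.path(cfg$outDir, "cluster.json"), auto_unbox = TRUE, digits = NA)
        manifest$stages$cluster <- list(n_clusters = cl$nClusters,
                                         n_genes = length(genes))
      }
    })
  }

  if (!is.null(cfg$pathways)) {
    withStage("enrich", {
      sets <- readGmt(cfg$pathways)
      universe <- if (isTRUE(cfg$landmarkOnly))
        rownames(ref)[geneInfo(ref)$pr_is_lm] else rownames(ref)
      byCompound <- split(do.call(rbind, consensus)$gene_id,
                          do.call(rbind, consensus)$pert_id)
      enr <- lapply(byCompound, function(g)
        hypergeomEnrich(unique(g), sets, universe,
                        qCutoff = cfg$enrichCutoff))
      combined <- do.call(rbind, Map(function(nm, e)
        cbind(pert_id = nm, e, stringsAsFactors = FALSE), names(enr), enr))
      writeTsv(combined, file.path(cfg$outDir, "enrichment.tsv"))
      writeGct(compoundPathwayMatrix(enr, qCutoff = cfg$enrichCutoff),
               file.path(cfg$outDir, "pathway_by_compound.gct"),
               dialect = "gct1.3")
      manifest$stages$enrich <- list(
        n_compounds = length(enr),
        n_significant = sum(vapply(enr, function(e) sum(e$significant),
                                   integer(1))))
    })
  }

  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
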