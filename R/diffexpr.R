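#' Quantile-normalize an expression matrix
#'
#' Forces every column to share the same value distribution: the vector of
#' row-wise means of the column-sorted values. Within-column rank order is
#' preserved; ties receive the mean of their span.
#'
#' @param mat numeric genes x samples matrix.
#' @return The normalized matrix, same dimnames.
#' @export
quantileNormalize <- function(mat) {
  stopIfNot(is.matrix(mat) && ncol(mat) >= 1L && nrow(mat) >= 1L,
            "a non-empty numeric matrix is required")
  allNA <- vapply(seq_len(ncol(mat)), function(j) all(is.na(mat[, j])),
                  logical(1))
  stopIfNot(!any(allNA), "column(s) with all values missing: %s",
            paste(colnames(mat)[allNA] %||% which(allNA), collapse = ", "))
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-gene differential expression (treated vs control)
#'
#' Computes, for every gene, the base-two log fold change
#' (mean treated minus mean control), a two-sample t-statistic on the pooled
#' variance, two-sided p-values and Benjamini-Hochberg q-values.
#'
#' With \code{method = "moderated_t"} the per-gene pooled variances
#' \eqn{s_g^2} (on \eqn{d_g = n_1 + n_2 - 2} df) are shrunk toward a common
#' prior \eqn{s_0^2} on \eqn{d_0} df,
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and the moderated t uses \eqn{\tilde s_g} on \eqn{d_g + d_0} df. The
#' hyperparameters are estimated by method of moments on the log sample
#' variances: writing \eqn{z_g = \log s_g^2}, under the scaled-chi-square
#' model \eqn{E[z_g]} and \eqn{Var[z_g]} involve digamma/trigamma terms in
#' \eqn{d_g/2} and \eqn{d_0/2}, so \eqn{d_0} solves
#' \eqn{trigamma(d_0/2) = Var(z) - trigamma(d_g/2)} (root-found on the
#' monotone trigamma) and \eqn{s_0^2} follows from the mean. When the
#' observed variance of \eqn{z} does not exceed the sampling term the prior
#' is effectively infinite and all genes share \eqn{s_0^2}.
#'
#' @param expr an \linkS4class{ExpressionExperiment}.
#' @param method \code{"moderated_t"} (default) or \code{"ordinary_t"}.
#' @param d0 optional override of the prior degrees of freedom (mainly for
#'   studying the \eqn{d_0 \to 0} limit, where the moderated t reduces to
#'   the ordinary t).
#' @return A DEG table: data.frame with columns \code{gene_id},
#'   \code{logFC}, \code{t}, \code{p}, \code{q}, one row per gene in input
#'   order.
#' @export
fitDifferential <- function(expr, method = c("moderated_t", "ordinary_t"),
                            d0 = NULL) {
  method <- match.arg(method)
  stopifnot(is(expr, "ExpressionExperiment"))
  mat <- SummarizedExperiment::assay(expr)
  grp <- SummarizedExperiment::colData(expr)$group
  ctl <- mat[, grp == "control", drop = FALSE]
  trt <- mat[, grp == "treated", drop = FALSE]
  n1 <- ncol(ctl); n2 <- ncol(trt)
  dg <- n1 + n2 - 2L
  logFC <- rowMeans(trt) - rowMeans(ctl)
  ss1 <- rowSums((ctl - rowMeans(ctl))^2)
  ss2 <- rowSums((trt - rowMeans(trt))^2)
  s2 <- (ss1 + ss2) / dg
  seFactor <- sqrt(1 / n1 + 1 / n2)

  if (method == "moderated_t") {
    prior <- if (is.null(d0)) {
      estimateVariancePrior(s2, dg)
    } else {
      mom <- estimateVariancePrior(s2, dg)
      if (is.null(mom)) NULL else list(d0 = d0, s02 = mom$s02)
    }
    if (is.null(prior)) {
      warning("variance prior not estimable; falling back to ordinary_t")
      method <- "ordinary_t"
    } else {
      s2tilde <- if (is.infinite(prior$d0)) rep(prior$s02, length(s2))
        else (prior$d0 * prior$s02 + dg * s2) / (prior$d0 + dg)
      tstat <- logFC / (sqrt(s2tilde) * seFactor)
      df <- dg + prior$d0
    }
  }
  if (method == "ordinary_t") {
    tstat <- logFC / (sqrt(s2) * seFactor)
    df <- dg
  }
  tstat[logFC == 0 & !is.finite(tstat)] <- 0  # 0/0 when a gene is flat
  p <- 2 * stats::pt(-abs(tstat), df = df)
  data.frame(gene_id = rownames(mat), logFC = logFC, t = tstat, p = p,
             q = benjaminiHochberg(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior on
# log sample variances. Returns list(d0, s02) or NULL when inestimable.
estimateVariancePrior <- function(s2, dg) {
  z <- log(s2[s2 > 0 & is.finite(s2)])
  if (length(z) < 2L) return(NULL)
  # z_g = log s0^2 + [digamma(dg/2) - log(dg/2)] - [digamma(d0/2) - log(d0/2)]
  #       + noise with variance trigamma(dg/2) + trigamma(d0/2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  t2 <- stats::var(z) - trigamma(dg / 2)
  if (is.na(t2) || t2 <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigammaInverse(t2)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

# Inverse of trigamma on (0, Inf); trigamma is strictly decreasing.
trigammaInverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))          # trigamma(x) ~ 1/x^2 as x -> 0
  lo <- 1e-8; hi <- 1e8
  stats::uniroot(function(x) trigamma(x) - y, c(lo, hi), tol = 1e-10)$root
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} \min(1, m
#' p_{(j)}/j)} over the sorted p-values; order-preserving and monotone.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same order as \code{p}.
#' @export
benjaminiHochberg <- function(p) {
  stopIfNot(is.numeric(p), "p must be numeric")
  ok <- !is.na(p)
  stopIfNot(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter a DEG table at a q-value cutoff
#'
#' Retains rows with \code{q < qCutoff} (strict) and sorts by descending
#' logFC; ties are broken by ascending q, then gene id.
#'
#' @param degs DEG table from \code{\link{fitDifferential}}.
#' @param qCutoff q-value cutoff (default 0.05).
#' @return The filtered, sorted DEG table.
#' @export
filterDegs <- function(degs, qCutoff = 0.05) {
  keep <- !is.na(degs$q) & degs$q < qCutoff
  out <- degs[keep, , drop = FALSE]
  out <- out[order(-out$logFC, out$q, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
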