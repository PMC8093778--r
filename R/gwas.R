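# MAGMA-style gene and gene-set analysis from GWAS summary statistics:
# SNP-to-gene mapping, LD-aware gene p-values from the mean-chi-square
# statistic, gene-gene correlation, competitive gene-set regression,
# within-set gene significance, and Fisher/FDR ontology enrichment.

#' Map SNPs to genes
#'
#' A SNP is annotated to every gene whose body (BED-like 0-based half-open
#' interval, optionally extended by \code{windowBp} on both sides) contains
#' its 1-based position; multi-gene SNPs are kept in all overlapping genes.
#'
#' @param summary GWAS summary data.frame (SNP, CHR, BP, P, N).
#' @param geneLoc data.frame chrom, start, end, gene (0-based half-open).
#' @param windowBp symmetric annotation window in bp (default 0: gene body
#'   only).
#' @return named list, gene -> character vector of SNP ids.
#' @export
mapSnpsToGenes <- function(summary, geneLoc, windowBp = 0L) {
  out <- setNames(vector("list", nrow(geneLoc)), geneLoc$gene)
  for (ch in unique(geneLoc$chrom)) {
    g <- geneLoc[geneLoc$chrom == ch, , drop = FALSE]
    s <- summary[summary$CHR == ch, , drop = FALSE]
    if (!nrow(s)) { out[g$gene] <- list(character(0)); next }
    gi <- IRanges::IRanges(start = g$start + 1L - windowBp,
                           end = g$end + windowBp)
    si <- IRanges::IRanges(start = s$BP, width = 1L)
    ov <- IRanges::findOverlaps(si, gi)
    for (j in seq_len(nrow(g))) {
      hits <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]
      out[[g$gene[j]]] <- s$SNP[hits]
    }
  }
  out
}

#' Upper-tail probability of a weighted sum of chi-squares
#'
#' \eqn{P(\sum_i w_i \chi^2_1 > q)}.  Default is Imhof's numerical
#' inversion of the characteristic function (accurate over the whole
#' range); \code{method = "satterthwaite"} uses two-moment scaled
#' chi-square matching (fast, approximate in the mid-tail).
#'
#' @param q observed statistic.
#' @param weights positive weights (eigenvalues of the LD matrix over K).
#' @param method "imhof" or "satterthwaite".
#' @return tail probability, clamped to (1e-300, 1].
#' @export
weightedChisqP <- function(q, weights, method = c("imhof", "satterthwaite")) {
  method <- match.arg(method)
  w <- weights[weights > 1e-12]
  if (!length(w)) stop("no positive weights")
  if (length(w) == 1L) return(pchisq(q / w, df = 1, lower.tail = FALSE))
  if (method == "satterthwaite") {
    a <- sum(w^2) / sum(w)
    g <- sum(w)^2 / sum(w^2)
    p <- pchisq(q / a, df = g, lower.tail = FALSE)
  } else {
    integrand <- function(u) {
      theta <- 0.5 * colSums(atan(outer(w, u))) - 0.5 * q * u
      rho <- exp(0.25 * colSums(log1p(outer(w^2, u^2))))
      sin(theta) / (u * rho)
    }
    val <- integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12,
                     stop.on.error = FALSE)$value
    p <- 0.5 + val / pi
  }
  min(max(p, 1e-300), 1)
}

#' LD-aware gene analysis from summary statistics
#'
#' Per-gene association test in MAGMA's summary-statistic form: SNP
#' p-values become 1-df chi-square statistics, the gene statistic is their
#' mean, and its null distribution is the weighted sum of independent
#' chi-squares whose weights are the eigenvalues of the gene's reference-
#' panel LD correlation matrix divided by the SNP count.  The gene p-value
#' is the upper-tail probability of that null (Imhof inversion by
#' default), and \eqn{Z = \Phi^{-1}(1 - p)}.  Covariates for the
#' competitive gene-set regression (gene length, SNP count, SNP density,
#' mean minor-allele count) are computed alongside.
#'
#' @param summary GWAS summary data.frame (SNP, CHR, BP, P, N).
#' @param panel individuals x SNPs dosage matrix (0/1/2), SNP ids as
#'   column names.
#' @param mapping gene -> SNP id list from \code{\link{mapSnpsToGenes}}.
#' @param geneLoc optional gene location table for gene lengths; without
#'   it the SNP span is used.
#' @param method tail method, "imhof" (default) or "satterthwaite".
#' @return data.frame: gene, nSnps, stat, p, z, lengthBp, density, meanMac.
#'   SNPs absent from the panel are dropped with a warning; genes left
#'   without SNPs are omitted.
#' @export
geneAnalysis <- function(summary, panel, mapping, geneLoc = NULL,
                         method = c("imhof", "satterthwaite")) {
  method <- match.arg(method)
  if (nrow(panel) < 50L) stop("reference panel needs >= 50 individuals")
  snpP <- setNames(summary$P, summary$SNP)
  snpBP <- setNames(summary$BP, summary$SNP)
  missing <- setdiff(unique(unlist(mapping)), colnames(panel))
  if (length(missing))
    warning(length(missing), " mapped SNP(s) absent from the panel; dropped")
  nGenes <- length(mapping)
  rows <- list()
  for (g in names(mapping)) {
    snps <- intersect(mapping[[g]], colnames(panel))
    snps <- snps[snps %in% names(snpP)]
    if (!length(snps)) next
    chi <- qchisq(pmin(pmax(snpP[snps], 1e-300), 1), df = 1,
                  lower.tail = FALSE)
    K <- length(snps)
    stat <- mean(chi)
    if (K == 1L) {
      p <- snpP[snps]
    } else {
      gmat <- panel[, snps, drop = FALSE]
      sds <- apply(gmat, 2L, sd)
      ld <- diag(K)
      ok <- sds > 0
      if (sum(ok) > 1L) ld[ok, ok] <- cor(gmat[, ok, drop = FALSE])
      ev <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
      p <- weightedChisqP(stat, pmax(ev, 0) / K, method = method)
    }
    # clamp so Z is finite at p -> 1 (logged via attribute below); the
    # floor of 100 keeps the clamp inert for tiny gene sets
    pClamped <- min(p, 1 - 1 / (2 * max(nGenes, 100L)))
    z <- qnorm(pClamped, lower.tail = FALSE)
    lengthBp <- if (!is.null(geneLoc) && g %in% geneLoc$gene) {
      gl <- geneLoc[geneLoc$gene == g, ][1L, ]; gl$end - gl$start
    } else max(snpBP[snps]) - min(snpBP[snps]) + 1L
    mac <- apply(panel[, snps, drop = FALSE], 2L, function(col)
      min(sum(col), 2L * length(col) - sum(col)))
    rows[[g]] <- data.frame(
      gene = g, nSnps = K, stat = stat, p = as.numeric(p), z = z,
      lengthBp = as.numeric(lengthBp), density = K / as.numeric(lengthBp),
      meanMac = mean(mac), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "nClamped") <- sum(out$p > 1 - 1 / (2 * max(nGenes, 100L)))
  out
}

#' Gene-gene correlation from panel LD
#'
#' Correlation between gene statistics induced by cross-gene LD,
#' approximated from squared SNP correlations:
#' \eqn{corr(g, h) = S_{gh} / \sqrt{S_{gg} S_{hh}}} with
#' \eqn{S_{gh} = \sum_{i \in g, j \in h} r^2_{ij}} in the reference panel.
#' Genes on different chromosomes are uncorrelated by construction.
#'
#' @param panel individuals x SNPs dosage matrix.
#' @param mapping gene -> SNP id list.
#' @param geneChrom named gene -> chromosome vector (genes on different
#'   chromosomes get 0 without touching the panel).
#' @return gene x gene correlation matrix with unit diagonal.
#' @export
geneGeneCorrelation <- function(panel, mapping, geneChrom) {
  genes <- names(mapping)
  n <- length(genes)
  out <- diag(n); dimnames(out) <- list(genes, genes)
  snps <- lapply(mapping, intersect, y = colnames(panel))
  selfS <- vapply(genes, function(g) {
    s <- snps[[g]]
    if (!length(s)) return(NA_real_)
    r <- suppressWarnings(cor(panel[, s, drop = FALSE]))
    r[is.na(r)] <- 0; diag(r) <- 1
    sum(r^2)
  }, 0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (geneChrom[genes[i]] != geneChrom[genes[j]]) next
    si <- snps[[genes[i]]]; sj <- snps[[genes[j]]]
    if (!length(si) || !length(sj)) next
    r <- suppressWarnings(cor(panel[, si, drop = FALSE],
                              panel[, sj, drop = FALSE]))
    r[is.na(r)] <- 0
    out[i, j] <- out[j, i] <- sum(r^2) / sqrt(selfS[genes[i]] * selfS[genes[j]])
  }
  out
}

#' Competitive gene-set test
#'
#' Generalized least squares regression of gene Z-scores on a set-
#' membership indicator plus confounder covariates (log gene length, log
#' SNP count, log SNP density, mean minor-allele count), with the
#' gene-gene correlation matrix as the error correlation.  Tests one-sided
#' whether genes inside the set are more strongly associated than genes
#' outside it.  Exactly collinear covariates are dropped with a warning;
#' a singular correlation matrix gets a 1e-6 ridge on the diagonal.
#'
#' @param records gene analysis data.frame from \code{\link{geneAnalysis}}.
#' @param setGenes character vector: the gene set (non-empty strict subset
#'   of the analyzed genes).
#' @param geneCorr optional gene x gene correlation matrix (NULL = OLS,
#'   i.e. independent genes).
#' @param nSets number of sets tested, for the Bonferroni correction
#'   (default 1).
#' @param ridge diagonal jitter added when the correlation factorization
#'   fails (default 1e-6).
#' @return data.frame: set size, beta (indicator coefficient), se, one-
#'   sided p, padj = min(1, p * nSets).
#' @export
competitiveSetTest <- function(records, setGenes, geneCorr = NULL,
                               nSets = 1L, ridge = 1e-6) {
  inSet <- records$gene %in% setGenes
  if (!any(inSet)) stop("gene set is empty within the analyzed genes")
  if (all(inSet)) stop("gene set must be a strict subset of the analyzed genes")
  X <- cbind(intercept = 1, set = as.numeric(inSet),
             logLength = log(records$lengthBp),
             logNsnps = log(records$nSnps),
             logDensity = log(records$density),
             meanMac = records$meanMac)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    warning("dropping collinear covariate(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  y <- records$z
  if (!is.null(geneCorr)) {
    cn <- colnames(X)
    R <- geneCorr[records$gene, records$gene]
    L <- tryCatch(chol(R), error = function(e) chol(R + diag(ridge, nrow(R))))
    X <- backsolve(L, X, transpose = TRUE)
    colnames(X) <- cn
    y <- backsolve(L, y, transpose = TRUE)
  }
  fit <- lm.fit(X, y)
  dfres <- length(y) - fit$rank
  sigma2 <- sum(fit$residuals^2) / dfres
  XtXinv <- chol2inv(qr.R(fit$qr))
  j <- which(colnames(X) == "set")
  se <- sqrt(sigma2 * XtXinv[j, j])
  tstat <- fit$coefficients["set"] / se
  p <- pt(tstat, df = dfres, lower.tail = FALSE)
  data.frame(nGenesInSet = sum(inSet), beta = unname(fit$coefficients["set"]),
             se = se, p = as.numeric(p),
             padj = min(1, as.numeric(p) * nSets), row.names = NULL)
}

#' Significant genes within a set
#'
#' Genes of the set whose gene p-value beats the Bonferroni threshold
#' alpha / (set size); the comparison is strict.
#'
#' @param records gene analysis data.frame.
#' @param setGenes the gene set.
#' @param alpha family-wise level (default 0.05).
#' @return list(threshold, genes).
#' @export
withinSetGeneSignificance <- function(records, setGenes, alpha = 0.05) {
  inSet <- records[records$gene %in% setGenes, , drop = FALSE]
  m <- nrow(inSet)
  if (m < 1L) stop("set has no analyzed genes")
  thr <- alpha / m
  list(threshold = thr, genes = inSet$gene[inSet$p < thr])
}

#' Fisher/FDR gene-set enrichment
#'
#' One-sided Fisher exact test of a query gene list against every term of
#' a collection, with Benjamini-Hochberg correction; terms with no
#' background genes are skipped.
#'
#' @param queryGenes character vector (subset of background).
#' @param collections named list, term -> gene vector (e.g. from
#'   \code{\link{readGmt}}).
#' @param background character vector of all analyzed genes.
#' @param qThreshold significance cutoff on the BH q-value (default 0.05).
#' @return data.frame: term, overlap, termSize, oddsRatio, p, q,
#'   significant.
#' @export
fisherFdrEnrichment <- function(queryGenes, collections, background,
                                qThreshold = 0.05) {
  if (!all(queryGenes %in% background))
    stop("query genes must be a subset of the background")
  rows <- list()
  for (term in names(collections)) {
    tg <- intersect(collections[[term]], background)
    if (!length(tg)) next
    a <- length(intersect(queryGenes, tg))
    b <- length(queryGenes) - a
    c <- length(tg) - a
    d <- length(background) - a - b - c
    p <- phyper(a - 1L, length(tg), length(background) - length(tg),
                length(queryGenes), lower.tail = FALSE)
    orat <- if (b * c == 0) { if (a == 0) 0 else Inf } else (a * d) / (b * c)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, overlap = a, termSize = length(tg), oddsRatio = orat,
      p = p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no term intersects the background")
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < qThreshold
  out
}
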