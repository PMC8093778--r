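# Cell-type specificity: RPKM, specificity index (SI) with permutation
# p-values (pSI), thresholded enrichment lists and Fisher module overlap.

#' RPKM normalisation
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \code{count / (librarySize / 1e6) / (length / 1e3)}.
#'
#' @param counts gene x sample count matrix.
#' @param geneLengths named bp vector covering the count rows.
#' @param librarySizes per-sample totals (default: column sums).
#' @return gene x sample RPKM matrix.
#' @examples
#' rpkm(matrix(100, 1, 1, dimnames = list("g", "s")),
#'      c(g = 1000), librarySizes = 1e6)  # 100
#' @export
rpkm <- function(counts, geneLengths, librarySizes = NULL) {
  if (is.null(librarySizes)) librarySizes <- colSums(counts)
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  len <- geneLengths[rownames(counts)]
  if (any(is.na(len) | len <= 0)) stop("gene lengths must be positive for all genes")
  sweep(counts, 2L, librarySizes / 1e6, "/") / (len / 1e3)
}

#' Average expression profiles per cell type
#'
#' @param rpkmMat gene x sample RPKM matrix.
#' @param sampleType named sample -> cell type vector.
#' @return gene x type matrix of mean RPKM.
#' @export
cellTypeProfiles <- function(rpkmMat, sampleType) {
  types <- sort(unique(sampleType[colnames(rpkmMat)]))
  out <- vapply(types, function(t)
    rowMeans(rpkmMat[, sampleType[colnames(rpkmMat)] == t, drop = FALSE]),
    numeric(nrow(rpkmMat)))
  colnames(out) <- types
  out
}

#' Specificity index (SI)
#'
#' For target type t and every other type u, genes are ranked by
#' descending fold change \eqn{(RPKM_t + \epsilon)/(RPKM_u + \epsilon)}
#' (rank 1 = most specific, midranks for ties); SI(g, t) is the average
#' rank of g over the comparisons.  SI lies in [1, nGenes]; a uniformly
#' most-specific gene scores 1.
#'
#' @param profiles gene x type mean-RPKM matrix (>= 2 types).
#' @param epsilon pseudo-RPKM stabilizing fold changes at zero expression
#'   (default 1e-3).
#' @return gene x type SI matrix.
#' @export
specificityIndex <- function(profiles, epsilon = 1e-3) {
  types <- colnames(profiles)
  if (length(types) < 2L) stop("need at least 2 cell types")
  si <- matrix(0, nrow(profiles), length(types),
               dimnames = list(rownames(profiles), types))
  lg <- log(profiles + epsilon)
  for (t in types) {
    rks <- vapply(setdiff(types, t), function(u)
      rank(-(lg[, t] - lg[, u])), numeric(nrow(profiles)))
    si[, t] <- rowMeans(rks)
  }
  si
}

#' Permutation p-values for the specificity index (pSI)
#'
#' The null shuffles expression values across genes independently within
#' each cell type (preserving every type's marginal distribution) and
#' recomputes SI; \eqn{pSI(g,t) = (1 + \#\{SI^{null} \le SI^{obs}\}) /
#' (B + 1)} with the add-one estimator, so the minimum attainable value is
#' 1/(B+1) and pSI is never 0.  The null count is taken per gene, so pSI
#' is monotone in the observed SI up to permutation noise.
#'
#' @param profiles gene x type mean-RPKM matrix.
#' @param nPermutations number of permutations B (default 10000, min 100).
#' @param epsilon pseudo-RPKM (see \code{\link{specificityIndex}}).
#' @param seed RNG seed.
#' @return list(si, psi): gene x type matrices.
#' @export
psiScores <- function(profiles, nPermutations = 10000L, epsilon = 1e-3,
                      seed = 1L) {
  if (nPermutations < 100L) stop("need at least 100 permutations")
  set.seed(seed)
  obs <- specificityIndex(profiles, epsilon)
  count <- matrix(0L, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  n <- nrow(profiles)
  for (b in seq_len(nPermutations)) {
    perm <- apply(profiles, 2L, function(col) col[sample.int(n)])
    rownames(perm) <- rownames(profiles)
    count <- count + (specificityIndex(perm, epsilon) <= obs)
  }
  list(si = obs, psi = (1 + count) / (nPermutations + 1))
}

#' Cell-type-enriched gene lists
#'
#' Genes with pSI strictly below the threshold, per cell type.
#'
#' @param psi gene x type pSI matrix.
#' @param threshold pSI cutoff (default 0.05, strict \code{<}).
#' @return named list, cell type -> character vector of genes.
#' @export
enrichedGeneLists <- function(psi, threshold = 0.05) {
  lapply(setNames(colnames(psi), colnames(psi)), function(t)
    rownames(psi)[psi[, t] < threshold])
}

#' Fisher overlap of modules with cell-type gene lists
#'
#' One-sided (enrichment) Fisher exact test of the 2x2 overlap table of
#' each module with each cell-type-enriched list against the analyzed
#' background, with a Bonferroni threshold of
#' alpha / (nTypes x nModules).
#'
#' @param moduleGenes named list, module -> gene vector (subsets of
#'   background).
#' @param cellTypeLists named list, cell type -> gene vector.
#' @param background character vector of all analyzed genes.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: module, cellType, overlap, oddsRatio, p, padj,
#'   threshold.
#' @export
moduleOverlap <- function(moduleGenes, cellTypeLists, background,
                          alpha = 0.05) {
  if (!length(background)) stop("background must be non-empty")
  for (m in moduleGenes) if (!all(m %in% background))
    stop("module genes must be a subset of the background")
  nTests <- length(moduleGenes) * length(cellTypeLists)
  rows <- list()
  for (mod in names(moduleGenes)) for (ct in names(cellTypeLists)) {
    mg <- unique(moduleGenes[[mod]])
    lg <- unique(intersect(cellTypeLists[[ct]], background))
    a <- length(intersect(mg, lg))
    b <- length(mg) - a
    c <- length(lg) - a
    d <- length(background) - a - b - c
    p <- phyper(a - 1L, length(lg), length(background) - length(lg),
                length(mg), lower.tail = FALSE)
    orat <- if (b * c == 0) Inf else (a * d) / (b * c)
    if (a == 0) orat <- 0
    rows[[length(rows) + 1L]] <- data.frame(
      module = mod, cellType = ct, overlap = a, oddsRatio = orat,
      p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  bc <- bonferroniCorrect(out$p, m = nTests, alpha = alpha)
  out$padj <- bc$padj
  out$threshold <- bc$threshold
  out
}
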