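# Weighted coexpression module detection: soft-threshold adjacency,
# topological overlap, average-linkage clustering with a simplified
# dynamic tree cut, eigengene merging and module eigengenes.

#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted network: \eqn{a_{ij} = |cor(g_i, g_j)|^\beta} with
#' unit diagonal.
#'
#' @param expr regions x genes matrix (genes in columns).
#' @param beta soft-thresholding power (positive).
#' @param corMethod correlation method (default "pearson").
#' @return symmetric gene x gene matrix with entries in [0, 1].
#' @export
adjacencyMatrix <- function(expr, beta, corMethod = "pearson") {
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(expr, 2L, sd)
  if (any(sds == 0))
    stop("constant gene profile(s): ",
         paste(head(colnames(expr)[sds == 0], 5), collapse = ", "))
  a <- abs(cor(expr, method = corMethod))^beta
  diag(a) <- 1
  a
}

#' Scale-free fit and soft power selection
#'
#' For each candidate power, builds the adjacency, computes connectivities
#' \eqn{k_i = \sum_{j \ne i} a_{ij}}, bins log10(k) and regresses
#' log10(p(k)) on log10(k); the fit index is the signed R-squared
#' (negative-slope convention, so only scale-free-like decay counts).
#' The chosen beta is the smallest power whose signed fit reaches
#' \code{fitTarget}; if none does, the power with the maximum fit.
#'
#' @param expr regions x genes matrix.
#' @param powers candidate powers (default 1:20).
#' @param fitTarget scale-free fit threshold (default 0.9).
#' @param nBins histogram bins for the degree distribution (default 10).
#' @return list(beta, fitTable) where fitTable has one row per power with
#'   the signed fit and mean connectivity.
#' @export
pickSoftPower <- function(expr, powers = 1:20, fitTarget = 0.9, nBins = 10L) {
  if (ncol(expr) < 30L) stop("need at least 30 genes")
  if (nrow(expr) < 10L) stop("need at least 10 regions")
  absCor <- abs(cor(expr))
  diag(absCor) <- 0
  fit <- numeric(length(powers)); meanK <- numeric(length(powers))
  for (i in seq_along(powers)) {
    k <- colSums(absCor^powers[i])
    meanK[i] <- mean(k)
    fit[i] <- scaleFreeFit(k, nBins)
  }
  tab <- data.frame(power = powers, fit = fit, meanK = meanK)
  hit <- which(fit >= fitTarget)
  beta <- if (length(hit)) powers[hit[1]] else powers[which.max(fit)]
  list(beta = beta, fitTable = tab)
}

# signed scale-free topology fit index of a connectivity vector
scaleFreeFit <- function(k, nBins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  br <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & !is.na(mk) & mk > 0
  if (sum(ok) < 3L) return(0)
  f <- lm(log10(pk[ok]) ~ log10(mk[ok]))
  r2 <- summary(f)$r.squared
  -sign(coef(f)[2]) * r2
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; unit diagonal.
#'
#' @param a symmetric adjacency with unit diagonal.
#' @return symmetric TOM with entries in [0, 1] and unit diagonal.
#' @export
tomSimilarity <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  # (A^2)_ij sums over all u; remove the u = i and u = j terms
  l <- a %*% a -
       outer(diag(a), rep(1, n)) * a - a * outer(rep(1, n), diag(a))
  tom <- (l + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# adjusted Rand index between two label vectors
adjustedRandIndex <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  d <- choose(sum(tab), 2)
  expected <- b * c / d
  mx <- (b + c) / 2
  if (mx == expected) return(1)
  (a - expected) / (mx - expected)
}

# recursively split an hclust subtree; returns a list of leaf-index vectors
splitBranch <- function(merge, height, node, minSize, depth, relGap) {
  leaves <- branchLeaves(merge, node)
  if (depth <= 0L || node < 0L || length(leaves) < 2L * minSize)
    return(list(leaves))
  kids <- merge[node, ]
  hTop <- height[node]
  hKids <- vapply(kids, function(k) if (k < 0) 0 else height[k], 0)
  sizes <- vapply(kids, function(k) length(branchLeaves(merge, k)), 0L)
  gap <- (hTop - max(hKids)) / max(hTop, .Machine$double.eps)
  if (all(sizes >= minSize) && gap >= relGap) {
    c(splitBranch(merge, height, kids[1], minSize, depth - 1L, relGap),
      splitBranch(merge, height, kids[2], minSize, depth - 1L, relGap))
  } else list(leaves)
}

branchLeaves <- function(merge, node) {
  if (node < 0L) return(-node)
  out <- integer(0); stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (k in merge[nd, ]) {
      if (k < 0L) out <- c(out, -k) else stack <- c(stack, k)
    }
  }
  out
}

#' Cluster the TOM and cut modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' followed by a simplified dynamic tree cut: a static cut near the top of
#' the dendrogram (99% of the height range), recursive sub-branch splitting
#' whose aggressiveness is set by \code{deepSplit} (0..4, larger = smaller
#' height gap needed to accept a split), a minimum module size, a cohesion
#' check that sends clusters indistinguishable from correlation noise to
#' the background, and iterative merging of modules whose eigengene
#' dissimilarity 1 - cor(ME) falls below \code{mergeHeight}.  Module labels
#' are sizes-ranked colour names (WGCNA convention); background genes get
#' "grey".
#'
#' @param tom TOM similarity matrix (genes x genes, named).
#' @param expr regions x genes matrix (needed for eigengene merging and the
#'   cohesion check).
#' @param minModuleSize minimum genes per module (default 50).
#' @param deepSplit split sensitivity 0..4 (default 2).
#' @param mergeHeight eigengene-dissimilarity merge threshold (default 0.1;
#'   0 disables merging).
#' @param cohesionFactor a cluster is kept only if its mean within-cluster
#'   |correlation| exceeds this multiple of the null mean
#'   \eqn{\sqrt{2/\pi(n-1)}} for n regions (default 3).
#' @return list(assignment = \linkS4class{ModuleAssignment},
#'   dendrogram = hclust object).
#' @export
clusterAndCut <- function(tom, expr, minModuleSize = 50L, deepSplit = 2L,
                          mergeHeight = 0.1, cohesionFactor = 3) {
  if (mergeHeight < 0 || mergeHeight >= 1) stop("mergeHeight must be in [0, 1)")
  if (!deepSplit %in% 0:4) stop("deepSplit must be in 0..4")
  genes <- colnames(tom)
  nGenes <- length(genes)
  hc <- hclust(as.dist(1 - tom), method = "average")
  if (nGenes < minModuleSize) {
    warning("fewer genes than minModuleSize: all background")
    return(list(assignment = ModuleAssignment(
      setNames(rep("grey", nGenes), genes)), dendrogram = hc))
  }
  h <- hc$height
  cutH <- min(h) + 0.99 * (max(h) - min(h))
  top <- cutree(hc, h = cutH)

  relGap <- c(0.5, 0.35, 0.25, 0.15, 0.05)[deepSplit + 1L]
  clusters <- list()
  for (cl in unique(top)) {
    idx <- which(top == cl)
    if (length(idx) < minModuleSize) { next }
    # locate the subtree node spanning exactly idx, then split recursively
    node <- spanningNode(hc$merge, idx)
    if (is.null(node)) { clusters <- c(clusters, list(idx)); next }
    parts <- if (node < 0) list(-node)
             else splitBranch(hc$merge, hc$height, node, minModuleSize,
                              as.integer(deepSplit), relGap)
    clusters <- c(clusters, parts)
  }
  clusters <- Filter(function(x) length(x) >= minModuleSize, clusters)

  # cohesion check against the correlation-noise floor
  nullMean <- sqrt(2 / (pi * (nrow(expr) - 1)))
  cohesive <- vapply(clusters, function(idx) {
    cc <- abs(cor(expr[, genes[idx], drop = FALSE]))
    mean(cc[upper.tri(cc)]) >= cohesionFactor * nullMean
  }, logical(1))
  clusters <- clusters[cohesive]

  labels <- setNames(rep("grey", nGenes), genes)
  if (length(clusters)) {
    ord <- order(vapply(clusters, length, 0L), decreasing = TRUE)
    clusters <- clusters[ord]
    for (i in seq_along(clusters))
      labels[clusters[[i]]] <- moduleColorNames(length(clusters))[i]
    if (mergeHeight > 0 && length(clusters) > 1L)
      labels <- mergeCloseModules(labels, expr, mergeHeight)
  }
  list(assignment = ModuleAssignment(labels), dendrogram = hc)
}

# find the merge-tree node whose leaf set equals idx (NULL if none)
spanningNode <- function(merge, idx) {
  if (length(idx) == 1L) return(-idx)
  for (nd in seq_len(nrow(merge))) {
    lv <- branchLeaves(merge, nd)
    if (length(lv) == length(idx) && setequal(lv, idx)) return(nd)
  }
  NULL
}

# WGCNA-like size-ranked colour labels
moduleColorNames <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "white", "skyblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("module", seq_len(n - length(base))))
}

# iteratively merge modules whose eigengenes are closer than mergeHeight
mergeCloseModules <- function(labels, expr, mergeHeight) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) return(labels)
    me <- moduleEigengenes(expr, ModuleAssignment(labels))
    cc <- cor(t(me[mods, , drop = FALSE]))
    diss <- 1 - cc; diag(diss) <- Inf
    if (min(diss) >= mergeHeight) return(labels)
    pair <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    keep <- mods[min(pair)]; drop <- mods[max(pair)]
    labels[labels == drop] <- keep
  }
}

#' Module eigengenes
#'
#' First principal component of each module's member genes, standardized
#' across regions, with the sign oriented so the eigengene correlates
#' positively with the module's mean member expression.  The fraction of
#' variance explained per module is attached as an attribute.
#'
#' @param expr regions x genes matrix.
#' @param assignment a \linkS4class{ModuleAssignment} (background excluded).
#' @return module x region matrix of eigengene values;
#'   \code{attr(, "varExplained")} holds the PC1 variance fractions.
#' @export
moduleEigengenes <- function(expr, assignment) {
  labs <- moduleLabels(assignment)
  mods <- setdiff(sort(unique(labs)), backgroundLabel(assignment))
  if (!length(mods)) stop("no modules to summarize")
  me <- matrix(0, length(mods), nrow(expr),
               dimnames = list(mods, rownames(expr)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- intersect(names(labs)[labs == m], colnames(expr))
    if (length(genes) < 2L) stop("module ", m, " has fewer than 2 genes")
    x <- scale(expr[, genes, drop = FALSE])
    x[is.na(x)] <- 0
    pc <- prcomp(x, center = FALSE, scale. = FALSE)
    scores <- pc$x[, 1L]
    if (cor(scores, rowMeans(x)) < 0) scores <- -scores
    me[m, ] <- scores
    ve[m] <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  }
  attr(me, "varExplained") <- ve
  me
}

#' Detect coexpression modules end to end
#'
#' Convenience wrapper: soft power selection, adjacency, TOM, dynamic cut
#' and eigengenes.
#'
#' @param expr regions x genes matrix.
#' @param beta soft power; NULL picks it by scale-free fit.
#' @param fitTarget scale-free fit target when picking beta.
#' @param minModuleSize,deepSplit,mergeHeight see \code{\link{clusterAndCut}}.
#' @return list(assignment, eigengenes, beta, fitTable, dendrogram).
#' @export
detectModules <- function(expr, beta = NULL, fitTarget = 0.9,
                          minModuleSize = 50L, deepSplit = 2L,
                          mergeHeight = 0.1) {
  fitTable <- NULL
  if (is.null(beta)) {
    sp <- pickSoftPower(expr, fitTarget = fitTarget)
    beta <- sp$beta; fitTable <- sp$fitTable
  }
  a <- adjacencyMatrix(expr, beta)
  tom <- tomSimilarity(a)
  cut <- clusterAndCut(tom, expr, minModuleSize, deepSplit, mergeHeight)
  me <- if (length(moduleSizes(cut$assignment)))
          moduleEigengenes(expr, cut$assignment) else NULL
  list(assignment = cut$assignment, eigengenes = me, beta = beta,
       fitTable = fitTable, dendrogram = cut$dendrogram)
}
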