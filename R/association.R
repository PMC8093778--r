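# Spatial association of module eigengenes with a regional phenotype,
# Bonferroni correction, and the multi-dataset replication rule.

#' Spearman association of eigengenes with a regional phenotype
#'
#' Spearman rho (midrank ties) between each module eigengene and the
#' phenotype across the regions common to both, with a two-sided p-value
#' from the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @param eigengenes module x region matrix.
#' @param phenotype \linkS4class{RegionValues} (or named numeric vector).
#' @param dataset optional dataset id recorded in the result.
#' @return data.frame: module, r, p, n, dataset.
#' @export
spearmanAssoc <- function(eigengenes, phenotype, dataset = "dataset1") {
  ph <- if (is(phenotype, "RegionValues")) regionValues(phenotype) else phenotype
  common <- intersect(colnames(eigengenes), names(ph))
  n <- length(common)
  if (n < 10L) stop("need at least 10 overlapping regions, got ", n)
  py <- rank(ph[common])
  out <- lapply(rownames(eigengenes), function(m) {
    px <- rank(eigengenes[m, common])
    rho <- cor(px, py)
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    data.frame(module = m, r = rho, p = min(p, 1), n = n,
               dataset = dataset, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact permutation p-value for a Spearman correlation
#'
#' Enumerates all n! rank permutations (n <= 12): oracle mode for
#' validating the t approximation on small fixtures.
#'
#' @param x,y numeric vectors.
#' @return two-sided permutation p-value for |rho|.
#' @export
spearmanExactP <- function(x, y) {
  n <- length(x)
  if (n > 12L) stop("exact enumeration limited to n <= 12")
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- permuteAll(n)
  stat <- apply(perms, 1L, function(pp) abs(cor(rx[pp], ry)))
  mean(stat >= obs - 1e-12)
}

permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Bonferroni correction
#'
#' @param p raw p-values.
#' @param m number of tests (default \code{length(p)}).
#' @param alpha family-wise level (default 0.05).
#' @return list(threshold = alpha/m, padj = pmin(1, p * m)).
#' @examples
#' bonferroniCorrect(0.001, m = 30)$threshold  # 0.05/30
#' @export
bonferroniCorrect <- function(p, m = length(p), alpha = 0.05) {
  if (m < 1L) stop("m must be >= 1")
  list(threshold = alpha / m, padj = pmin(1, p * m))
}

#' Multi-dataset replication rule
#'
#' A module replicates when its Bonferroni-corrected p is below alpha in
#' EVERY dataset (discovery and all replications).  Sign agreement of r
#' across datasets is reported but not required.
#'
#' @param results list of association data.frames (one per dataset, as
#'   from \code{\link{spearmanAssoc}}), all with the same modules.
#' @param alpha corrected-p significance level (default 0.05).
#' @param m number of tests for the Bonferroni correction (default: number
#'   of modules in the first dataset).
#' @return data.frame per module: significant-in-all flag
#'   (\code{replicated}), sign-consistency flag, per-dataset corrected p.
#' @export
replicateModules <- function(results, alpha = 0.05, m = NULL) {
  mods <- sort(results[[1]]$module)
  for (r in results)
    if (!setequal(r$module, mods)) stop("module labels differ across datasets")
  if (is.null(m)) m <- length(mods)
  sig <- sapply(results, function(r) {
    r <- r[match(mods, r$module), ]
    bonferroniCorrect(r$p, m = m, alpha = alpha)$padj < alpha
  })
  signs <- sapply(results, function(r) sign(r[match(mods, r$module), "r"]))
  padj <- sapply(results, function(r)
    bonferroniCorrect(r[match(mods, r$module), "p"], m = m)$padj)
  if (is.null(dim(sig))) { sig <- matrix(sig, nrow = 1); signs <- matrix(signs, nrow = 1)
                           padj <- matrix(padj, nrow = 1) }
  data.frame(module = mods,
             replicated = apply(sig, 1L, all),
             signConsistent = apply(signs, 1L, function(s) length(unique(s)) == 1L),
             padj, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
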