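# AHBA-style expression preprocessing: intensity filtering, probe
# selection against an RNA-seq reference, sample-to-region assignment,
# per-region aggregation and scaled robust sigmoid normalisation.

#' Intensity-based probe filtering
#'
#' Keeps probes whose expression exceeds the array background in at least
#' \code{minFraction} of samples (the AHBA rule is 50%).
#'
#' @param expression probes x samples matrix.
#' @param aboveBackground logical probes x samples matrix of background
#'   calls (produced upstream by the array platform).
#' @param minFraction minimum fraction of above-background samples
#'   (default 0.5; the comparison is \code{>=}).
#' @return the filtered expression matrix; kept/removed counts in
#'   \code{attr(, "report")}.
#' @export
intensityFilter <- function(expression, aboveBackground, minFraction = 0.5) {
  stopifnot(identical(dim(expression), dim(aboveBackground)))
  frac <- rowMeans(aboveBackground)
  keep <- frac >= minFraction
  if (!any(keep)) stop("intensity filter removed every probe (minFraction = ",
                       minFraction, ")")
  out <- expression[keep, , drop = FALSE]
  attr(out, "report") <- c(kept = sum(keep), removed = sum(!keep))
  out
}

#' Probe selection by correlation with an RNA-seq reference
#'
#' For genes measured by several probes, keeps the probe with the highest
#' Pearson correlation with the gene's reference profile across the shared
#' samples (ties to the lowest probe id).  Genes absent from the reference
#' fall back to the probe with the highest mean expression.  Single-probe
#' genes are kept unconditionally.
#'
#' @param expression probes x samples matrix.
#' @param probeGene named character vector (or data.frame with columns
#'   probe_id, gene) mapping probe -> gene symbol.
#' @param reference gene x sample matrix of reference expression; column
#'   names are matched against the expression columns.
#' @return gene x sample matrix (one row per gene); chosen probe ids in
#'   \code{attr(, "selectedProbe")}.
#' @export
selectProbes <- function(expression, probeGene, reference = NULL) {
  if (is.data.frame(probeGene))
    probeGene <- setNames(probeGene$gene, probeGene$probe_id)
  probes <- rownames(expression)
  genes <- unique(probeGene[probes])
  shared <- if (is.null(reference)) character(0)
            else intersect(colnames(expression), colnames(reference))
  pick <- character(length(genes)); names(pick) <- genes
  for (g in genes) {
    cand <- probes[probeGene[probes] == g]
    cand <- sort(cand)
    if (length(cand) == 1L) { pick[g] <- cand; next }
    if (!is.null(reference) && g %in% rownames(reference) &&
        length(shared) >= 3L) {
      ref <- reference[g, shared]
      cc <- suppressWarnings(
        apply(expression[cand, shared, drop = FALSE], 1L, cor, y = ref))
      if (all(is.na(cc))) stop("gene ", g, " has only zero-variance probes")
      pick[g] <- cand[which.max(cc)]       # first max = lowest probe id
    } else {
      pick[g] <- cand[which.max(rowMeans(expression[cand, , drop = FALSE]))]
    }
  }
  out <- expression[pick, , drop = FALSE]
  rownames(out) <- genes
  attr(out, "selectedProbe") <- pick
  out
}

#' Assign tissue samples to atlas regions
#'
#' Each sample is assigned to the region of the nearest labelled voxel
#' (Euclidean mm distance to the voxel centre).  Samples farther than
#' \code{maxDistance} mm from every labelled voxel are unassigned, and
#' samples whose annotated hemisphere differs from the hemisphere of the
#' assigned voxel (sign of its world x-coordinate) are excluded.
#'
#' @param samples data.frame with columns sample_id, hemisphere, mni_x,
#'   mni_y, mni_z (donor optional).
#' @param parcellation integer 3D label array.
#' @param voxelSize voxel edge lengths in mm.
#' @param maxDistance assignment threshold in mm (default 2).
#' @return data.frame: sample_id, region (NA if unassigned), distance_mm,
#'   excluded_reason ("", "distance" or "hemisphere").
#' @export
assignSamples <- function(samples, parcellation, voxelSize = c(3, 3, 3),
                          maxDistance = 2) {
  co <- as.matrix(samples[, c("mni_x", "mni_y", "mni_z")])
  if (any(!is.finite(co))) stop("malformed sample coordinates")
  vox <- which(parcellation > 0L, arr.ind = TRUE)
  voxLab <- parcellation[parcellation > 0L]
  mm <- voxelToWorld(vox - 1L, dim(parcellation), voxelSize)
  region <- rep(NA_character_, nrow(samples))
  dist <- numeric(nrow(samples))
  reason <- rep("", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    d2 <- colSums((t(mm) - co[s, ])^2)
    j <- which.min(d2)
    dist[s] <- sqrt(d2[j])
    if (dist[s] > maxDistance) { reason[s] <- "distance"; next }
    hemi <- hemisphereOf(mm[j, 1])
    if (!is.na(samples$hemisphere[s]) && hemi != samples$hemisphere[s]) {
      reason[s] <- "hemisphere"; next
    }
    region[s] <- as.character(voxLab[j])
  }
  data.frame(sample_id = samples$sample_id, region = region,
             distance_mm = dist, excluded_reason = reason,
             stringsAsFactors = FALSE)
}

#' Aggregate samples to a region x gene matrix
#'
#' Per-region mean over the assigned samples; regions with no samples are
#' absent from the output and listed in \code{attr(, "droppedRegions")}.
#' With a \code{donor} vector, aggregation is done per donor and a named
#' list of region x gene matrices is returned (the donor blocks are later
#' combined by \code{\link{srsNormalize}}).
#'
#' @param geneMatrix gene x sample matrix.
#' @param assignment result of \code{\link{assignSamples}} (or a named
#'   sample -> region vector).
#' @param donor optional named sample -> donor vector.
#' @param allRegions optional full region label set, for the dropped report.
#' @return region x gene matrix, or a per-donor list of them.
#' @export
aggregateRegions <- function(geneMatrix, assignment, donor = NULL,
                             allRegions = NULL) {
  if (is.data.frame(assignment))
    assignment <- setNames(assignment$region, assignment$sample_id)
  samp <- colnames(geneMatrix)
  reg <- assignment[samp]
  if (!is.null(donor)) {
    donors <- sort(unique(donor[samp]))
    out <- lapply(donors, function(d) {
      sel <- samp[!is.na(reg) & donor[samp] == d]
      aggregateRegions(geneMatrix[, sel, drop = FALSE],
                       assignment[sel], allRegions = allRegions)
    })
    names(out) <- donors
    return(out)
  }
  keep <- !is.na(reg)
  if (!any(keep)) stop("no assigned samples")
  reg <- reg[keep]
  gm <- geneMatrix[, keep, drop = FALSE]
  regs <- sort(unique(reg))
  out <- t(vapply(regs, function(r)
    rowMeans(gm[, reg == r, drop = FALSE]), numeric(nrow(gm))))
  dimnames(out) <- list(regs, rownames(geneMatrix))
  if (!is.null(allRegions))
    attr(out, "droppedRegions") <- setdiff(as.character(allRegions), regs)
  out
}

# scaled robust sigmoid of one vector: sigmoid around the median scaled by
# IQR/1.35 (the SD equivalent under normality), then min-max to [0, 1]
srsVector <- function(x) {
  med <- median(x)
  sc <- IQR(x) / 1.35
  if (sc == 0) sc <- sd(x)
  if (is.na(sc) || sc == 0) return(rep(0.5, length(x)))
  s <- 1 / (1 + exp(-(x - med) / sc))
  rng <- range(s)
  if (diff(rng) == 0) return(rep(0.5, length(x)))
  (s - rng[1]) / diff(rng)
}

#' Scaled robust sigmoid normalisation
#'
#' Removes donor-specific level and scale differences: each gene is passed,
#' within each donor, through a sigmoid centred on its median with width
#' IQR/1.35, then min-max rescaled to [0, 1].  The transform is strictly
#' monotone, so within-donor rank order is preserved.  Donor blocks are
#' then averaged per region (regions present in at least one donor are
#' kept).  Zero-IQR genes fall back to an SD-based sigmoid; fully constant
#' genes map to 0.5.
#'
#' @param x region x gene matrix, or a per-donor named list of them (as
#'   returned by \code{\link{aggregateRegions}} with \code{donor}).
#' @return region x gene matrix with values in [0, 1].
#' @export
srsNormalize <- function(x) {
  if (!is.list(x)) x <- list(x)
  normed <- lapply(x, function(m) apply(m, 2L, srsVector))
  for (i in seq_along(normed)) {
    dimnames(normed[[i]]) <- dimnames(x[[i]])
  }
  regs <- sort(unique(unlist(lapply(normed, rownames))))
  genes <- colnames(normed[[1]])
  acc <- matrix(0, length(regs), length(genes), dimnames = list(regs, genes))
  cnt <- matrix(0, length(regs), length(genes), dimnames = list(regs, genes))
  for (m in normed) {
    acc[rownames(m), ] <- acc[rownames(m), ] + m
    cnt[rownames(m), ] <- cnt[rownames(m), ] + 1
  }
  acc / cnt
}

#' Full expression preprocessing pipeline
#'
#' Convenience wrapper: intensity filter, probe selection, sample
#' assignment, per-donor regional aggregation and scaled robust sigmoid
#' normalisation, producing the normalized region x gene matrix.
#'
#' @param expr output of \code{\link{simulateExpression}}, or a list with
#'   the same fields (expression, probes, aboveBackground, samples,
#'   reference).
#' @param parcellation integer 3D label array.
#' @param voxelSize voxel edge lengths in mm.
#' @param maxDistance assignment threshold in mm.
#' @param minFraction intensity-filter threshold.
#' @return region x gene matrix in [0, 1]; the assignment table is kept in
#'   \code{attr(, "assignment")}.
#' @export
prepareExpression <- function(expr, parcellation, voxelSize = c(3, 3, 3),
                              maxDistance = 2, minFraction = 0.5) {
  filt <- intensityFilter(expr$expression, expr$aboveBackground, minFraction)
  byGene <- selectProbes(filt, expr$probes, expr$reference)
  assign <- assignSamples(expr$samples, parcellation, voxelSize, maxDistance)
  donor <- setNames(expr$samples$donor, expr$samples$sample_id)
  perDonor <- aggregateRegions(byGene, assign, donor = donor)
  out <- srsNormalize(perDonor)
  attr(out, "assignment") <- assign
  out
}
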