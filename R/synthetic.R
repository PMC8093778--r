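# Synthetic-data generators with planted ground truth.  Every generator is
# a pure function of its seed (it seeds the RNG on entry), so identical
# calls are bit-identical.  Gaussian white noise is used throughout: the
# downstream statistics are rank-based or calibration-checked, so the noise
# law is deliberately light.

#' Simulate an atlas parcellation
#'
#' Voronoi partition of the in-mask voxels around randomly drawn seed
#' voxels: every in-mask voxel takes the label of its nearest seed
#' (Euclidean distance in voxel units, ties to the lowest label).  Labels
#' are 1..nRegions, 0 outside the mask; every label is non-empty.
#'
#' @param shape length-3 grid dimensions.
#' @param mask logical 3D array (default: all voxels in).
#' @param nRegions number of regions; must not exceed the mask size.
#' @param seed RNG seed.
#' @return integer 3D array of labels.
#' @export
simulateParcellation <- function(shape, nRegions, mask = NULL, seed = 1L) {
  if (any(shape < 3L)) stop("each grid dimension must be >= 3")
  if (is.null(mask)) mask <- array(TRUE, shape)
  vox <- which(mask, arr.ind = TRUE)
  if (nRegions > nrow(vox)) stop("nRegions exceeds the number of in-mask voxels")
  set.seed(seed)
  seeds <- vox[sample.int(nrow(vox), nRegions), , drop = FALSE]
  lab <- array(0L, shape)
  d2 <- matrix(0, nrow(vox), nRegions)
  for (s in seq_len(nRegions))
    d2[, s] <- (vox[, 1] - seeds[s, 1])^2 + (vox[, 2] - seeds[s, 2])^2 +
               (vox[, 3] - seeds[s, 3])^2
  lab[mask] <- max.col(-d2, ties.method = "first")
  lab
}

#' Simulate a BOLD series with planted neighbourhood synchrony
#'
#' Each voxel's time course is
#' \eqn{\sqrt{w_v}\,L + \sqrt{1 - w_v}\,\epsilon_v}, where L is a shared
#' unit-variance white-noise latent series and \eqn{\epsilon_v} independent
#' unit-variance white noise, so the planted weight w controls local
#' synchrony and hence ReHo.  With a parcellation, one latent is drawn per
#' region (clean planted regional ordering); otherwise a single latent
#' spans the whole mask.
#'
#' @param shape length-3 grid dimensions.
#' @param nTimepoints number of timepoints (>= 10).
#' @param syncWeights per-voxel weights in [0, 1]: a scalar, or a 3D array.
#' @param seed RNG seed.
#' @param mask logical 3D array (default all-in).
#' @param parcellation optional integer 3D label array; one latent per label.
#' @param voxelSize voxel edge lengths in mm.
#' @return A \linkS4class{BoldSeries}.
#' @export
simulateBold <- function(shape, nTimepoints, syncWeights, seed = 1L,
                         mask = NULL, parcellation = NULL,
                         voxelSize = c(3, 3, 3)) {
  if (any(shape < 3L)) stop("each grid dimension must be >= 3")
  if (nTimepoints < 10L) stop("nTimepoints must be >= 10")
  if (is.null(mask)) mask <- array(TRUE, shape)
  if (length(syncWeights) == 1L) {
    w <- array(syncWeights, shape)
  } else {
    w <- syncWeights
    if (!identical(dim(w), as.integer(shape))) stop("syncWeights shape mismatch")
  }
  wm <- w[mask]
  if (any(!is.finite(wm)) || any(wm < 0) || any(wm > 1))
    stop("sync weights must lie in [0, 1]")
  set.seed(seed)
  nv <- sum(mask)
  if (is.null(parcellation)) {
    groups <- rep(1L, nv)
  } else {
    groups <- parcellation[mask]
    groups[groups <= 0L] <- max(groups) + 1L   # unlabelled in-mask: own latent
  }
  ug <- sort(unique(groups))
  latents <- matrix(rnorm(length(ug) * nTimepoints), length(ug))
  rownames(latents) <- as.character(ug)
  noise <- matrix(rnorm(nv * nTimepoints), nv)
  series <- sqrt(wm) * latents[as.character(groups), , drop = FALSE] +
            sqrt(1 - wm) * noise
  dat <- array(0, c(shape, nTimepoints))
  flat <- matrix(dat, ncol = nTimepoints)
  flat[which(mask), ] <- series
  dat <- array(flat, c(shape, nTimepoints))
  BoldSeries(dat, mask, voxelSize)
}

# normal scores of a vector (rank-based, midranks)
normalScores <- function(x) qnorm((rank(x) - 0.5) / length(x))

#' Simulate a probe x sample expression table with planted modules
#'
#' Plants \code{nModules} coexpression modules whose latent regional
#' profiles have a target population Spearman correlation with a supplied
#' phenotype: the latent is \eqn{\rho z + \sqrt{1-\rho^2}\,e} with
#' \eqn{\rho = 2\sin(\pi r_s/6)} (the bivariate-normal inversion of the
#' Spearman/Pearson relation) and z the normal scores of the phenotype.
#' Member genes add independent Gaussian noise (\code{noiseSd}) to their
#' module latent; background genes are pure noise.  Samples carry MNI-like
#' mm coordinates inside their region, donor ids with a per-donor
#' scale/offset, and hemisphere labels; optional fractions of samples are
#' planted > 2 mm outside any region (to exercise assignment exclusion) or
#' with a flipped hemisphere annotation.
#'
#' @param parcellation integer 3D label array.
#' @param phenotype \linkS4class{RegionValues} over the parcellation labels.
#' @param nGenes total genes; \code{genesPerModule * nModules} must fit.
#' @param nModules number of planted modules.
#' @param plantedR per-module target Spearman correlation with the
#'   phenotype (recycled to nModules).
#' @param noiseSd within-module gene noise SD (latent has SD 1).
#' @param nDonors donors (default 2).
#' @param genesPerModule genes per planted module (default
#'   \code{floor(nGenes / (nModules + 1))}).
#' @param probesPerGene probes per gene (default 2).
#' @param samplesPerRegion samples per region per donor (default 1).
#' @param outsideFraction fraction of extra samples planted > 2 mm from any
#'   labelled voxel (default 0).
#' @param mismatchFraction fraction of samples with flipped hemisphere
#'   annotation (default 0).
#' @param sampleNoiseSd per-sample measurement noise SD (default 0.1).
#' @param probeNoiseRange range of per-probe noise SDs; the first probe of
#'   each gene gets the minimum (so probe selection has a planted answer).
#' @param lowQualityFraction fraction of extra probes planted below
#'   background in most samples (default 0.1).
#' @param voxelSize voxel edge lengths in mm.
#' @param seed RNG seed.
#' @return list with \code{expression} (probes x samples),
#'   \code{probes} (probe_id, gene), \code{aboveBackground} (logical,
#'   probes x samples), \code{samples} (sample_id, donor, hemisphere,
#'   mni_x/y/z), \code{reference} (gene x sample RNA-seq-style reference)
#'   and \code{truth} (module membership, planted r, module latents).
#' @export
simulateExpression <- function(parcellation, phenotype, nGenes, nModules,
                               plantedR, noiseSd = 0.3, nDonors = 2L,
                               genesPerModule = NULL, probesPerGene = 2L,
                               samplesPerRegion = 1L, outsideFraction = 0,
                               mismatchFraction = 0, sampleNoiseSd = 0.1,
                               probeNoiseRange = c(0.05, 0.6),
                               lowQualityFraction = 0.1,
                               voxelSize = c(3, 3, 3), seed = 1L) {
  labs <- names(regionValues(phenotype))
  R <- length(labs)
  if (is.null(genesPerModule)) genesPerModule <- floor(nGenes / (nModules + 1))
  if (nModules * genesPerModule > nGenes)
    stop("nModules * genesPerModule exceeds nGenes")
  plantedR <- rep(plantedR, length.out = nModules)
  if (any(abs(plantedR) > 1)) stop("planted correlations must lie in [-1, 1]")
  set.seed(seed)
  z <- normalScores(regionValues(phenotype))

  moduleNames <- paste0("M", seq_len(nModules))
  latents <- matrix(0, nModules, R, dimnames = list(moduleNames, labs))
  for (m in seq_len(nModules)) {
    rho <- 2 * sin(pi * plantedR[m] / 6)
    latents[m, ] <- rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(R)
  }

  genes <- sprintf("G%04d", seq_len(nGenes))
  membership <- setNames(rep("none", nGenes), genes)
  profiles <- matrix(rnorm(nGenes * R), nGenes, R,
                     dimnames = list(genes, labs))
  for (m in seq_len(nModules)) {
    idx <- ((m - 1) * genesPerModule + 1):(m * genesPerModule)
    membership[idx] <- moduleNames[m]
    profiles[idx, ] <- matrix(rep(latents[m, ], each = length(idx)),
                              length(idx)) +
                       noiseSd * matrix(rnorm(length(idx) * R), length(idx))
  }

  # samples: per donor, per region
  vox <- which(parcellation > 0L, arr.ind = TRUE)
  voxLab <- as.character(parcellation[parcellation > 0L])
  dims <- dim(parcellation)
  nCore <- nDonors * R * samplesPerRegion
  nOutside <- round(outsideFraction * nCore)
  donorScale <- runif(nDonors, 0.8, 1.2)
  donorOffset <- rnorm(nDonors, 0, 0.5)

  sampleRegion <- character(0); sampleDonor <- integer(0)
  coords <- matrix(0, 0, 3)
  for (d in seq_len(nDonors)) for (r in labs) for (s in seq_len(samplesPerRegion)) {
    cand <- which(voxLab == r)
    v <- vox[cand[sample.int(length(cand), 1L)], ] - 1L
    mm <- voxelToWorld(v, dims, voxelSize) +
          runif(3, -0.3, 0.3) * voxelSize
    coords <- rbind(coords, mm)
    sampleRegion <- c(sampleRegion, r)
    sampleDonor <- c(sampleDonor, d)
  }
  if (nOutside > 0L) {
    # out-of-atlas voxel centres > 2 mm from every labelled voxel centre
    outIdx <- which(parcellation == 0L, arr.ind = TRUE)
    if (nrow(outIdx) == 0L) stop("no out-of-atlas voxels available")
    labMM <- voxelToWorld(vox - 1L, dims, voxelSize)
    pick <- outIdx[sample.int(nrow(outIdx), min(nrow(outIdx), 20L * nOutside)),
                   , drop = FALSE]
    pickMM <- voxelToWorld(pick - 1L, dims, voxelSize)
    mind <- apply(pickMM, 1L, function(p)
      sqrt(min(colSums((t(labMM) - p)^2))))
    far <- which(mind > 2.4)[seq_len(nOutside)]
    if (any(is.na(far))) stop("could not place enough outside samples")
    coords <- rbind(coords, pickMM[far, , drop = FALSE])
    sampleRegion <- c(sampleRegion, rep(NA_character_, nOutside))
    sampleDonor <- c(sampleDonor, sample.int(nDonors, nOutside, replace = TRUE))
  }
  nSamples <- length(sampleDonor)
  sampleId <- sprintf("S%04d", seq_len(nSamples))
  hemi <- hemisphereOf(coords[, 1])
  nFlip <- round(mismatchFraction * nSamples)
  flipped <- if (nFlip > 0L) sample.int(nSamples, nFlip) else integer(0)
  hemi[flipped] <- ifelse(hemi[flipped] == "L", "R", "L")

  # gene x sample values: regional profile + donor effect + sample noise;
  # outside samples get the grand-mean profile plus noise
  geneSample <- matrix(0, nGenes, nSamples, dimnames = list(genes, sampleId))
  for (s in seq_len(nSamples)) {
    base <- if (is.na(sampleRegion[s])) rowMeans(profiles)
            else profiles[, sampleRegion[s]]
    d <- sampleDonor[s]
    geneSample[, s] <- donorScale[d] * base + donorOffset[d] +
                       rnorm(nGenes, 0, sampleNoiseSd)
  }

  # probes: gene value + per-probe noise; probe 1 is the cleanest
  probeId <- sprintf("%s_p%d", rep(genes, each = probesPerGene),
                     rep(seq_len(probesPerGene), nGenes))
  probeGene <- rep(genes, each = probesPerGene)
  nProbes <- length(probeId)
  probeSd <- runif(nProbes, probeNoiseRange[1], probeNoiseRange[2])
  probeSd[seq(1L, nProbes, by = probesPerGene)] <- probeNoiseRange[1]
  expr <- geneSample[probeGene, , drop = FALSE] +
          matrix(rnorm(nProbes * nSamples), nProbes) * probeSd
  rownames(expr) <- probeId

  above <- matrix(runif(nProbes * nSamples) < 0.95, nProbes, nSamples,
                  dimnames = list(probeId, sampleId))
  nLow <- round(lowQualityFraction * nProbes)
  if (nLow > 0L) {
    # only probes beyond the first of each gene may be low quality
    elig <- which(!seq_len(nProbes) %in% seq(1L, nProbes, by = probesPerGene))
    low <- sample(elig, min(nLow, length(elig)))
    above[low, ] <- matrix(runif(length(low) * nSamples) < 0.3, length(low))
  }

  reference <- geneSample + matrix(rnorm(nGenes * nSamples, 0, 0.05), nGenes)

  list(
    expression = expr,
    probes = data.frame(probe_id = probeId, gene = probeGene,
                        stringsAsFactors = FALSE),
    aboveBackground = above,
    samples = data.frame(sample_id = sampleId,
                         donor = paste0("donor", sampleDonor),
                         hemisphere = hemi,
                         mni_x = coords[, 1], mni_y = coords[, 2],
                         mni_z = coords[, 3],
                         stringsAsFactors = FALSE),
    reference = reference,
    truth = list(moduleMembership = membership,
                 plantedR = setNames(plantedR, moduleNames),
                 latents = latents,
                 outsideSamples = sampleId[is.na(sampleRegion)],
                 flippedSamples = sampleId[flipped],
                 sampleRegion = setNames(sampleRegion, sampleId))
  )
}

#' Simulate cell-type RNA-seq counts with planted markers
#'
#' Negative-binomial counts for purified cell-type replicates.  Marker
#' genes of a type have their mean multiplied by \code{foldChange} in that
#' type; non-markers are exchangeable across types.  \code{foldChange = 1}
#' is the exchangeable null.
#'
#' @param nGenes number of genes.
#' @param cellTypes character vector of type names (>= 2).
#' @param markers named list, cell type -> character vector of marker gene
#'   ids (must be disjoint across types); may be empty.
#' @param foldChange marker mean fold change (> 1 for real markers).
#' @param nReplicates replicates per type.
#' @param dispersion NB size parameter (default 10).
#' @param seed RNG seed.
#' @return list with \code{counts} (gene x sample), \code{geneLengths}
#'   (named bp vector), \code{sampleType} (named type per sample).
#' @export
simulateCellTypeCounts <- function(nGenes, cellTypes, markers = list(),
                                   foldChange = 20, nReplicates = 3L,
                                   dispersion = 10, seed = 1L) {
  if (length(cellTypes) < 2L) stop("need at least 2 cell types")
  allMark <- unlist(markers, use.names = FALSE)
  if (anyDuplicated(allMark)) stop("marker sets must be disjoint across types")
  if (length(allMark) && foldChange <= 1)
    stop("marker fold change must exceed 1")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  if (length(allMark) && !all(allMark %in% genes))
    stop("marker gene ids must exist in the generated gene index")
  lens <- round(runif(nGenes, 500, 5000))
  names(lens) <- genes
  baseMu <- exp(rnorm(nGenes, log(200), 1))
  sampleType <- rep(cellTypes, each = nReplicates)
  sampleId <- paste0(sampleType, "_r", rep(seq_len(nReplicates),
                                           length(cellTypes)))
  counts <- matrix(0L, nGenes, length(sampleId),
                   dimnames = list(genes, sampleId))
  for (j in seq_along(sampleId)) {
    mu <- baseMu * lens / 1000
    mk <- markers[[sampleType[j]]]
    if (!is.null(mk) && length(mk)) mu[mk] <- mu[mk] * foldChange
    counts[, j] <- rnbinom(nGenes, mu = mu, size = dispersion)
  }
  list(counts = counts, geneLengths = lens,
       sampleType = setNames(sampleType, sampleId))
}

#' Simulate GWAS summary statistics with planted gene-set enrichment
#'
#' Genotypes follow an exchangeable within-gene LD model (correlation
#' \code{ldRho} between a gene's SNP dosages, independence between genes;
#' allele frequency 0.5 via latent-Gaussian thresholding).  The phenotype
#' is the sum of \code{effect} times the standardized dosage over all SNPs
#' of the enriched gene set, plus unit Gaussian noise; summary p-values
#' come from per-SNP simple regression.  A reference panel is drawn from
#' the same genotype law.
#'
#' @param nGenes number of genes.
#' @param snpsPerGene SNPs per gene: a scalar, or a length-2 range from
#'   which per-gene counts are drawn uniformly.
#' @param ldRho within-gene dosage correlation, in [0, 1).
#' @param enrichedSet character vector of gene ids with planted signal.
#' @param effect standardized per-SNP effect size (0 = global null).
#' @param nSamples GWAS sample size.
#' @param panelSize reference-panel individuals (>= 50).
#' @param seed RNG seed.
#' @return list with \code{summary} (data.frame SNP, CHR, BP, P, N),
#'   \code{panel} (individuals x SNPs dosage matrix), \code{geneLoc}
#'   (BED-like data.frame chrom, start, end, gene; 0-based half-open) and
#'   \code{truth} (enriched set, effect).
#' @export
simulateGwas <- function(nGenes, snpsPerGene, ldRho = 0, enrichedSet = character(0),
                         effect = 0, nSamples = 2000L, panelSize = 500L,
                         seed = 1L) {
  if (ldRho < 0 || ldRho >= 1) stop("ldRho must lie in [0, 1)")
  if (panelSize < 50L) stop("panel must have at least 50 individuals")
  if (effect != 0 && length(enrichedSet) == 0L)
    stop("nonzero effect requires a non-empty enriched set")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  if (length(enrichedSet) && !all(enrichedSet %in% genes))
    stop("enriched-set gene ids must exist among the generated genes")
  # scalar: fixed SNPs per gene; length 2: per-gene uniform draw in range
  Kvec <- if (length(snpsPerGene) == 2L)
    sample(snpsPerGene[1]:snpsPerGene[2], nGenes, replace = TRUE)
  else rep(as.integer(snpsPerGene), nGenes)
  nSnps <- sum(Kvec)
  snpId <- sprintf("rs%05d", seq_len(nSnps))
  snpGene <- rep(genes, times = Kvec)
  chrom <- ((seq_len(nGenes) - 1L) %% 22L) + 1L
  withinChromIdx <- ave(seq_len(nGenes), chrom, FUN = seq_along)
  geneLen <- Kvec * 1000L + sample.int(5000L, nGenes, replace = TRUE)
  start <- (withinChromIdx - 1L) * 100000L          # 0-based
  end <- start + geneLen
  geneLoc <- data.frame(chrom = paste0("chr", chrom), start = start,
                        end = end, gene = genes, stringsAsFactors = FALSE)
  # SNP positions: 1-based bp inside the gene body
  bp <- rep(start, times = Kvec) +
        unlist(lapply(Kvec, seq_len), use.names = FALSE) * 999L
  chromSnp <- rep(paste0("chr", chrom), times = Kvec)
  geneOfSnp <- rep(seq_len(nGenes), times = Kvec)

  rhoL <- sin(pi * ldRho / 2)   # latent correlation giving dosage corr ldRho
  drawDosage <- function(nInd) {
    g <- matrix(0L, nInd, nSnps)
    for (h in 1:2) {
      f <- matrix(rnorm(nInd * nGenes), nInd)[, geneOfSnp, drop = FALSE]
      liab <- sqrt(rhoL) * f + sqrt(1 - rhoL) * matrix(rnorm(nInd * nSnps), nInd)
      g <- g + (liab > 0)
    }
    dimnames(g) <- list(sprintf("ind%04d", seq_len(nInd)), snpId)
    g
  }
  G <- drawDosage(nSamples)
  causal <- snpGene %in% enrichedSet
  y <- rnorm(nSamples)
  if (effect != 0 && any(causal)) {
    Gs <- scale(G[, causal, drop = FALSE])
    Gs[is.na(Gs)] <- 0
    y <- y + rowSums(Gs) * effect
  }
  r <- suppressWarnings(cor(G, y))
  r[is.na(r)] <- 0
  tstat <- r * sqrt((nSamples - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = nSamples - 2)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  summary <- data.frame(SNP = snpId, CHR = chromSnp, BP = bp,
                        P = as.numeric(p), N = nSamples,
                        stringsAsFactors = FALSE)
  panel <- drawDosage(panelSize)
  list(summary = summary, panel = panel, geneLoc = geneLoc,
       truth = list(enrichedSet = enrichedSet, effect = effect,
                    snpGene = setNames(snpGene, snpId)))
}
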