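# End-to-end orchestration: a declarative config, a synthetic demo
# scenario with planted truth, and a stage-ordered runner with a
# reproducibility manifest.

#' Pipeline configuration
#'
#' All stage parameters with their standard defaults (8 mm smoothing
#' kernel, 2 mm sample-assignment threshold, scale-free fit target 0.9,
#' minimum module size 50, deep split 2, eigengene merge height 0.1, pSI
#' threshold 0.05, alpha 0.05, gene-body SNP annotation window), plus the
#' input/output directories and a master seed from which every stage
#' derives a named substream.
#'
#' @param inputDir directory holding the scenario inputs (see
#'   \code{\link{simulateScenario}} for the file layout).
#' @param outDir output directory (created if missing).
#' @param fwhm smoothing FWHM in mm.
#' @param maxDistance sample assignment threshold in mm.
#' @param fitTarget scale-free fit target for soft-power selection.
#' @param minModuleSize,deepSplit,mergeHeight module detection parameters.
#' @param psiThreshold pSI cutoff for cell-type gene lists.
#' @param alpha family-wise significance level.
#' @param nPermutations pSI permutations.
#' @param windowBp SNP-to-gene annotation window in bp.
#' @param seed master seed.
#' @return a config list (class "imgtxConfig").
#' @export
pipelineConfig <- function(inputDir, outDir, fwhm = 8, maxDistance = 2,
                           fitTarget = 0.9, minModuleSize = 50L,
                           deepSplit = 2L, mergeHeight = 0.1,
                           psiThreshold = 0.05, alpha = 0.05,
                           nPermutations = 10000L, windowBp = 0L,
                           seed = 1L) {
  cfg <- list(inputDir = inputDir, outDir = outDir, fwhm = fwhm,
              maxDistance = maxDistance, fitTarget = fitTarget,
              minModuleSize = as.integer(minModuleSize),
              deepSplit = as.integer(deepSplit), mergeHeight = mergeHeight,
              psiThreshold = psiThreshold, alpha = alpha,
              nPermutations = as.integer(nPermutations),
              windowBp = as.integer(windowBp), seed = as.integer(seed))
  class(cfg) <- "imgtxConfig"
  cfg
}

#' Generate a complete synthetic scenario on disk
#'
#' Writes every input the pipeline consumes, with planted ground truth:
#' an atlas parcellation and mask, three BOLD runs with region-graded
#' synchrony weights, a probe x sample expression table with three planted
#' modules (target Spearman correlations with the discovery zReHo of
#' 0.75, -0.6 and 0), cell-type RNA-seq counts with planted astrocyte and
#' microglia markers drawn from the first two modules, GWAS summary
#' statistics with the first module as the enriched set, a small GMT
#' collection containing a planted term, and a truth.json.
#'
#' @param dir output directory.
#' @param seed master seed (stage substreams are derived from it).
#' @param shape grid dimensions (default 14^3, spherical mask radius 6).
#' @param nRegions atlas regions (default 48).
#' @param nTimepoints BOLD timepoints (default 120).
#' @param nGenes genes (default 240; three 60-gene planted modules).
#' @return invisibly, the list of written paths plus the in-memory truth.
#' @export
simulateScenario <- function(dir, seed = 7L, shape = c(14L, 14L, 14L),
                             nRegions = 48L, nTimepoints = 120L,
                             nGenes = 240L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  ctr <- (shape - 1) / 2
  co <- which(array(TRUE, shape), arr.ind = TRUE)
  mask <- array(sqrt(colSums((t(co) - ctr)^2)) <= 6, shape)
  atlas <- simulateParcellation(shape, nRegions, mask,
                                seed = substreamSeed(seed, "parcellation"))
  w <- array(0, shape)
  w[mask] <- 0.15 + 0.7 * (atlas[mask] - 1) / (nRegions - 1)
  writeVolume(mask + 0, p("mask.nii.gz"))
  writeVolume(atlas, p("atlas.nii.gz"))
  writeVolume(w, p("sync_weights.nii.gz"))
  datasets <- c("discovery", "replication1", "replication2")
  for (i in seq_along(datasets)) {
    bold <- simulateBold(shape, nTimepoints, w,
                         seed = substreamSeed(seed, "bold") + i,
                         mask = mask, parcellation = atlas)
    writeVolume(boldData(bold), p(paste0("bold_", datasets[i], ".nii.gz")))
  }
  # discovery-phenotype for the planted expression modules
  bold1 <- simulateBold(shape, nTimepoints, w,
                        seed = substreamSeed(seed, "bold") + 1L,
                        mask = mask, parcellation = atlas)
  z1 <- smoothMap(zStandardize(rehoMap(bold1)), fwhm = 8)
  pheno <- regionalMean(z1, atlas)

  expr <- simulateExpression(atlas, pheno, nGenes = nGenes, nModules = 3L,
                             plantedR = c(0.75, -0.6, 0), noiseSd = 0.3,
                             nDonors = 2L, genesPerModule = 60L,
                             samplesPerRegion = 2L, outsideFraction = 0.05,
                             mismatchFraction = 0.03,
                             seed = substreamSeed(seed, "expression"))
  writeTsv(expr$expression, p("expression.tsv"), rowNamesColumn = "probe_id")
  writeTsv(expr$aboveBackground + 0, p("above_background.tsv"),
           rowNamesColumn = "probe_id")
  writeTsv(expr$probes, p("probes.tsv"))
  writeTsv(expr$samples, p("samples.tsv"))
  writeTsv(expr$reference, p("reference.tsv"), rowNamesColumn = "gene")

  truth <- expr$truth
  m1 <- names(truth$moduleMembership)[truth$moduleMembership == "M1"]
  m2 <- names(truth$moduleMembership)[truth$moduleMembership == "M2"]
  bg <- names(truth$moduleMembership)[truth$moduleMembership == "none"]
  markers <- list(astrocyte = m1[seq_len(min(40L, length(m1)))],
                  microglia = m2[seq_len(min(40L, length(m2)))],
                  neuron = bg[seq_len(min(20L, length(bg)))])
  cellTypes <- c("astrocyte", "endothelial", "microglia", "neuron",
                 "oligodendrocyte")
  ct <- simulateCellTypeCounts(nGenes, cellTypes, markers, foldChange = 20,
                               nReplicates = 3L,
                               seed = substreamSeed(seed, "celltype"))
  writeTsv(ct$counts, p("celltype_counts.tsv"), rowNamesColumn = "gene")
  writeTsv(data.frame(gene = names(ct$geneLengths),
                      length_bp = as.integer(ct$geneLengths)),
           p("gene_lengths.tsv"))
  writeTsv(data.frame(sample_id = names(ct$sampleType),
                      cell_type = as.character(ct$sampleType)),
           p("sample_types.tsv"))

  gw <- simulateGwas(nGenes, snpsPerGene = c(3L, 10L), ldRho = 0.3,
                     enrichedSet = m1, effect = 0.025, nSamples = 3000L,
                     panelSize = 300L, seed = substreamSeed(seed, "gwas"))
  writeGwasSummary(gw$summary, p("gwas_summary.txt"))
  writeTsv(gw$panel, p("panel.tsv"), rowNamesColumn = "individual")
  writeGeneLocations(gw$geneLoc, p("gene_locations.bed"))

  set.seed(substreamSeed(seed, "demo"))
  sets <- c(list(PLANTED_TERM = m1[6:min(50L, length(m1))]),
            setNames(lapply(1:5, function(i)
              sample(bg, min(30L, length(bg)))),
              paste0("RANDOM_TERM_", 1:5)))
  writeGmt(sets, p("sets.gmt"))

  truthOut <- list(
    plantedModules = list(M1 = m1, M2 = m2,
                          M3 = names(truth$moduleMembership)[
                            truth$moduleMembership == "M3"]),
    plantedR = as.list(truth$plantedR),
    markers = markers,
    enrichedSet = m1,
    outsideSamples = truth$outsideSamples,
    flippedSamples = truth$flippedSamples,
    datasets = datasets)
  writeTruth(truthOut, p("truth.json"))
  invisible(list(dir = dir, truth = truthOut))
}

stageStep <- function(name, fun) {
  tryCatch(fun(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order against a scenario directory:
#' ReHo mapping and regional aggregation per dataset, expression
#' preprocessing, module detection, spatial association with the
#' replication rule, cell-type specificity of the replicated modules, and
#' GWAS gene-set enrichment for the cell-type-specific replicated modules.
#' Every stage writes its outputs under \code{config$outDir}; a manifest
#' (parameters, package version, input/output MD5 digests) is written
#' last, so an identical re-run reproduces identical digests.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the stage results and the manifest path.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "imgtxConfig"))
  ind <- config$inputDir; outd <- config$outDir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  ip <- function(f) file.path(ind, f)
  op <- function(f) file.path(outd, f)
  for (f in c("atlas.nii.gz", "mask.nii.gz", "expression.tsv"))
    if (!file.exists(ip(f))) stop("missing input: ", ip(f))

  atlas <- readVolume(ip("atlas.nii.gz"))
  vs <- atlas$voxelSize
  atlasArr <- array(as.integer(round(atlas$data)), dim(atlas$data))
  mask <- readVolume(ip("mask.nii.gz"))$data > 0

  boldFiles <- list.files(ind, pattern = "^bold_.*\\.nii(\\.gz)?$",
                          full.names = TRUE)
  datasets <- sub("^bold_(.*)\\.nii(\\.gz)?$", "\\1", basename(boldFiles))
  regional <- stageStep("reho", function() {
    out <- list()
    for (i in seq_along(boldFiles)) {
      vol <- readVolume(boldFiles[i])
      bold <- BoldSeries(vol$data, mask, vs)
      zmap <- smoothMap(zStandardize(rehoMap(bold)), fwhm = config$fwhm)
      rv <- regionalMean(zmap, atlasArr)
      writeVolume(rehoValues(zmap),
                  op(paste0("zreho_", datasets[i], ".nii.gz")), vs)
      writeTsv(data.frame(label = names(regionValues(rv)),
                          mean_zreho = as.numeric(regionValues(rv)),
                          n_voxels = as.integer(regionCounts(rv))),
               op(paste0("zreho_regions_", datasets[i], ".tsv")))
      out[[datasets[i]]] <- rv
    }
    out
  })

  exprMat <- stageStep("expression", function() {
    raw <- list(expression = readTsvMatrix(ip("expression.tsv")),
                aboveBackground = readTsvMatrix(ip("above_background.tsv")) > 0,
                probes = read.delim(ip("probes.tsv"),
                                    stringsAsFactors = FALSE),
                samples = read.delim(ip("samples.tsv"),
                                     stringsAsFactors = FALSE),
                reference = readTsvMatrix(ip("reference.tsv")))
    m <- prepareExpression(raw, atlasArr, vs, config$maxDistance)
    writeTsv(m, op("region_by_gene.tsv"), rowNamesColumn = "region")
    m
  })

  mods <- stageStep("modules", function() {
    res <- detectModules(exprMat, fitTarget = config$fitTarget,
                         minModuleSize = config$minModuleSize,
                         deepSplit = config$deepSplit,
                         mergeHeight = config$mergeHeight)
    writeTsv(data.frame(gene = names(moduleLabels(res$assignment)),
                        module = as.character(moduleLabels(res$assignment))),
             op("gene_modules.tsv"))
    if (!is.null(res$eigengenes))
      writeTsv(res$eigengenes, op("module_eigengenes.tsv"),
               rowNamesColumn = "module")
    if (!is.null(res$fitTable)) writeTsv(res$fitTable, op("soft_power_fit.tsv"))
    res
  })

  assoc <- stageStep("association", function() {
    res <- lapply(names(regional), function(d)
      spearmanAssoc(mods$eigengenes, regional[[d]], dataset = d))
    tab <- do.call(rbind, res)
    bc <- bonferroniCorrect(tab$p, m = nrow(mods$eigengenes))
    tab$p_bonferroni <- bc$padj
    writeTsv(tab, op("associations.tsv"))
    rep <- replicateModules(res, alpha = config$alpha)
    writeTsv(rep, op("replicated_modules.tsv"))
    list(byDataset = res, replication = rep)
  })
  repMods <- assoc$replication$module[assoc$replication$replicated]

  ctres <- stageStep("celltype", function() {
    counts <- readTsvMatrix(ip("celltype_counts.tsv"))
    lens <- read.delim(ip("gene_lengths.tsv"), stringsAsFactors = FALSE)
    lens <- setNames(lens$length_bp, lens$gene)
    st <- read.delim(ip("sample_types.tsv"), stringsAsFactors = FALSE)
    st <- setNames(st$cell_type, st$sample_id)
    prof <- cellTypeProfiles(rpkm(counts, lens), st)
    ps <- psiScores(prof, nPermutations = config$nPermutations,
                    seed = substreamSeed(config$seed, "celltype"))
    lists <- enrichedGeneLists(ps$psi, config$psiThreshold)
    background <- colnames(exprMat)
    modGenes <- setNames(lapply(repMods, function(m)
      intersect(moduleGenes(mods$assignment, m), background)), repMods)
    ov <- moduleOverlap(modGenes, lists, background, config$alpha)
    writeTsv(ov, op("celltype_overlap.tsv"))
    list(psi = ps, lists = lists, overlap = ov)
  })
  ctSig <- ctres$overlap[ctres$overlap$padj < config$alpha, , drop = FALSE]
  ctMods <- unique(ctSig$module)

  gwres <- stageStep("disorder", function() {
    if (!file.exists(ip("gwas_summary.txt"))) return(NULL)
    summ <- readGwasSummary(ip("gwas_summary.txt"))
    panel <- readTsvMatrix(ip("panel.tsv"))
    gl <- readGeneLocations(ip("gene_locations.bed"))
    mapping <- mapSnpsToGenes(summ, gl, config$windowBp)
    rec <- geneAnalysis(summ, panel, mapping, gl)
    writeTsv(rec, op("gene_analysis.tsv"))
    gc <- geneGeneCorrelation(panel, mapping[rec$gene],
                              setNames(gl$chrom, gl$gene))
    testMods <- if (length(ctMods)) ctMods else repMods
    setTests <- lapply(testMods, function(m) {
      genes <- moduleGenes(mods$assignment, m)
      cbind(module = m,
            competitiveSetTest(rec, genes, gc, nSets = length(testMods)))
    })
    tests <- if (length(setTests)) do.call(rbind, setTests) else NULL
    if (!is.null(tests)) writeTsv(tests, op("geneset_tests.tsv"))
    sigGenes <- lapply(setNames(testMods, testMods), function(m)
      withinSetGeneSignificance(rec, moduleGenes(mods$assignment, m),
                                config$alpha))
    enr <- NULL
    if (file.exists(ip("sets.gmt")) && length(testMods)) {
      sets <- readGmt(ip("sets.gmt"))
      enr <- fisherFdrEnrichment(moduleGenes(mods$assignment, testMods[1]),
                                 sets, colnames(exprMat))
      writeTsv(enr, op("go_enrichment.tsv"))
    }
    list(records = rec, setTests = tests, withinSet = sigGenes,
         goEnrichment = enr)
  })

  manifest <- list(
    package = "imgtx",
    version = as.character(utils::packageVersion("imgtx")),
    parameters = unclass(config),
    datasets = datasets,
    inputs = as.list(tools::md5sum(list.files(ind, full.names = TRUE))),
    outputs = as.list(tools::md5sum(list.files(outd, full.names = TRUE,
                                               pattern = "\\.(tsv|nii|gz)$"))))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(regional = regional, expression = exprMat, modules = mods,
                 association = assoc, celltype = ctres, disorder = gwres,
                 manifest = op("manifest.json")))
}

# majority-vote mapping of detected modules onto planted modules
matchPlanted <- function(assignment, plantedModules) {
  sz <- moduleSizes(assignment)
  out <- setNames(character(length(sz)), names(sz))
  for (m in names(sz)) {
    genes <- moduleGenes(assignment, m)
    ov <- vapply(plantedModules, function(pg)
      length(intersect(genes, pg)) / length(genes), 0)
    out[m] <- if (max(ov) >= 0.5) names(plantedModules)[which.max(ov)]
              else "none"
  }
  out
}

#' One-command synthetic demo
#'
#' Simulates a full scenario with planted truth, runs the pipeline on it,
#' and evaluates recovery: does the replication rule recover exactly the
#' planted ReHo-correlated modules, is the planted cell type flagged for
#' them, and is the planted GWAS-enriched module significant in the
#' competitive test?
#'
#' @param seed master seed (default 7).
#' @param dir working directory (default a tempdir).
#' @param nPermutations pSI permutations for the demo (default 1000).
#' @return list with \code{checks} (named logicals), the truth, the
#'   detected-to-planted module map, and the pipeline results.
#' @export
demoPipeline <- function(seed = 7L, dir = tempfile("imgtx_demo_"),
                         nPermutations = 1000L) {
  sc <- simulateScenario(file.path(dir, "inputs"), seed = seed)
  cfg <- pipelineConfig(file.path(dir, "inputs"), file.path(dir, "outputs"),
                        nPermutations = nPermutations, seed = seed)
  res <- runPipeline(cfg)
  truth <- sc$truth
  map <- matchPlanted(res$modules$assignment, truth$plantedModules)
  rep <- res$association$replication
  repPlanted <- sort(unique(map[rep$module[rep$replicated]]))
  wantPlanted <- names(truth$plantedR)[unlist(truth$plantedR) != 0]

  ov <- res$celltype$overlap
  ctHit <- function(planted, type) {
    mods <- names(map)[map == planted]
    any(ov$module %in% mods & ov$cellType == type & ov$padj < cfg$alpha)
  }
  gw <- res$disorder$setTests
  gwHit <- if (is.null(gw)) NA else {
    mods <- names(map)[map == "M1"]
    any(gw$module %in% mods & gw$padj < cfg$alpha)
  }
  checks <- c(
    replicatedModulesMatchPlanted = setequal(repPlanted, wantPlanted),
    nullModuleNotReplicated = !any(map[rep$module[rep$replicated]] == "M3"),
    astrocyteModuleFlagged = ctHit("M1", "astrocyte"),
    microgliaModuleFlagged = ctHit("M2", "microglia"),
    gwasEnrichedModuleFlagged = isTRUE(gwHit))
  list(checks = checks, truth = truth, moduleMap = map, results = res,
       dir = dir)
}
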