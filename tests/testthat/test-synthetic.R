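test_that("generators are pure functions of their seed", {
  b1 <- simulateBold(c(5, 5, 5), 20, 0.5, seed = 3)
  b2 <- simulateBold(c(5, 5, 5), 20, 0.5, seed = 3)
  expect_identical(boldData(b1), boldData(b2))
  p1 <- simulateParcellation(c(8, 8, 8), 6, seed = 5)
  expect_identical(p1, simulateParcellation(c(8, 8, 8), 6, seed = 5))
  ct1 <- simulateCellTypeCounts(50, c("a", "b"), seed = 2)
  ct2 <- simulateCellTypeCounts(50, c("a", "b"), seed = 2)
  expect_identical(ct1$counts, ct2$counts)
  g1 <- simulateGwas(10, 4, seed = 6)
  g2 <- simulateGwas(10, 4, seed = 6)
  expect_identical(g1$summary, g2$summary)
  expect_identical(g1$panel, g2$panel)
})

test_that("generator contracts reject invalid inputs", {
  expect_error(simulateBold(c(2, 5, 5), 20, 0.5), "dimension")
  expect_error(simulateBold(c(5, 5, 5), 5, 0.5), "nTimepoints")
  expect_error(simulateBold(c(5, 5, 5), 20, 1.2), "\\[0, 1\\]")
  expect_error(simulateParcellation(c(3, 3, 3), 100), "exceeds")
  expect_error(simulateCellTypeCounts(50, "onlyone"), "2 cell types")
  expect_error(simulateCellTypeCounts(
    50, c("a", "b"), markers = list(a = "G0001", b = "G0001")), "disjoint")
  expect_error(simulateGwas(10, 4, ldRho = 1), "ldRho")
  expect_error(simulateGwas(10, 4, panelSize = 10), "panel")
  expect_error(simulateGwas(10, 4, effect = 0.5), "enriched set")
})

test_that("parcellation labels partition the mask with no empty region", {
  shape <- c(12, 12, 12)
  mask <- sphereMask(shape)
  parc <- simulateParcellation(shape, 10, mask, seed = 4)
  expect_true(all(parc[!mask] == 0L))
  expect_true(all(parc[mask] > 0L))
  expect_setequal(unique(parc[mask]), 1:10)
  parc1 <- simulateParcellation(shape, 1, mask, seed = 4)
  expect_true(all(parc1[mask] == 1L))
})

test_that("zero-synchrony BOLD matches the null expectation of Kendall's W", {
  # Monte-Carlo oracle: W over 27 independent rank sequences of length n
  set.seed(10)
  n <- 200
  oracle <- mean(replicate(300, bruteKcc(matrix(rnorm(27 * n), 27))))
  b <- simulateBold(c(7, 7, 7), n, syncWeights = 0, seed = 12)
  rmap <- rehoMap(b)
  interior <- array(FALSE, c(7, 7, 7)); interior[2:6, 2:6, 2:6] <- TRUE
  got <- mean(rehoValues(rmap)[interior & neighborCounts(rmap) == 27L])
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("planted expression modules have the promised geometry", {
  shape <- c(10, 10, 10)
  mask <- sphereMask(shape)
  parc <- simulateParcellation(shape, 30, mask, seed = 2)
  pheno <- RegionValues(setNames(rnorm(30), as.character(1:30)))
  # noiseless, planted r = 1: member profiles rank-identical to phenotype
  ex <- simulateExpression(parc, pheno, nGenes = 30, nModules = 1,
                           plantedR = 1, noiseSd = 0, genesPerModule = 10,
                           seed = 3)
  m1 <- names(ex$truth$moduleMembership)[ex$truth$moduleMembership == "M1"]
  lat <- ex$truth$latents["M1", ]
  expect_equal(rank(lat), rank(regionValues(pheno)))
  # planted memberships all exist in the emitted matrices
  expect_true(all(names(ex$truth$moduleMembership) %in% ex$probes$gene))
  expect_true(all(names(ex$truth$moduleMembership) %in% rownames(ex$reference)))
})

test_that("planted module-phenotype correlation is recovered by eigengenes", {
  shape <- c(12, 12, 12)
  mask <- sphereMask(shape)
  parc <- simulateParcellation(shape, 200, mask, seed = 5)
  pheno <- RegionValues(setNames(rnorm(200), as.character(1:200)))
  rec <- vapply(1:20, function(s) {
    ex <- simulateExpression(parc, pheno, nGenes = 30, nModules = 1,
                             plantedR = 0.8, noiseSd = 0.3,
                             genesPerModule = 30, probesPerGene = 1,
                             nDonors = 1, seed = s)
    truthAssign <- ModuleAssignment(ex$truth$moduleMembership,
                                    background = "none")
    prof <- t(ex$reference)
    rownames(prof) <- ex$truth$sampleRegion[rownames(prof)]
    me <- moduleEigengenes(prof, truthAssign)
    cor(me["M1", names(regionValues(pheno))], rank(regionValues(pheno)),
        method = "spearman")
  }, 0)
  expect_lt(abs(mean(rec) - 0.8), 0.1)
})

test_that("out-of-atlas samples are planted beyond the assignment threshold", {
  shape <- c(10, 10, 10)
  mask <- sphereMask(shape, 3.5)
  parc <- simulateParcellation(shape, 12, mask, seed = 7)
  pheno <- RegionValues(setNames(rnorm(12), as.character(1:12)))
  ex <- simulateExpression(parc, pheno, nGenes = 20, nModules = 1,
                           plantedR = 0.5, genesPerModule = 8,
                           outsideFraction = 0.2, seed = 9)
  expect_gt(length(ex$truth$outsideSamples), 0)
  asn <- assignSamples(ex$samples, parc)
  out <- asn[asn$sample_id %in% ex$truth$outsideSamples, ]
  expect_true(all(out$excluded_reason == "distance"))
  expect_true(all(out$distance_mm > 2))
})

test_that("null cell-type counts give uniform pSI downstream", {
  ct <- simulateCellTypeCounts(1000, c("a", "b", "c", "d"), markers = list(),
                               nReplicates = 3, seed = 21)
  prof <- cellTypeProfiles(rpkm(ct$counts, ct$geneLengths), ct$sampleType)
  ps <- psiScores(prof, nPermutations = 300, seed = 1)
  ks <- suppressWarnings(ks.test(ps$psi[, "a"], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("null GWAS p-values are uniform and zero-LD panels are uncorrelated", {
  gw <- simulateGwas(50, 100, ldRho = 0, effect = 0, nSamples = 500,
                     panelSize = 500, seed = 13)
  ks <- suppressWarnings(ks.test(gw$summary$P, "punif"))
  expect_gt(ks$p.value, 0.01)
  sub <- gw$panel[, sample.int(ncol(gw$panel), 80)]
  cc <- cor(sub)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.2)
  # within a gene, planted exchangeable LD is realized
  gw2 <- simulateGwas(20, 10, ldRho = 0.5, nSamples = 4000,
                      panelSize = 100, seed = 14)
  g1 <- gw2$truth$snpGene == "G0001"
  cc2 <- cor(gw2$panel[, g1])
  expect_equal(mean(cc2[upper.tri(cc2)]), 0.5, tolerance = 0.12)
})
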