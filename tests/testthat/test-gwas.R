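test_that("SNP-to-gene mapping honors the half-open interval convention", {
  gl <- data.frame(chrom = "chr1", start = 1000L, end = 2000L, gene = "gA",
                   stringsAsFactors = FALSE)
  summ <- data.frame(SNP = c("mid", "past", "atStart", "atEnd"),
                     CHR = "chr1", BP = c(1500L, 2001L, 1001L, 2000L),
                     P = 0.5, N = 100L, stringsAsFactors = FALSE)
  mp <- mapSnpsToGenes(summ, gl)
  expect_setequal(mp$gA, c("mid", "atStart", "atEnd"))
  mpW <- mapSnpsToGenes(summ, gl, windowBp = 10L)
  expect_true("past" %in% mpW$gA)
  # interval-scan oracle on a random fixture; multi-gene SNPs allowed
  set.seed(70)
  gl2 <- data.frame(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                    start = sample.int(5000, 10), gene = paste0("g", 1:10),
                    stringsAsFactors = FALSE)
  gl2$end <- gl2$start + sample.int(3000, 10)
  summ2 <- data.frame(SNP = paste0("rs", 1:100),
                      CHR = sample(c("chr1", "chr2"), 100, TRUE),
                      BP = sample.int(9000, 100), P = 0.5, N = 10L,
                      stringsAsFactors = FALSE)
  mp2 <- mapSnpsToGenes(summ2, gl2)
  for (i in 1:10) {
    want <- summ2$SNP[summ2$CHR == gl2$chrom[i] &
                      summ2$BP > gl2$start[i] & summ2$BP <= gl2$end[i]]
    expect_setequal(mp2[[gl2$gene[i]]], want)
  }
})

test_that("weighted chi-square tail: one weight collapses to pchisq,
           Imhof and Satterthwaite agree where both are valid", {
  expect_equal(weightedChisqP(3.84, 1), pchisq(3.84, 1, lower.tail = FALSE))
  w <- rep(1 / 8, 8)   # identity LD: Q = chi2_8 / 8
  q <- qchisq(0.95, 8) / 8
  expect_equal(weightedChisqP(q, w), 0.05, tolerance = 1e-6)
  expect_equal(weightedChisqP(q, w, "satterthwaite"), 0.05, tolerance = 1e-9)
})

test_that("single-SNP genes return the SNP p exactly and Z = probit(1 - p)", {
  gw <- simulateGwas(5, 3, ldRho = 0.2, nSamples = 500, panelSize = 100,
                     seed = 71)
  mp <- mapSnpsToGenes(gw$summary, gw$geneLoc)
  mp1 <- list(G0001 = mp$G0001[2])
  rec <- geneAnalysis(gw$summary, gw$panel, mp1, gw$geneLoc)
  expect_identical(rec$p, unname(gw$summary$P[gw$summary$SNP == mp$G0001[2]]))
  expect_equal(rec$z, qnorm(1 - rec$p), tolerance = 1e-12)
})

test_that("gene Z decreases strictly in gene p and stays finite", {
  gw <- simulateGwas(40, c(2L, 8L), ldRho = 0.4, enrichedSet = "G0001",
                     effect = 0.05, nSamples = 1000, panelSize = 100,
                     seed = 72)
  mp <- mapSnpsToGenes(gw$summary, gw$geneLoc)
  rec <- geneAnalysis(gw$summary, gw$panel, mp, gw$geneLoc)
  expect_true(all(is.finite(rec$z)))
  ord <- order(rec$p)
  expect_true(all(diff(rec$z[ord]) <= 1e-12))
  # SNPs missing from the panel are dropped with a warning
  panel2 <- gw$panel[, -(1:2)]
  expect_warning(geneAnalysis(gw$summary, panel2, mp, gw$geneLoc),
                 "absent from the panel")
})

test_that("gene-gene correlation follows cross-LD, zero across chromosomes", {
  gw <- simulateGwas(8, 4, ldRho = 0.5, nSamples = 200, panelSize = 200,
                     seed = 73)
  mp <- mapSnpsToGenes(gw$summary, gw$geneLoc)
  chrom <- setNames(gw$geneLoc$chrom, gw$geneLoc$gene)
  gg <- geneGeneCorrelation(gw$panel, mp, chrom)
  expect_equal(diag(gg), setNames(rep(1, 8), names(mp)))
  expect_equal(gg["G0001", "G0002"], 0)   # different chromosomes
  # identical SNP sets correlate exactly 1
  mpDup <- list(gA = mp$G0001, gB = mp$G0001)
  ggDup <- geneGeneCorrelation(gw$panel, mpDup, c(gA = "chr1", gB = "chr1"))
  expect_equal(ggDup["gA", "gB"], 1, tolerance = 1e-12)
  # brute-force mean-r2 oracle for two genes sharing a chromosome
  gl <- gw$geneLoc
  sameChrom <- gl$gene[gl$chrom == gl$chrom[1]]
  if (length(sameChrom) >= 2) {
    g1 <- sameChrom[1]; g2 <- sameChrom[2]
    r2sum <- function(s1, s2) {
      out <- 0
      for (i in s1) for (j in s2)
        out <- out + cor(gw$panel[, i], gw$panel[, j])^2
      out
    }
    want <- r2sum(mp[[g1]], mp[[g2]]) /
      sqrt(r2sum(mp[[g1]], mp[[g1]]) * r2sum(mp[[g2]], mp[[g2]]))
    expect_equal(gg[g1, g2], want, tolerance = 1e-12)
  }
})

test_that("competitive test contract: strict subset, shift invariance", {
  rec <- nullGeneRecords(500, seed = 74)
  expect_error(competitiveSetTest(rec, rec$gene), "strict subset")
  expect_error(competitiveSetTest(rec, "absent"), "empty")
  set <- rec$gene[1:50]
  r1 <- suppressWarnings(competitiveSetTest(rec, set))
  rec2 <- rec; rec2$z <- rec2$z + 5    # intercept absorbs constant shifts
  r2 <- suppressWarnings(competitiveSetTest(rec2, set))
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
  # Bonferroni over the number of sets
  r5 <- suppressWarnings(competitiveSetTest(rec, set, nSets = 5))
  expect_equal(r5$padj, min(1, r5$p * 5))
})

test_that("collinear covariates are dropped with a warning, not an error", {
  rec <- nullGeneRecords(300, seed = 75)
  rec$lengthBp <- rec$nSnps * 1000          # force exact collinearity
  rec$density <- rec$nSnps / rec$lengthBp
  expect_warning(out <- competitiveSetTest(rec, rec$gene[1:30]),
                 "collinear")
  expect_true(is.finite(out$p))
})

test_that("within-set significance reproduces the printed thresholds", {
  rec <- nullGeneRecords(200, seed = 76)
  r94 <- withinSetGeneSignificance(rec, rec$gene[1:94])
  expect_equal(r94$threshold, 0.05 / 94)
  r101 <- withinSetGeneSignificance(rec, rec$gene[1:101])
  expect_equal(r101$threshold, 0.05 / 101)
  # boundary: p exactly at the threshold is excluded
  rec2 <- rec[1:10, ]; rec2$p <- rep(0.05 / 10, 10)
  expect_length(withinSetGeneSignificance(rec2, rec2$gene)$genes, 0)
})

test_that("Fisher/FDR enrichment follows the BH step-up exactly", {
  bg <- sprintf("G%03d", 1:100)
  # analytic BH example: p = (.01, .02, .03) -> q = .03 for all three
  p <- c(0.01, 0.02, 0.03)
  q <- p.adjust(p, "BH")
  expect_equal(q, rep(0.03, 3))
  # planted-term fixture vs hypergeometric + step-up oracle
  set.seed(77)
  colls <- list(planted = bg[1:20], rand1 = sample(bg, 15),
                rand2 = sample(bg, 25), outside = paste0("X", 1:5))
  query <- bg[1:15]
  out <- fisherFdrEnrichment(query, colls, bg)
  expect_false("outside" %in% out$term)    # empty intersection skipped
  pOracle <- vapply(out$term, function(tm) {
    tg <- intersect(colls[[tm]], bg)
    bruteHyperTail(length(intersect(query, tg)), length(tg),
                   length(query), length(bg))
  }, 0)
  expect_equal(out$p, unname(pOracle), tolerance = 1e-12)
  expect_equal(out$q, p.adjust(out$p, "BH"))
  one <- fisherFdrEnrichment(query, colls["planted"], bg)
  expect_equal(one$q, one$p)               # single term: q = p
  expect_error(fisherFdrEnrichment("X1", colls, bg), "subset")
})
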