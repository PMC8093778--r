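test_that("intensity filter applies the above-background fraction rule", {
  ex <- matrix(rnorm(500), 100, 5,
               dimnames = list(sprintf("p%03d", 1:100), paste0("s", 1:5)))
  set.seed(6)
  ab <- matrix(runif(500) < 0.6, 100, 5, dimnames = dimnames(ex))
  ab[1, ] <- c(TRUE, TRUE, FALSE, FALSE, FALSE)   # 40%: removed
  ab[2, ] <- c(TRUE, TRUE, TRUE, FALSE, FALSE)    # 60%: kept
  out <- intensityFilter(ex, ab)
  expect_false("p001" %in% rownames(out))
  expect_true("p002" %in% rownames(out))
  # kept set equals the explicit loop
  keep <- character(0)
  for (i in 1:100) if (sum(ab[i, ]) / 5 >= 0.5) keep <- c(keep, rownames(ex)[i])
  expect_identical(rownames(out), keep)
  expect_identical(unname(attr(out, "report")["kept"]), length(keep))
  expect_error(intensityFilter(ex, ab, minFraction = 1.01), "every probe")
})

test_that("probe selection maximizes reference correlation, with fallback", {
  set.seed(12)
  nS <- 20
  ref <- matrix(rnorm(3 * nS), 3, nS,
                dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:nS)))
  mk <- function(base, noise) base + rnorm(nS, 0, noise)
  ex <- rbind(gA_p1 = mk(ref["gA", ], 0.1), gA_p2 = mk(ref["gA", ], 3),
              gB_p1 = mk(ref["gB", ], 2), gB_p2 = mk(ref["gB", ], 0.05),
              gC_p1 = mk(ref["gC", ], 1),
              gD_p1 = rnorm(nS, 5), gD_p2 = rnorm(nS, 1))
  colnames(ex) <- paste0("s", 1:nS)
  pg <- setNames(c("gA", "gA", "gB", "gB", "gC", "gD", "gD"), rownames(ex))
  out <- selectProbes(ex, pg, ref)
  sel <- attr(out, "selectedProbe")
  # exhaustive-correlation oracle for the reference-covered genes
  for (g in c("gA", "gB")) {
    cand <- names(pg)[pg == g]
    cc <- apply(ex[cand, ], 1, cor, y = ref[g, ])
    expect_identical(unname(sel[g]), names(which.max(cc)))
  }
  expect_identical(unname(sel["gC"]), "gC_p1")       # single probe kept
  expect_identical(unname(sel["gD"]), "gD_p1")       # fallback: highest mean
})

test_that("sample assignment honors distance and hemisphere rules", {
  parc <- array(0L, c(9, 9, 9))
  parc[2, 5, 5] <- 1L      # left (x < centre)
  parc[8, 5, 5] <- 2L      # right
  vs <- c(3, 3, 3)
  mmL <- voxelToWorld(c(1, 4, 4), c(9, 9, 9), vs)   # centre of voxel [2,5,5]
  samples <- data.frame(
    sample_id = c("near", "far", "wronghemi"),
    hemisphere = c("L", "L", "R"),
    mni_x = mmL[1] + c(1.5, 2.5, 0), mni_y = mmL[2], mni_z = mmL[3],
    stringsAsFactors = FALSE)
  asn <- assignSamples(samples, parc, vs)
  expect_identical(asn$region, c("1", NA, NA))
  expect_identical(asn$excluded_reason, c("", "distance", "hemisphere"))
  expect_equal(asn$distance_mm[1], 1.5)
})

test_that("regional aggregation is a per-region mean with a dropped report", {
  gm <- rbind(g1 = c(2, 4, 7), g2 = c(0, 1, 5))
  colnames(gm) <- c("s1", "s2", "s3")
  asn <- c(s1 = "10", s2 = "10", s3 = "11")
  out <- aggregateRegions(gm, asn, allRegions = c("10", "11", "12"))
  expect_equal(out["10", "g1"], 3)
  expect_equal(out["11", "g2"], 5)
  expect_identical(attr(out, "droppedRegions"), "12")
  # group-by-mean oracle on a larger random fixture
  set.seed(20)
  gm2 <- matrix(rnorm(40 * 9), 9, 40,
                dimnames = list(paste0("g", 1:9), paste0("s", 1:40)))
  asn2 <- setNames(as.character(sample(1:6, 40, TRUE)), colnames(gm2))
  out2 <- aggregateRegions(gm2, asn2)
  for (r in rownames(out2)) for (g in rownames(gm2))
    expect_equal(out2[r, g], mean(gm2[g, names(asn2)[asn2 == r]]))
})

test_that("scaled robust sigmoid matches the hand-evaluated formula", {
  x <- c(0.1, 0.4, 0.5, 0.9, 1.4, 2.2, 7.0)
  s <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
  hand <- (s - min(s)) / (max(s) - min(s))
  m <- matrix(x, 7, 1, dimnames = list(paste0("r", 1:7), "g1"))
  expect_equal(srsNormalize(m)[, "g1"], setNames(hand, rownames(m)),
               tolerance = 1e-12)
  # sigmoid midpoint: the median value sits at 0.5 before rescaling
  expect_equal(s[x == median(x)], 0.5)
  expect_equal(range(srsNormalize(m)), c(0, 1))
})

test_that("srs normalisation preserves rank order and handles degeneracy", {
  set.seed(30)
  m <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(paste0("r", 1:50), paste0("g", 1:4)))
  out <- srsNormalize(m)[rownames(m), ]
  for (g in colnames(m)) expect_equal(rank(out[, g]), rank(m[, g]))
  # inter-region gene-profile correlations unchanged (rank preservation)
  expect_equal(cor(m, method = "spearman"),
               cor(out, method = "spearman"), tolerance = 1e-12)
  # constant gene: flat 0.5
  mc <- cbind(m, gconst = rep(2, 50))
  expect_true(all(srsNormalize(mc)[, "gconst"] == 0.5))
  # zero IQR but positive SD: SD fallback keeps monotonicity
  xz <- c(rep(1, 40), seq(2, 10, length.out = 10))
  mz <- matrix(xz, 50, 1, dimnames = list(paste0("r", 1:50), "g"))
  oz <- srsNormalize(mz)[rownames(mz), ]
  expect_equal(range(oz), c(0, 1))
  expect_true(all(diff(oz[order(xz)]) >= 0))
})

test_that("donor blocks are normalized separately then averaged", {
  set.seed(31)
  regions <- paste0("r", 1:12)
  mA <- matrix(rnorm(12 * 3, 10, 1), 12, 3,
               dimnames = list(regions, paste0("g", 1:3)))
  mB <- mA[1:10, ] * 5 + 40      # second donor: shifted and scaled
  rownames(mB) <- regions[1:10]
  out <- srsNormalize(list(donorA = mA, donorB = mB))
  expect_setequal(rownames(out), regions)
  # where both donors contribute, the combined value is the block mean
  nA <- apply(mA, 2, imgtx:::srsVector); rownames(nA) <- regions
  nB <- apply(mB, 2, imgtx:::srsVector); rownames(nB) <- regions[1:10]
  expect_equal(out["r3", "g2"], (nA["r3", "g2"] + nB["r3", "g2"]) / 2)
  expect_equal(out["r12", "g1"], nA["r12", "g1"])   # donor A only
})
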