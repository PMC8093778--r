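test_that("kcc hits the concordance boundaries", {
  expect_equal(kcc(matrix(rep(1:10, each = 27), 27, byrow = FALSE)), 1)
  expect_equal(kcc(rbind(1:4, 4:1)), 0)
  # monotone per-series transforms leave W unchanged
  set.seed(11)
  s <- matrix(rnorm(5 * 12), 5)
  w0 <- kcc(s)
  s2 <- rbind(exp(s[1, ]), s[2, ]^3 + 2, 5 * s[3, ] - 1, atan(s[4, ]),
              s[5, ])
  expect_equal(kcc(s2), w0, tolerance = 1e-14)
})

test_that("kcc equals the brute-force rank-sum evaluation, with ties", {
  set.seed(42)
  for (i in 1:25) {
    K <- sample(2:27, 1); n <- sample(4:30, 1)
    s <- matrix(sample(1:8, K * n, replace = TRUE), K)  # many ties
    expect_equal(kcc(s), bruteKcc(s), tolerance = 1e-12)
    s2 <- matrix(rnorm(K * n), K)
    expect_equal(kcc(s2), bruteKcc(s2), tolerance = 1e-12)
  }
})

test_that("kcc agrees with an independent reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  s <- matrix(rnorm(27 * 20), 27)
  ref <- vegan::kendall.global(t(s))$Concordance_analysis["W", 1]
  expect_equal(kcc(s), unname(ref), tolerance = 1e-12)
})

test_that("kcc rejects degenerate input and flags all-constant series", {
  expect_error(kcc(matrix(1:5, 1)), "2 series")
  expect_error(kcc(matrix(1:2, 2, 1)), "2 timepoints")
  expect_true(is.na(kcc(matrix(1, 3, 8))))
})

test_that("rehoMap equals a per-voxel loop over kcc, edges included", {
  set.seed(3)
  shape <- c(5, 5, 4)
  mask <- array(TRUE, shape); mask[1, 1, 1] <- FALSE
  dat <- array(rnorm(prod(shape) * 15), c(shape, 15))
  rmap <- rehoMap(BoldSeries(dat, mask))
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    pos <- sweep(as.matrix(nb), 2, idx[v, ], "+")
    ok <- apply(pos, 1, function(p) all(p >= 1) && all(p <= shape) &&
                  mask[p[1], p[2], p[3]])
    series <- t(apply(pos[ok, , drop = FALSE], 1, function(p)
      dat[p[1], p[2], p[3], ]))
    expect_identical(rehoValues(rmap)[idx[v, 1], idx[v, 2], idx[v, 3]],
                     min(max(kcc(series), 0), 1))
    expect_identical(neighborCounts(rmap)[idx[v, 1], idx[v, 2], idx[v, 3]],
                     sum(ok))
  }
})

test_that("fully synchronous volumes give W = 1 everywhere in the mask", {
  b <- simulateBold(c(5, 5, 5), 20, syncWeights = 1, seed = 2)
  rmap <- rehoMap(b)
  expect_true(all(abs(rehoValues(rmap)[boldMask(rmap)] - 1) < 1e-12))
})

test_that("isolated voxels get the NA sentinel", {
  shape <- c(5, 5, 5)
  mask <- array(FALSE, shape)
  mask[3, 3, 3] <- TRUE; mask[1, 1, 1] <- TRUE; mask[1, 1, 2] <- TRUE
  dat <- array(rnorm(prod(shape) * 12), c(shape, 12))
  expect_message(rmap <- rehoMap(BoldSeries(dat, mask)), "undefined")
  expect_true(is.na(rehoValues(rmap)[3, 3, 3]))
  expect_false(is.na(rehoValues(rmap)[1, 1, 1]))
})

test_that("zStandardize forces population mean 0 / SD 1 and preserves order", {
  shape <- c(4, 4, 4)
  mask <- array(FALSE, shape); mask[1:3, 1, 1] <- TRUE
  vals <- array(NA_real_, shape); vals[1:3, 1, 1] <- c(1, 2, 3) / 4
  k <- array(2L, shape)
  z <- zStandardize(imgtx:::RehoMap(vals, k, mask, c(3, 3, 3)))
  expect_equal(rehoValues(z)[mask], c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  # affine-invariance: a * W + b standardizes to the same map
  vals2 <- vals * 0.13 + 0.4
  z2 <- zStandardize(imgtx:::RehoMap(vals2, k, mask, c(3, 3, 3)))
  expect_equal(rehoValues(z2)[mask], rehoValues(z)[mask], tolerance = 1e-12)
  # constant map: zero SD is an error
  vals3 <- vals; vals3[1:3, 1, 1] <- 0.5
  expect_error(zStandardize(imgtx:::RehoMap(vals3, k, mask, c(3, 3, 3))),
               "zero standard deviation")
})

test_that("smoothing: identity at fwhm 0, unit-mass Gaussian on a delta", {
  set.seed(5)
  a <- array(rnorm(9 * 9 * 9), c(9, 9, 9))
  expect_identical(smoothMap(a, fwhm = 0), a)
  delta <- array(0, c(15, 15, 15)); delta[8, 8, 8] <- 1
  sm <- smoothMap(delta, fwhm = 8, voxelSize = c(3, 3, 3))
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  # kernel matches the closed-form sigma = fwhm / (2 sqrt(2 ln 2)) / voxel
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sigma, 1.1324, tolerance = 1e-4)
  r <- ceiling(4 * sigma)
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  expect_equal(sm[8 + (-r:r), 8, 8], k1 * k1[r + 1]^2, tolerance = 1e-12)
  expect_error(smoothMap(a, fwhm = -1), "non-negative")
})

test_that("regional means match an explicit per-label loop", {
  set.seed(8)
  shape <- c(8, 8, 8)
  parc <- simulateParcellation(shape, 7, seed = 1)
  vals <- array(rnorm(prod(shape)), shape)
  rv <- regionalMean(vals, parc)
  for (lab in names(regionValues(rv))) {
    sel <- parc == as.integer(lab)
    expect_equal(unname(regionValues(rv)[lab]), mean(vals[sel]))
    expect_equal(unname(regionCounts(rv)[lab]), sum(sel))
  }
  # single-voxel region and dropped empty labels
  parc2 <- array(0L, c(3, 3, 3)); parc2[1, 1, 1] <- 1L; parc2[2, 2, 2] <- 3L
  vals2 <- array(seq_len(27) / 27, c(3, 3, 3))
  rv2 <- regionalMean(vals2, parc2)
  expect_equal(unname(regionValues(rv2)["1"]), vals2[1, 1, 1])
  expect_false("2" %in% names(regionValues(rv2)))
  # a label whose voxels are all non-finite is dropped and reported
  vals2[2, 2, 2] <- NA
  rv3 <- regionalMean(vals2, parc2)
  expect_identical(attr(rv3, "dropped"), "3")
})

test_that("group maps average voxel-wise", {
  set.seed(4)
  a <- array(rnorm(64), c(4, 4, 4))
  expect_identical(groupMap(list(a)), a)
  expect_equal(groupMap(list(a, -a)), array(0, c(4, 4, 4)))
  maps <- lapply(1:5, function(i) array(rnorm(64), c(4, 4, 4)))
  expect_equal(groupMap(maps), Reduce(`+`, maps) / 5, tolerance = 1e-15)
  expect_error(groupMap(list(a, array(0, c(3, 3, 3)))), "grids differ")
})

test_that("regional ReHo increases with the planted synchrony weight", {
  shape <- c(10, 10, 10)
  parc <- simulateParcellation(shape, 20, seed = 3)
  w <- array(0, shape)
  w[parc > 0] <- (parc[parc > 0] - 1) / 19 * 0.9
  b <- simulateBold(shape, 200, w, seed = 9, parcellation = parc)
  rv <- regionalMean(rehoMap(b), parc)
  planted <- (as.integer(names(regionValues(rv))) - 1) / 19 * 0.9
  expect_gt(cor(planted, regionValues(rv), method = "spearman"), 0.9)
})
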