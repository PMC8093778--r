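# Shared fixture builders: everything is generated in code at test time.

# spherical gray-matter-like mask inside a cubic grid
sphereMask <- function(shape, radius = min(shape) / 2 - 0.8) {
  co <- which(array(TRUE, shape), arr.ind = TRUE)
  ctr <- (shape + 1) / 2
  array(sqrt(colSums((t(co) - ctr)^2)) <= radius, shape)
}

# independent brute-force evaluation of Kendall's W from the rank-sum
# definition (with the tie correction), written as plain loops
bruteKcc <- function(series) {
  K <- nrow(series); n <- ncol(series)
  r <- matrix(0, K, n)
  for (j in seq_len(K)) r[j, ] <- rank(series[j, ])
  R <- numeric(n)
  for (i in seq_len(n)) R[i] <- sum(r[, i])
  S <- sum((R - mean(R))^2)
  Tj <- 0
  for (j in seq_len(K)) {
    tb <- table(series[j, ])
    Tj <- Tj + sum(tb^3 - tb)
  }
  12 * S / (K^2 * (n^3 - n) - K * Tj)
}

# triple-loop brute-force topological overlap
bruteTom <- function(a) {
  m <- nrow(a)
  out <- diag(m)
  k <- numeric(m)
  for (i in seq_len(m)) k[i] <- sum(a[i, -i])
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(m)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exhaustive hypergeometric upper tail via binomial coefficients
bruteHyperTail <- function(overlap, listSize, moduleSize, background) {
  kmax <- min(listSize, moduleSize)
  num <- 0
  for (k in overlap:kmax)
    num <- num + choose(listSize, k) *
           choose(background - listSize, moduleSize - k)
  num / choose(background, moduleSize)
}

# two-block expression fixture: 100+100 genes on planted latents
twoBlockExpression <- function(nRegions = 200, blockSize = 100,
                               noiseSd = 0.3, seed = 1) {
  set.seed(seed)
  l1 <- rnorm(nRegions); l2 <- rnorm(nRegions)
  g1 <- matrix(l1, nRegions, blockSize) +
        matrix(rnorm(nRegions * blockSize, 0, noiseSd), nRegions)
  g2 <- matrix(l2, nRegions, blockSize) +
        matrix(rnorm(nRegions * blockSize, 0, noiseSd), nRegions)
  x <- cbind(g1, g2)
  dimnames(x) <- list(paste0("R", seq_len(nRegions)),
                      sprintf("G%03d", seq_len(2 * blockSize)))
  list(expr = x, truth = rep(c(1L, 2L), each = blockSize),
       latents = cbind(l1, l2))
}

# small synthetic gene-analysis records table (null unless shift given)
nullGeneRecords <- function(nGenes, seed, shiftGenes = character(0),
                            shift = 0) {
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(nGenes))
  z <- rnorm(nGenes)
  z[genes %in% shiftGenes] <- z[genes %in% shiftGenes] + shift
  nsnp <- sample(2:30, nGenes, replace = TRUE)
  len <- nsnp * 1000 + sample.int(20000, nGenes, replace = TRUE)
  data.frame(gene = genes, nSnps = nsnp, stat = NA_real_,
             p = pnorm(z, lower.tail = FALSE), z = z,
             lengthBp = len, density = nsnp / len,
             meanMac = runif(nGenes, 50, 150), stringsAsFactors = FALSE)
}
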