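# Regional homogeneity: Kendall's W over voxel neighbourhoods, voxel-wise
# mapping, z-standardisation, Gaussian smoothing and atlas aggregation.

#' Kendall's coefficient of concordance (KCC)
#'
#' Concordance W in [0, 1] of K time series of common length n, computed
#' from midranks with the standard tie correction:
#' \deqn{W = \frac{12 \sum_i (R_i - \bar R)^2}{K^2 (n^3 - n) - K \sum_j T_j}}
#' where \eqn{R_i} is the rank sum at timepoint i and
#' \eqn{T_j = \sum (t^3 - t)} over tie groups of series j.
#'
#' @param series numeric matrix, K series (rows) x n timepoints (columns).
#' @return W in [0, 1]; \code{NA} if every series is constant (all-tied
#'   ranks carry no concordance information).
#' @examples
#' x <- matrix(rep(1:10, each = 3), nrow = 3, byrow = FALSE)
#' kcc(rbind(1:10, 1:10, 1:10))  # perfect concordance: 1
#' @export
kcc <- function(series) {
  series <- as.matrix(series)
  K <- nrow(series); n <- ncol(series)
  if (K < 2L) stop("kcc needs at least 2 series")
  if (n < 2L) stop("kcc needs at least 2 timepoints")
  ranks <- t(apply(series, 1L, rank))      # midranks
  ties <- apply(series, 1L, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  if (all(ties == n^3 - n)) return(NA_real_)  # every series constant
  R <- colSums(ranks)
  S <- sum((R - K * (n + 1) / 2)^2)
  W <- 12 * S / (K^2 * (n^3 - n) - K * sum(ties))
  # clip floating error only
  if (W < 0 && W > -1e-12) W <- 0
  if (W > 1 && W < 1 + 1e-12) W <- 1
  W
}

# neighbourhood offsets for 6/18/26-connectivity (self excluded)
neighborhoodOffsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1L,
    "18" = rowSums(abs(g)) <= 2L,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Voxel-wise ReHo map
#'
#' For every in-mask voxel, the KCC of its BOLD time course with the
#' in-mask members of its 3x3x3 neighbourhood (26-connectivity by default,
#' so K <= 27).  Partial neighbourhoods at mask edges use only the in-mask
#' series rather than padding; the per-voxel K is recorded for audit.
#' Isolated voxels (K = 1) and voxels whose series are all constant get
#' \code{NA}.
#'
#' @param bold a \linkS4class{BoldSeries}.
#' @param connectivity 6, 18 or 26 neighbours (default 26).
#' @return A \linkS4class{RehoMap}.
#' @export
rehoMap <- function(bold, connectivity = 26L) {
  stopifnot(is(bold, "BoldSeries"))
  mask <- boldMask(bold)
  if (!any(mask)) stop("mask is empty")
  dat <- boldData(bold)
  dims <- dim(dat)[1:3]; n <- dim(dat)[4]
  vox <- which(mask)                        # linear indices
  nv <- length(vox)
  mat <- matrix(aperm(dat, c(4, 1, 2, 3)), nrow = n)[, vox, drop = FALSE]  # n x nv
  ranks <- apply(mat, 2L, rank)             # n x nv midranks
  ties <- apply(mat, 2L, function(x) { t <- table(x); sum(t^3 - t) })
  rowOf <- array(0L, dims); rowOf[vox] <- seq_len(nv)
  off <- neighborhoodOffsets(connectivity)
  idx <- which(mask, arr.ind = TRUE)
  values <- array(NA_real_, dims)
  kArr <- array(0L, dims)
  allTied <- n^3 - n
  for (v in seq_len(nv)) {
    nb <- sweep(off, 2L, idx[v, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    rows <- rowOf[nb]
    rows <- c(v, rows[rows > 0L])
    K <- length(rows)
    kArr[vox[v]] <- K
    if (K < 2L) next                        # isolated voxel: sentinel NA
    tieSum <- sum(ties[rows])
    if (tieSum == K * allTied) next         # all series constant
    R <- rowSums(ranks[, rows, drop = FALSE])
    S <- sum((R - K * (n + 1) / 2)^2)
    W <- 12 * S / (K^2 * allTied - K * tieSum)
    values[vox[v]] <- min(max(W, 0), 1)
  }
  nBad <- sum(is.na(values[mask]))
  if (nBad > 0L)
    message(nBad, " in-mask voxel(s) have undefined ReHo (isolated or constant)")
  RehoMap(values, kArr, mask, voxelSize(bold))
}

#' z-standardize a ReHo map over the mask
#'
#' Subtracts the mean and divides by the standard deviation of all finite
#' in-mask values (population SD, 1/N; recorded in the object).  Produces
#' the zReHo map used for smoothing and regional aggregation.
#'
#' @param reho a \linkS4class{RehoMap}.
#' @return A standardized \linkS4class{RehoMap}.
#' @export
zStandardize <- function(reho) {
  stopifnot(is(reho, "RehoMap"))
  mask <- boldMask(reho)
  v <- rehoValues(reho)
  inm <- v[mask]
  fin <- inm[is.finite(inm)]
  if (length(fin) < 2L) stop("need at least 2 finite in-mask values")
  mu <- mean(fin)
  sdp <- sqrt(mean((fin - mu)^2))
  if (sdp == 0) stop("zero standard deviation over the mask")
  out <- v
  out[mask] <- (v[mask] - mu) / sdp
  RehoMap(out, neighborCounts(reho), mask, voxelSize(reho), standardized = TRUE)
}

gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigmaVox))
  k <- dnorm(-r:r, sd = sigmaVox)
  k / sum(k)
}

# shift a 3D array by d along axis, zero-filling
shift3d <- function(a, d, axis) {
  if (d == 0L) return(a)
  out <- array(0, dim(a))
  n <- dim(a)[axis]
  if (abs(d) >= n) return(out)
  src <- if (d > 0) 1:(n - d) else (1 - d):n
  dst <- if (d > 0) (1 + d):n else 1:(n + d)
  ix <- function(which) switch(axis, list(which, TRUE, TRUE),
                               list(TRUE, which, TRUE), list(TRUE, TRUE, which))
  do.call(`[<-`, c(list(out), ix(dst),
                   list(do.call(`[`, c(list(a), ix(src), list(drop = FALSE))))))
}

convolveAxis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (d in -r:r) out <- out + kernel[d + r + 1L] * shift3d(a, d, axis)
  out
}

#' Gaussian smoothing of a 3D map
#'
#' Separable Gaussian convolution with per-axis sigma =
#' fwhm / (2 sqrt(2 ln 2)) in mm, converted to voxels by the voxel size.
#' fwhm = 0 is the identity.  With a mask, values outside are treated as
#' missing and the result is renormalized by the smoothed mask indicator,
#' which avoids out-of-mask signal dilution at the gray-matter edge.
#'
#' @param map 3D numeric array, or a \linkS4class{RehoMap}.
#' @param fwhm full width at half maximum in mm; scalar or length-3.
#' @param voxelSize voxel edge lengths in mm (taken from the RehoMap when
#'   one is supplied).
#' @param mask optional logical 3D array; NULL smooths the raw array with
#'   zero padding.
#' @return Same type as \code{map}.
#' @export
smoothMap <- function(map, fwhm = 8, voxelSize = c(3, 3, 3), mask = NULL) {
  if (is(map, "RehoMap")) {
    sm <- smoothMap(rehoValues(map), fwhm, voxelSize(map), boldMask(map))
    return(RehoMap(sm, neighborCounts(map), boldMask(map), voxelSize(map),
                   standardized = map@standardized))
  }
  if (any(fwhm < 0)) stop("fwhm must be non-negative")
  fwhm <- rep(fwhm, length.out = 3L)
  if (all(fwhm == 0)) return(map)
  sigmaVox <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize
  a <- map
  if (!is.null(mask)) { a[!mask] <- 0; a[is.na(a)] <- 0 }
  den <- if (is.null(mask)) NULL else (mask + 0)
  for (axis in 1:3) {
    k <- gaussKernel1d(sigmaVox[axis])
    if (length(k) == 1L) next
    a <- convolveAxis(a, k, axis)
    if (!is.null(den)) den <- convolveAxis(den, k, axis)
  }
  if (is.null(mask)) return(a)
  out <- array(NA_real_, dim(map))
  out[mask] <- a[mask] / den[mask]
  out
}

#' Regional mean of a voxel map
#'
#' Arithmetic mean of the map over the in-mask voxels of every atlas label
#' (labels > 0).  Labels with no finite in-mask voxels are omitted and
#' reported in the \code{dropped} attribute.
#'
#' @param map 3D numeric array or \linkS4class{RehoMap}.
#' @param parcellation integer 3D array of region labels, 0 = outside.
#' @param mask optional logical 3D array (defaults to the RehoMap's mask,
#'   or all labelled voxels).
#' @return A \linkS4class{RegionValues}; dropped labels in
#'   \code{attr(, "dropped")}.
#' @export
regionalMean <- function(map, parcellation, mask = NULL) {
  if (is(map, "RehoMap")) {
    if (is.null(mask)) mask <- boldMask(map)
    map <- rehoValues(map)
  }
  if (!identical(dim(map), dim(parcellation)))
    stop("map and parcellation grids differ")
  if (is.null(mask)) mask <- parcellation > 0L
  use <- mask & parcellation > 0L & is.finite(map)
  labs <- parcellation[use]
  vals <- map[use]
  means <- tapply(vals, labs, mean)
  counts <- tapply(vals, labs, length)
  allLabs <- sort(unique(parcellation[parcellation > 0L]))
  dropped <- setdiff(as.character(allLabs), names(means))
  rv <- RegionValues(setNames(as.numeric(means), names(means)),
                     as.integer(counts))
  attr(rv, "dropped") <- dropped
  rv
}

#' Group-level map: voxel-wise mean across subjects
#'
#' @param maps list of \linkS4class{RehoMap}s (or 3D arrays) on a common
#'   grid and mask.
#' @return Same type as the elements of \code{maps}.
#' @export
groupMap <- function(maps) {
  if (length(maps) < 1L) stop("need at least one map")
  if (is(maps[[1]], "RehoMap")) {
    ref <- maps[[1]]
    arrs <- lapply(maps, function(m) {
      if (!identical(dim(rehoValues(m)), dim(rehoValues(ref))))
        stop("map grids differ")
      rehoValues(m)
    })
    avg <- Reduce(`+`, arrs) / length(arrs)
    return(RehoMap(avg, neighborCounts(ref), boldMask(ref), voxelSize(ref),
                   standardized = ref@standardized))
  }
  dims <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), dims)) stop("map grids differ")
  Reduce(`+`, maps) / length(maps)
}
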