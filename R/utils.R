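# Shared helpers: world coordinates and seed substreams.

#' Voxel indices to world (mm) coordinates
#'
#' Identity-scaled affine with the origin at the volume centre, so the
#' x-coordinate is negative in the left half of the grid (MNI-like L/R
#' convention).  Indices are 0-based.
#'
#' @param idx0 matrix (n x 3) of 0-based voxel indices, or a length-3 vector.
#' @param dim spatial grid dimensions (length 3).
#' @param voxelSize voxel edge lengths in mm.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxelToWorld <- function(idx0, dim, voxelSize = c(3, 3, 3)) {
  if (is.null(dim(idx0))) idx0 <- matrix(idx0, nrow = 1)
  centre <- (dim - 1) / 2
  sweep(sweep(idx0, 2, centre, "-"), 2, voxelSize, "*")
}

# 0-based index triples of all TRUE voxels in a 3D logical array
maskIndices <- function(mask) {
  which(mask, arr.ind = TRUE) - 1L
}

# Derive a named substream seed from a master seed; keeps results below
# 2^31 and makes each pipeline stage independently reproducible.
substreamSeed <- function(seed, stream) {
  offsets <- c(bold = 11L, parcellation = 23L, expression = 37L,
               celltype = 53L, gwas = 71L, modules = 89L, demo = 101L)
  off <- offsets[[stream]]
  (as.integer(seed) * 1000L + off) %% 2147483647L
}

# left/right hemisphere of world x-coordinates
hemisphereOf <- function(xmm) ifelse(xmm < 0, "L", "R")
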