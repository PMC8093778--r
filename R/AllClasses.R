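#' @include AllGenerics.R
NULL

# Central data containers.
#
# Spatial conventions used throughout the package: volumes are 3D arrays
# indexed [i, j, k] with 0-based voxel indices in world-coordinate
# computations; world (mm) coordinates use an identity-scaled affine with
# the origin at the volume centre, so x < 0 is the left hemisphere
# (MNI-like).  Voxel size is in mm.

#' BoldSeries: a masked 4D BOLD acquisition
#'
#' Container for a preprocessed resting-state BOLD run: a 4D array
#' (x, y, z, time), a binary gray-matter mask on the same spatial grid, and
#' the voxel size in mm.  Values are arbitrary units; only their ranks over
#' time matter for regional homogeneity.
#'
#' @slot data 4D numeric array, spatial dims x time.
#' @slot mask logical 3D array, same spatial dims as \code{data}.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#'
#' @export
setClass("BoldSeries",
  representation(data = "array", mask = "array", voxelSize = "numeric"))

setValidity("BoldSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (x, y, z, time)")
  if (d[4] < 2L) return("time dimension must be >= 2")
  if (!identical(dim(object@mask), d[1:3]))
    return("mask shape must equal the spatial shape of data")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive mm values")
  TRUE
})

#' Construct a BoldSeries
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param mask logical 3D array; defaults to all-TRUE.
#' @param voxelSize voxel edge lengths in mm (default 3 mm isotropic).
#' @return A \linkS4class{BoldSeries}.
#' @examples
#' b <- BoldSeries(array(rnorm(4 * 4 * 4 * 20), c(4, 4, 4, 20)))
#' dim(boldData(b))
#' @export
BoldSeries <- function(data, mask = NULL, voxelSize = c(3, 3, 3)) {
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  if (!is.logical(mask)) mask <- array(mask > 0, dim(mask))
  new("BoldSeries", data = data, mask = mask, voxelSize = as.numeric(voxelSize))
}

#' @describeIn BoldSeries the 4D data array
#' @param x a BoldSeries
#' @export
setMethod("boldData", "BoldSeries", function(x) x@data)

#' @describeIn BoldSeries the logical 3D mask
#' @export
setMethod("boldMask", "BoldSeries", function(x) x@mask)

#' @describeIn BoldSeries voxel size in mm
#' @export
setMethod("voxelSize", "BoldSeries", function(x) x@voxelSize)

setMethod("show", "BoldSeries", function(object) {
  d <- dim(object@data)
  cat("BoldSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "timepoints\n")
  cat("  in-mask voxels:", sum(object@mask),
      " voxel size:", paste(object@voxelSize, collapse = " x "), "mm\n")
})

#' RehoMap: voxel-wise regional homogeneity
#'
#' Kendall's coefficient of concordance (W, in [0, 1]) of each in-mask
#' voxel's time course with its in-mask neighbours, plus the number of
#' series K actually used per voxel (<= 27 for 26-connectivity).  Voxels
#' where W is undefined (isolated voxel, or all series constant) hold
#' \code{NA}.  After \code{\link{zStandardize}} the values are z-scores and
#' \code{standardized} is TRUE.
#'
#' @slot values numeric 3D array; NA outside the mask and at undefined voxels.
#' @slot k integer 3D array; number of concordant series per voxel.
#' @slot mask logical 3D array.
#' @slot voxelSize numeric length-3, mm.
#' @slot standardized logical scalar.
#'
#' @export
setClass("RehoMap",
  representation(values = "array", k = "array", mask = "array",
                 voxelSize = "numeric", standardized = "logical"))

setValidity("RehoMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask shapes differ")
  if (!identical(dim(object@k), dim(object@mask)))
    return("k and mask shapes differ")
  v <- object@values[object@mask]
  if (!object@standardized) {
    v <- v[is.finite(v)]
    if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
      return("in-mask W values must lie in [0, 1]")
  }
  TRUE
})

RehoMap <- function(values, k, mask, voxelSize, standardized = FALSE) {
  new("RehoMap", values = values, k = k, mask = mask,
      voxelSize = as.numeric(voxelSize), standardized = standardized)
}

#' @describeIn RehoMap the 3D value array (W or zReHo)
#' @param x a RehoMap
#' @export
setMethod("rehoValues", "RehoMap", function(x) x@values)

#' @describeIn RehoMap per-voxel number of series entering the KCC
#' @export
setMethod("neighborCounts", "RehoMap", function(x) x@k)

#' @describeIn RehoMap the logical 3D mask
#' @export
setMethod("boldMask", "RehoMap", function(x) x@mask)

#' @describeIn RehoMap voxel size in mm
#' @export
setMethod("voxelSize", "RehoMap", function(x) x@voxelSize)

setMethod("show", "RehoMap", function(object) {
  v <- object@values[object@mask]
  cat("RehoMap (", if (object@standardized) "zReHo" else "W", "): ",
      paste(dim(object@values), collapse = " x "), " grid, ",
      sum(object@mask), " in-mask voxels\n", sep = "")
  cat("  value range:", paste(signif(range(v, na.rm = TRUE), 4),
      collapse = " .. "), "\n")
})

#' RegionValues: one scalar per atlas region
#'
#' A per-region summary (regional mean zReHo, or any per-region phenotype)
#' keyed by parcel label, together with the number of voxels averaged.
#'
#' @slot values named numeric vector; names are parcel labels.
#' @slot nVoxels named integer vector, same names; voxels per region.
#'
#' @export
setClass("RegionValues",
  representation(values = "numeric", nVoxels = "integer"))

setValidity("RegionValues", function(object) {
  if (is.null(names(object@values))) return("values must be named by region")
  if (!identical(names(object@values), names(object@nVoxels)))
    return("values and nVoxels must share names")
  if (any(object@nVoxels < 1L)) return("region voxel counts must be >= 1")
  TRUE
})

#' Construct RegionValues
#' @param values named numeric vector (names = region labels).
#' @param nVoxels per-region voxel counts; defaults to 1 each.
#' @return A \linkS4class{RegionValues}.
#' @export
RegionValues <- function(values, nVoxels = NULL) {
  if (is.null(nVoxels)) nVoxels <- setNames(rep(1L, length(values)), names(values))
  new("RegionValues", values = values,
      nVoxels = setNames(as.integer(nVoxels), names(values)))
}

#' @describeIn RegionValues named vector of per-region values
#' @param x a RegionValues
#' @export
setMethod("regionValues", "RegionValues", function(x) x@values)

#' @describeIn RegionValues named vector of per-region voxel counts
#' @export
setMethod("regionCounts", "RegionValues", function(x) x@nVoxels)

setMethod("show", "RegionValues", function(object) {
  cat("RegionValues:", length(object@values), "regions; range",
      paste(signif(range(object@values), 4), collapse = " .. "), "\n")
})

#' ModuleAssignment: gene-to-module labels
#'
#' Result of coexpression module detection.  Genes not placed in any proper
#' module carry the reserved background label (WGCNA's "grey" convention)
#' and are excluded from downstream module testing.
#'
#' @slot labels named character vector, gene -> module label.
#' @slot background the reserved background label (default "grey").
#'
#' @export
setClass("ModuleAssignment",
  representation(labels = "character", background = "character"))

setValidity("ModuleAssignment", function(object) {
  if (is.null(names(object@labels))) return("labels must be named by gene")
  if (length(object@background) != 1L) return("background must be length 1")
  TRUE
})

#' Construct a ModuleAssignment
#' @param labels named character vector, gene -> module label.
#' @param background the reserved background label (default "grey").
#' @return A \linkS4class{ModuleAssignment}.
#' @export
ModuleAssignment <- function(labels, background = "grey") {
  new("ModuleAssignment", labels = labels, background = background)
}

#' @describeIn ModuleAssignment named gene -> module vector
#' @param x a ModuleAssignment
#' @export
setMethod("moduleLabels", "ModuleAssignment", function(x) x@labels)

#' @describeIn ModuleAssignment the reserved background label
#' @export
setMethod("backgroundLabel", "ModuleAssignment", function(x) x@background)

#' @describeIn ModuleAssignment genes of one module
#' @param module module label
#' @export
setMethod("moduleGenes", "ModuleAssignment", function(x, module) {
  names(x@labels)[x@labels == module]
})

#' @describeIn ModuleAssignment module sizes, background excluded
#' @export
setMethod("moduleSizes", "ModuleAssignment", function(x) {
  tab <- table(x@labels)
  tab <- tab[names(tab) != x@background]
  sort(setNames(as.integer(tab), names(tab)), decreasing = TRUE)
})

setMethod("show", "ModuleAssignment", function(object) {
  sz <- moduleSizes(object)
  cat("ModuleAssignment:", length(object@labels), "genes,",
      length(sz), "modules (+",
      sum(object@labels == object@background), "background genes)\n")
  if (length(sz)) print(sz)
})
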