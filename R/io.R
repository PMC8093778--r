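# Readers and writers for the pipeline's on-disk formats: NIfTI volumes,
# TSV tables, GWAS summaries, BED-like gene locations, GMT gene sets and
# the planted-truth JSON.

#' Write a 3D/4D volume to NIfTI
#'
#' @param vol numeric array (3D or 4D).
#' @param path output .nii or .nii.gz path.
#' @param voxelSize voxel edge lengths in mm (stored in pixdim).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path, voxelSize = c(3, 3, 3)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- if (length(dim(vol)) == 4L) c(voxelSize, 1)
                         else voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path .nii or .nii.gz path.
#' @return list(data = array, voxelSize = mm triple).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  list(data = unclass(as.array(img)), voxelSize = vs)
}

#' @rdname tsvIO
#' @export
writeTsv <- function(x, path, rowNamesColumn = NULL) {
  if (!is.null(rowNamesColumn)) {
    x <- data.frame(setNames(list(rownames(x)), rowNamesColumn),
                    as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' TSV I/O
#'
#' Plain tab-separated tables with a header row.  \code{writeTsv} can
#' spill row names into a leading column; \code{readTsvMatrix} reads such
#' a table back into a named numeric matrix.
#'
#' @param x data.frame or matrix.
#' @param path file path.
#' @param rowNamesColumn name for the row-name column (NULL = none).
#' @name tsvIO
#' @export
readTsvMatrix <- function(path, rowNamesColumn = 1L) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[rowNamesColumn]]
  m <- as.matrix(df[, -rowNamesColumn, drop = FALSE])
  rownames(m) <- rn
  m
}

#' Read/write GWAS summary statistics
#'
#' Whitespace-delimited with header columns SNP, CHR, BP, P, N.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
readGwasSummary <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "P", "N")
  if (!all(need %in% names(df)))
    stop("GWAS summary must have columns ", paste(need, collapse = ", "))
  if (any(df$P <= 0 | df$P > 1)) stop("p-values must lie in (0, 1]")
  if (any(df$BP <= 0)) stop("positions must be positive")
  df[, need]
}

#' @rdname readGwasSummary
#' @param summary data.frame (SNP, CHR, BP, P, N).
#' @export
writeGwasSummary <- function(summary, path) {
  write.table(summary, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write BED-like gene locations
#'
#' Four tab-separated columns without header: chrom, start, end, gene
#' (0-based half-open intervals).
#'
#' @param path file path.
#' @return data.frame chrom, start, end, gene.
#' @export
readGeneLocations <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "gene"))
  if (any(df$end <= df$start)) stop("gene intervals must have end > start")
  df
}

#' @rdname readGeneLocations
#' @param geneLoc data.frame chrom, start, end, gene.
#' @export
writeGeneLocations <- function(geneLoc, path) {
  write.table(geneLoc[, c("chrom", "start", "end", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write GMT gene-set collections
#'
#' Reading delegates to \code{fgsea::gmtPathways}; writing emits the
#' standard name, description, genes... tab layout.
#'
#' @param path file path.
#' @return named list, term -> character vector of genes.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param sets named list of gene vectors.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write/read a planted-truth JSON file
#'
#' @param truth list of planted ground-truth fields.
#' @param path file path.
#' @export
writeTruth <- function(truth, path) {
  # matrices are stored with dimnames so they round-trip
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
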