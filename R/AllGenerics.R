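NULL

#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))

#' @export
setGeneric("boldMask", function(x) standardGeneric("boldMask"))

#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setGeneric("rehoValues", function(x) standardGeneric("rehoValues"))

#' @export
setGeneric("neighborCounts", function(x) standardGeneric("neighborCounts"))

#' @export
setGeneric("regionValues", function(x) standardGeneric("regionValues"))

#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @export
setGeneric("moduleGenes", function(x, module) standardGeneric("moduleGenes"))

#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @export
setGeneric("backgroundLabel", function(x) standardGeneric("backgroundLabel"))
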