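#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @export
setGeneric("chainLengths", function(x) standardGeneric("chainLengths"))

#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))

#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' @export
setGeneric("confidences", function(x) standardGeneric("confidences"))

#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))

#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))

#' @export
setGeneric("insertEmissions", function(x) standardGeneric("insertEmissions"))

#' @export
setGeneric("transitionTable", function(x) standardGeneric("transitionTable"))

#' @export
setGeneric("bgFrequencies", function(x) standardGeneric("bgFrequencies"))

#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))
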