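#' Construct a ResidueProfile
#'
#' @param chainId chain identifier.
#' @param P L x 20 probability matrix, columns in fixed alphabetical
#'   one-letter amino-acid order (A, C, D, ..., Y).
#' @param confidence length-L confidence vector in [0, 1].
#' @return a \linkS4class{ResidueProfile}.
#' @export
ResidueProfile <- function(chainId, P, confidence) {
  P <- as.matrix(P)
  colnames(P) <- AA_ALPHABET
  new("ResidueProfile", chainId = as.character(chainId), P = P,
      confidence = as.numeric(confidence))
}

#' @describeIn ResidueProfile number of residues L.
#' @param x a ResidueProfile.
#' @export
setMethod("profileLength", "ResidueProfile", function(x) nrow(x@P))

#' @describeIn ResidueProfile the L x 20 probability matrix.
#' @export
setMethod("probMatrix", "ResidueProfile", function(x) x@P)

#' @describeIn ResidueProfile the per-residue confidence vector.
#' @export
setMethod("confidences", "ResidueProfile", function(x) x@confidence)

#' @describeIn ResidueProfile the chain identifier.
#' @export
setMethod("chainId", "ResidueProfile", function(x) x@chainId)

setMethod("show", "ResidueProfile", function(object) {
  cat(sprintf("ResidueProfile '%s': %d residues, mean confidence %.3f\n",
              object@chainId, nrow(object@P), mean(object@confidence)))
})

#' Construct a ProfileHMM
#'
#' @param name profile name.
#' @param matchEmit,insertEmit L x 20 emission probability matrices.
#' @param transitions L x 7 matrix with columns
#'   \code{MM, MI, MD, IM, II, DM, DD}.
#' @param background length-20 background distribution (default uniform).
#' @return a \linkS4class{ProfileHMM}.
#' @export
ProfileHMM <- function(name, matchEmit, insertEmit, transitions,
                       background = rep(1 / 20, 20)) {
  matchEmit <- as.matrix(matchEmit); insertEmit <- as.matrix(insertEmit)
  transitions <- as.matrix(transitions)
  colnames(matchEmit) <- AA_ALPHABET
  colnames(insertEmit) <- AA_ALPHABET
  colnames(transitions) <- TRANS_COLS
  new("ProfileHMM", name = as.character(name), matchEmit = matchEmit,
      insertEmit = insertEmit, transitions = transitions,
      background = as.numeric(background))
}

#' @describeIn ProfileHMM number of match nodes L.
#' @param x a ProfileHMM.
#' @export
setMethod("profileLength", "ProfileHMM", function(x) nrow(x@matchEmit))

#' @describeIn ProfileHMM L x 20 match emission probabilities.
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmit)

#' @describeIn ProfileHMM L x 20 insert emission probabilities.
#' @export
setMethod("insertEmissions", "ProfileHMM", function(x) x@insertEmit)

#' @describeIn ProfileHMM L x 7 transition probabilities.
#' @export
setMethod("transitionTable", "ProfileHMM", function(x) x@transitions)

#' @describeIn ProfileHMM length-20 background distribution.
#' @export
setMethod("bgFrequencies", "ProfileHMM", function(x) x@background)

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM '%s': %d nodes\n", object@name,
              nrow(object@matchEmit)))
  cat(sprintf("  mean M->M %.3f, consensus %s%s\n",
              mean(object@transitions[, "MM"]),
              paste(AA_ALPHABET[apply(head(object@matchEmit, 20), 1,
                                      which.max)], collapse = ""),
              if (nrow(object@matchEmit) > 20) "..." else ""))
})

#' Construct a DensityMap
#'
#' @param grid 3-D numeric array.
#' @param voxelSize Angstrom per voxel, length 1 (isotropic) or 3.
#' @param origin Angstrom coordinates of the first voxel centre.
#' @return a \linkS4class{DensityMap}.
#' @export
DensityMap <- function(grid, voxelSize = 1, origin = c(0, 0, 0)) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  new("DensityMap", grid = grid, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' @describeIn DensityMap Angstrom per voxel along each axis.
#' @param x a DensityMap.
#' @export
setMethod("voxelSize", "DensityMap", function(x) x@voxelSize)

#' @describeIn DensityMap Angstrom position of the first voxel centre.
#' @export
setMethod("mapOrigin", "DensityMap", function(x) x@origin)

#' @describeIn DensityMap grid dimensions.
#' @export
setMethod("dim", "DensityMap", function(x) dim(x@grid))

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf(
    "DensityMap: %d x %d x %d voxels, %.3g/%.3g/%.3g A/voxel, origin (%g, %g, %g)\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3], object@origin[1], object@origin[2],
    object@origin[3]))
})
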