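#' AtomicModel: chains of residues with coordinates and per-residue scores
#'
#' Container for a (partial) atomic model as built into a cryo-EM map:
#' ordered chains of protein or nucleotide residues, each residue holding
#' named atom coordinates in Angstrom, an optional sequence position, and an
#' optional confidence score in [0, 1]. The score round-trips through the
#' B-factor column of coordinate files.
#'
#' The model is stored as a flat atom table with one row per atom and
#' columns \code{chain}, \code{res_idx} (1-based order within the chain),
#' \code{res_name} (three-letter amino-acid name, one-letter nucleotide
#' name, or \code{UNK}), \code{seq_pos} (integer or NA), \code{atom},
#' \code{x}, \code{y}, \code{z}, \code{score} (in [0,1] or NA).
#'
#' @slot atoms data.frame as described above.
#' @export
setClass("AtomicModel", representation(atoms = "data.frame"))

setValidity("AtomicModel", function(object) {
  a <- object@atoms
  need <- c("chain", "res_idx", "res_name", "seq_pos", "atom",
            "x", "y", "z", "score")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return(TRUE)
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  sc <- a$score[!is.na(a$score)]
  if (length(sc) && (any(sc < 0) || any(sc > 1)))
    return("scores must lie in [0, 1]")
  if (any(a$res_idx < 1L)) return("res_idx must be >= 1")
  TRUE
})

#' ResidueProfile: per-residue amino-acid probabilities with confidences
#'
#' One chain's predicted amino-acid probability matrix (L x 20, columns in
#' fixed alphabetical one-letter order) together with a per-residue
#' confidence vector in [0, 1]. Rows sum to 1.
#'
#' @slot chainId single string naming the chain.
#' @slot P numeric L x 20 matrix of probabilities.
#' @slot confidence numeric length-L vector in [0, 1].
#' @export
setClass("ResidueProfile",
         representation(chainId = "character", P = "matrix",
                        confidence = "numeric"))

setValidity("ResidueProfile", function(object) {
  P <- object@P
  if (ncol(P) != 20L) return("P must have 20 columns")
  if (nrow(P) == 0L) return("profile must have at least one residue")
  if (length(object@confidence) != nrow(P))
    return("length(confidence) must equal nrow(P)")
  if (any(P < 0)) return("probabilities must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-6))
    return("each row of P must sum to 1 within 1e-6")
  cc <- object@confidence
  if (any(cc < 0 | cc > 1)) return("confidences must lie in [0, 1]")
  if (length(object@chainId) != 1L) return("chainId must be a single string")
  TRUE
})

#' ProfileHMM: the searchable profile hidden Markov model
#'
#' Match and insert emission probabilities plus the 7-way transition table
#' per node, in column order M->M, M->I, M->D, I->M, I->I, D->M, D->D
#' (I->D and D->I are identically zero and not stored).
#'
#' @slot name profile name (written to the HMMER3 NAME line).
#' @slot matchEmit L x 20 match-emission probabilities.
#' @slot insertEmit L x 20 insert-emission probabilities.
#' @slot transitions L x 7 transition probabilities, columns
#'   \code{MM, MI, MD, IM, II, DM, DD}.
#' @slot background length-20 background amino-acid distribution.
#' @export
setClass("ProfileHMM",
         representation(name = "character", matchEmit = "matrix",
                        insertEmit = "matrix", transitions = "matrix",
                        background = "numeric"))

TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

setValidity("ProfileHMM", function(object) {
  L <- nrow(object@matchEmit)
  if (L == 0L) return("profile must have at least one node")
  if (ncol(object@matchEmit) != 20L || ncol(object@insertEmit) != 20L)
    return("emission matrices must have 20 columns")
  if (nrow(object@insertEmit) != L) return("insertEmit must have L rows")
  tr <- object@transitions
  if (!identical(dim(tr), c(L, 7L)) && !identical(dim(tr), as.integer(c(L, 7))))
    return("transitions must be L x 7")
  if (any(object@matchEmit < 0) || any(object@insertEmit < 0) || any(tr < 0))
    return("probabilities must be non-negative")
  if (any(abs(rowSums(object@matchEmit) - 1) > 1e-9))
    return("match emission rows must sum to 1 within 1e-9")
  if (any(abs(rowSums(object@insertEmit) - 1) > 1e-9))
    return("insert emission rows must sum to 1 within 1e-9")
  if (any(abs(tr[, 1] + tr[, 2] + tr[, 3] - 1) > 1e-9))
    return("M->M + M->I + M->D must sum to 1 within 1e-9")
  if (any(abs(tr[, 4] + tr[, 5] - 1) > 1e-9))
    return("I->M + I->I must sum to 1 within 1e-9")
  if (any(abs(tr[, 6] + tr[, 7] - 1) > 1e-9))
    return("D->M + D->D must sum to 1 within 1e-9")
  if (length(object@background) != 20L)
    return("background must have length 20")
  if (abs(sum(object@background) - 1) > 1e-9)
    return("background must sum to 1")
  TRUE
})

#' DensityMap: a 3-D density grid with voxel size and origin
#'
#' @slot grid 3-D numeric array of density values.
#' @slot voxelSize numeric length-3, Angstrom per voxel along each axis.
#' @slot origin numeric length-3, Angstrom position of grid index (1,1,1).
#' @export
setClass("DensityMap",
         representation(grid = "array", voxelSize = "numeric",
                        origin = "numeric"))

setValidity("DensityMap", function(object) {
  d <- dim(object@grid)
  if (length(d) != 3L) return("grid must be a 3-D array")
  if (any(d < 2L)) return("grid dimensions must be >= 2 on each axis")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})
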