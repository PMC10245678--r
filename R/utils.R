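#' @useDynLib densid, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats optim runif rnorm setNames cor fft sd rbinom
#' @importFrom utils head tail read.table write.table
NULL

## Fixed alphabetical one-letter amino-acid order; matches the HMMER3
## "amino" alphabet so emission columns map 1:1.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- setNames(names(AA_THREE), AA_THREE)

## Nucleotide residue names as deposited for RNA; P is the anchor atom.
NT_NAMES <- c("A", "C", "G", "U")

is_protein_resname <- function(x) x %in% AA_THREE
is_nucleotide_resname <- function(x) x %in% NT_NAMES

#' Convert residue names to one-letter identities
#'
#' Three-letter amino-acid names map to their one-letter code; nucleotide
#' names and \code{UNK} pass through unchanged.
#'
#' @param resname character vector of residue names.
#' @return character vector of identities.
#' @keywords internal
resname_to_identity <- function(resname) {
  out <- resname
  hit <- resname %in% names(AA_ONE)
  out[hit] <- AA_ONE[resname[hit]]
  out
}

identity_to_resname <- function(identity) {
  out <- identity
  hit <- identity %in% names(AA_THREE)
  out[hit] <- AA_THREE[identity[hit]]
  out
}

## Anchor atom for a residue name: CA for protein, P for nucleotide.
anchor_atom_for <- function(resname) {
  ifelse(is_nucleotide_resname(resname), "P", "CA")
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

## Seeded evaluation that leaves the caller's RNG stream untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
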