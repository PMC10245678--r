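#' Construct an AtomicModel from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{res_idx},
#'   \code{res_name}, \code{seq_pos}, \code{atom}, \code{x}, \code{y},
#'   \code{z}, \code{score}. \code{seq_pos} and \code{score} may be NA.
#' @return an \linkS4class{AtomicModel}.
#' @examples
#' a <- data.frame(chain = "A", res_idx = 1L, res_name = "ALA",
#'                 seq_pos = NA_integer_, atom = "CA",
#'                 x = 0, y = 0, z = 0, score = 0.8)
#' AtomicModel(a)
#' @export
AtomicModel <- function(atoms) {
  atoms$chain <- as.character(atoms$chain)
  atoms$res_idx <- as.integer(atoms$res_idx)
  atoms$res_name <- as.character(atoms$res_name)
  atoms$seq_pos <- as.integer(atoms$seq_pos)
  atoms$atom <- as.character(atoms$atom)
  atoms$score <- as.numeric(atoms$score)
  rownames(atoms) <- NULL
  new("AtomicModel", atoms = atoms)
}

#' @describeIn AtomicModel chain identifiers in model order.
#' @param x an AtomicModel.
#' @export
setMethod("chainIds", "AtomicModel", function(x) unique(x@atoms$chain))

#' @describeIn AtomicModel residues per chain, named by chain id.
#' @export
setMethod("chainLengths", "AtomicModel", function(x) {
  rt <- residueTable(x)
  tab <- table(factor(rt$chain, levels = unique(rt$chain)))
  setNames(as.integer(tab), names(tab))
})

#' @describeIn AtomicModel total number of residues.
#' @export
setMethod("nResidues", "AtomicModel", function(x) sum(chainLengths(x)))

#' @describeIn AtomicModel the underlying one-row-per-atom table.
#' @export
setMethod("atomTable", "AtomicModel", function(x) x@atoms)

#' @describeIn AtomicModel one row per residue with identity, seq_pos,
#'   score, and the anchor-atom (CA for protein, P for nucleotide)
#'   coordinates (NA when the anchor atom is missing).
#' @export
setMethod("residueTable", "AtomicModel", function(x) {
  a <- x@atoms
  key <- paste(a$chain, a$res_idx, sep = "\r")
  first <- !duplicated(key)
  rt <- data.frame(chain = a$chain[first], res_idx = a$res_idx[first],
                   res_name = a$res_name[first], seq_pos = a$seq_pos[first],
                   score = a$score[first], stringsAsFactors = FALSE)
  rt$anchor <- anchor_atom_for(rt$res_name)
  idx <- match(paste(rt$chain, rt$res_idx, rt$anchor, sep = "\r"),
               paste(a$chain, a$res_idx, a$atom, sep = "\r"))
  rt$ax <- a$x[idx]; rt$ay <- a$y[idx]; rt$az <- a$z[idx]
  rownames(rt) <- NULL
  rt
})

setMethod("show", "AtomicModel", function(object) {
  cl <- chainLengths(object)
  cat(sprintf("AtomicModel: %d chain(s), %d residue(s), %d atom(s)\n",
              length(cl), sum(cl), nrow(object@atoms)))
  if (length(cl)) {
    shown <- head(cl, 8)
    cat("  chains:", paste(sprintf("%s(%d)", names(shown), shown),
                           collapse = " "),
        if (length(cl) > 8) "..." else "", "\n")
  }
})

#' One-letter identity sequence of a chain
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param chain chain id.
#' @return the chain's residue identities as a single string (one-letter
#'   amino-acid codes; nucleotide and UNK names pass through).
#' @export
chainSequence <- function(model, chain) {
  rt <- residueTable(model)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rt) == 0L) stopf("no chain '%s' in model", chain)
  paste(resname_to_identity(rt$res_name), collapse = "")
}

chain_sequence <- chainSequence

## Replace the identity / seq_pos / score of residues of one chain.
## idx is res_idx within the chain; vectors recycled to length(idx).
set_residue_fields <- function(model, chain, idx, res_name = NULL,
                               seq_pos = NULL, score = NULL) {
  a <- model@atoms
  for (k in seq_along(idx)) {
    sel <- a$chain == chain & a$res_idx == idx[k]
    if (!is.null(res_name)) a$res_name[sel] <- res_name[k]
    if (!is.null(seq_pos)) a$seq_pos[sel] <- seq_pos[k]
    if (!is.null(score)) a$score[sel] <- score[k]
  }
  AtomicModel(a)
}
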