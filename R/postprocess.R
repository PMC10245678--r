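#' ResidueGraph: k-nearest-neighbour graph over residues
#'
#' @slot nodes data.frame, one row per residue with an anchor atom
#'   (columns as in \code{\link{residueTable}}).
#' @slot neighbors list of integer vectors: per node, its neighbour row
#'   indices sorted by ascending anchor-atom distance.
#' @slot k the requested neighbour count.
#' @export
setClass("ResidueGraph",
         representation(nodes = "data.frame", neighbors = "list",
                        k = "integer"))

setMethod("show", "ResidueGraph", function(object) {
  cat(sprintf("ResidueGraph: %d nodes, k = %d, out-degrees %s\n",
              nrow(object@nodes), object@k,
              paste(range(lengths(object@neighbors)), collapse = "-")))
})

#' Build the k-nearest-neighbour residue graph
#'
#' Each residue with an anchor atom (CA for protein, P for nucleotide) is
#' a node; edges go to its k nearest neighbours by anchor-atom Euclidean
#' distance (default 20). Distance ties are broken by lower residue index.
#' Systems with n <= k residues get n - 1 neighbours per node.
#'
#' @param model an \linkS4class{AtomicModel} with >= 2 anchored residues.
#' @param k neighbour count, default 20.
#' @return a \linkS4class{ResidueGraph}.
#' @export
buildResidueGraph <- function(model, k = 20L) {
  rt <- residueTable(model)
  rt <- rt[!is.na(rt$ax), , drop = FALSE]
  n <- nrow(rt)
  if (n < 2L) stopf("need at least 2 residues with anchor atoms, got %d", n)
  rownames(rt) <- NULL
  xyz <- as.matrix(rt[, c("ax", "ay", "az")])
  dmat <- as.matrix(stats::dist(xyz))
  kk <- min(as.integer(k), n - 1L)
  nb <- lapply(seq_len(n), function(i) {
    ord <- order(dmat[i, ], seq_len(n))  # ties: lower residue index first
    ord <- ord[ord != i]
    ord[seq_len(kk)]
  })
  new("ResidueGraph", nodes = rt, neighbors = nb, k = as.integer(k))
}

#' Assign sequences to chains and mutate matched residues
#'
#' Residues whose profile node appears as a match (M) state in the chain's
#' best Viterbi alignment are mutated to the target sequence's amino acid
#' at the aligned position, and get that position as \code{seq_pos}.
#' Residues not matched (insert/delete/outside the alignment) keep their
#' argmax-probability identity from the profile (or become UNK when
#' \code{unmatchedAsUnk}), with \code{seq_pos} unset. Chains without a hit
#' are left unchanged.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param profiles list of \linkS4class{ResidueProfile} (chain ids must
#'   match model chains).
#' @param hits named list: chain id -> hit data.frame from
#'   \code{\link{searchDb}} (the top row is used), or NULL/empty for no hit.
#' @param db the \code{AAStringSet} the hits refer to.
#' @param unmatchedAsUnk mutate unmatched residues to UNK instead of their
#'   argmax identity.
#' @return a list with \code{model} (mutated \linkS4class{AtomicModel}) and
#'   \code{assignment}: \code{chains} (data.frame chain, target_id) and
#'   \code{residues} (data.frame chain, res_idx, seq_pos).
#' @export
assignAndMutate <- function(model, profiles, hits, db,
                            unmatchedAsUnk = FALSE) {
  prof_by_chain <- setNames(profiles,
                            vapply(profiles, chainId, character(1)))
  cl <- chainLengths(model)
  chain_target <- data.frame(chain = character(), target_id = character(),
                             stringsAsFactors = FALSE)
  res_rows <- list()
  out <- model
  for (ch in chainIds(model)) {
    L <- cl[[ch]]
    rp <- prof_by_chain[[ch]]
    h <- hits[[ch]]
    ## start from profile argmax identities where a profile exists
    new_ident <- NULL
    if (!is.null(rp)) {
      if (profileLength(rp) != L)
        stopf("profile for chain %s has %d residues, chain has %d",
              ch, profileLength(rp), L)
      new_ident <- AA_THREE[AA_ALPHABET[apply(probMatrix(rp), 1, which.max)]]
    }
    seq_pos <- rep(NA_integer_, L)
    if (!is.null(h) && nrow(h) > 0L) {
      ali <- h$alignment[[1]]
      tgt <- as.character(db[[h$target_id[1]]])
      m <- ali[ali$state == "M", , drop = FALSE]
      if (any(m$node > L))
        stopf("alignment for chain %s references node %d beyond chain length %d",
              ch, max(m$node), L)
      if (is.null(new_ident)) new_ident <- rep(NA_character_, L)
      new_ident[m$node] <-
        identity_to_resname(substring(tgt, m$pos, m$pos))
      seq_pos[m$node] <- m$pos
      chain_target <- rbind(chain_target,
                            data.frame(chain = ch,
                                       target_id = h$target_id[1],
                                       stringsAsFactors = FALSE))
      if (unmatchedAsUnk) new_ident[is.na(seq_pos)] <- "UNK"
      keep <- !is.na(new_ident)
      out <- set_residue_fields(out, ch, which(keep),
                                res_name = new_ident[keep])
      out <- set_residue_fields(out, ch, seq_len(L), seq_pos = seq_pos)
    }
    res_rows[[ch]] <- data.frame(chain = ch, res_idx = seq_len(L),
                                 seq_pos = seq_pos,
                                 stringsAsFactors = FALSE)
  }
  residues <- do.call(rbind, res_rows)
  rownames(residues) <- NULL
  list(model = out,
       assignment = list(chains = chain_target, residues = residues))
}

#' Connect chains assigned to the same target sequence
#'
#' Two chains are merged when (a) they are assigned to the same target,
#' (b) their matched sequence ranges are disjoint and in order with a
#' residue gap g >= 0, and (c) the distance between the upstream chain's
#' last anchor atom and the downstream chain's first anchor atom is at most
#' \code{dmax * (g + 1)}. Merging is applied greedily by ascending gap,
#' then ascending distance, until no pair qualifies. The default
#' \code{dmax} of 3.8 A is the C-alpha virtual bond length, so a gap of g
#' unbuilt residues may span up to (g + 1) peptide bonds.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param assignment the assignment list from \code{\link{assignAndMutate}}.
#' @param dmax maximum bridging distance per gapped residue, Angstrom.
#' @return an \linkS4class{AtomicModel} with qualifying chains merged
#'   (upstream chain id kept, residues renumbered).
#' @export
connectChains <- function(model, assignment, dmax = 3.8) {
  targets <- assignment$chains
  resmap <- assignment$residues
  if (nrow(targets) == 0L) return(model)
  atoms <- model@atoms
  chain_info <- function() {
    rt <- residueTable(AtomicModel(atoms))
    lapply(split(rt, factor(rt$chain, levels = unique(rt$chain))),
           function(g) {
      mp <- resmap$seq_pos[match(paste(g$chain, g$res_idx),
                                 paste(resmap$chain, resmap$res_idx))]
      list(chain = g$chain[1], n = nrow(g),
           target = targets$target_id[match(g$chain[1], targets$chain)],
           first_pos = if (all(is.na(mp))) NA else min(mp, na.rm = TRUE),
           last_pos = if (all(is.na(mp))) NA else max(mp, na.rm = TRUE),
           first_xyz = unlist(g[1, c("ax", "ay", "az")]),
           last_xyz = unlist(g[nrow(g), c("ax", "ay", "az")]))
    })
  }
  repeat {
    info <- chain_info()
    cand <- NULL
    ids <- names(info)
    for (a in ids) for (b in ids) {
      if (a == b) next
      ia <- info[[a]]; ib <- info[[b]]
      if (is.na(ia$target) || is.na(ib$target) || ia$target != ib$target)
        next
      if (is.na(ia$last_pos) || is.na(ib$first_pos)) next
      g <- ib$first_pos - ia$last_pos - 1L
      if (g < 0L) next
      if (any(is.na(ia$last_xyz)) || any(is.na(ib$first_xyz))) next
      d <- sqrt(sum((ia$last_xyz - ib$first_xyz)^2))
      if (d > dmax * (g + 1)) next
      cand <- rbind(cand, data.frame(up = a, down = b, gap = g, dist = d,
                                     stringsAsFactors = FALSE))
    }
    if (is.null(cand)) break
    cand <- cand[order(cand$gap, cand$dist), , drop = FALSE]
    up <- cand$up[1]; down <- cand$down[1]
    ## renumber the downstream residues after the upstream ones
    n_up <- info[[up]]$n
    sel <- atoms$chain == down
    old_idx <- atoms$res_idx[sel]
    atoms$res_idx[sel] <- old_idx + n_up
    atoms$chain[sel] <- up
    rsel <- resmap$chain == down
    resmap$res_idx[rsel] <- resmap$res_idx[rsel] + n_up
    resmap$chain[rsel] <- up
    targets <- targets[targets$chain != down, , drop = FALSE]
    ## keep atom rows ordered by chain then residue
    atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                         atoms$res_idx), , drop = FALSE]
  }
  AtomicModel(atoms)
}

#' Prune chains shorter than a minimum length
#'
#' Chains with fewer than \code{minLen} residues (default 4) are removed;
#' all others are untouched. Intended to run after
#' \code{\link{connectChains}} so that connectable short fragments are not
#' lost prematurely.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param minLen minimum chain length to keep.
#' @return an \linkS4class{AtomicModel}; an empty model is a valid result.
#' @export
pruneChains <- function(model, minLen = 4L) {
  cl <- chainLengths(model)
  keep <- names(cl)[cl >= minLen]
  AtomicModel(model@atoms[model@atoms$chain %in% keep, , drop = FALSE])
}
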