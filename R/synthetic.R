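#' Amino-acid background compositions
#'
#' @param which \code{"uniform"} (1/20 each) or \code{"swissprot"}
#'   (average Swiss-Prot composition).
#' @return named length-20 probability vector in alphabetical order.
#' @export
aaComposition <- function(which = c("uniform", "swissprot")) {
  which <- match.arg(which)
  if (which == "uniform") return(setNames(rep(1 / 20, 20), AA_ALPHABET))
  ## UniProtKB/Swiss-Prot average amino-acid frequencies (release-level
  ## statistics, renormalized over the 20 standard residues)
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
}

random_aa_seq <- function(len, composition = aaComposition("uniform")) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = composition),
        collapse = "")
}

#' Generate an idealized multi-chain test structure
#'
#' Each chain is an ideal alpha-helical backbone (rise 1.5 A per residue,
#' 100 degree twist, helix radius 2.3 A, giving the canonical ~3.8 A
#' consecutive C-alpha spacing) with N/CA/C/O atoms at idealized offsets.
#' Chains are placed on a lattice with 14 A spacing to avoid clashes.
#' Residue identities are drawn from the composition. Deterministic given
#' the seed.
#'
#' @param chainLengths integer vector of residues per chain.
#' @param seed RNG seed (used for identities).
#' @param sequences optional character vector of explicit chain sequences
#'   overriding random identities (lengths must match).
#' @return an \linkS4class{AtomicModel} with chains "A", "B", ...
#' @export
genStructure <- function(chainLengths, seed = 1L, sequences = NULL) {
  if (any(chainLengths < 1L)) stopf("chain lengths must be >= 1")
  nch <- length(chainLengths)
  ids <- make.unique(rep(LETTERS, length.out = nch), sep = "")
  if (!is.null(sequences)) {
    if (length(sequences) != nch ||
        any(nchar(sequences) != chainLengths))
      stopf("sequences must match chainLengths")
  }
  with_seed(seed, {
    chains <- lapply(seq_len(nch), function(ci) {
      L <- chainLengths[ci]
      seqc <- if (is.null(sequences)) random_aa_seq(L) else sequences[ci]
      aa <- strsplit(seqc, "")[[1]]
      i <- seq_len(L)
      theta <- (i - 1) * 100 * pi / 180
      cx <- 2.3 * cos(theta); cy <- 2.3 * sin(theta); cz <- (i - 1) * 1.5
      ## chain lattice offset: 14 A grid in x/y
      ox <- ((ci - 1) %% 5) * 14; oy <- ((ci - 1) %/% 5) * 14
      ## idealized backbone offsets in the local helix frame
      ux <- cos(theta); uy <- sin(theta)           # radial
      tx <- -sin(theta); ty <- cos(theta)          # tangential
      per_res <- function(atom, dx, dy, dz) {
        data.frame(chain = ids[ci], res_idx = i,
                   res_name = AA_THREE[aa], seq_pos = NA_integer_,
                   atom = atom, x = ox + cx + dx, y = oy + cy + dy,
                   z = cz + dz, score = NA_real_,
                   stringsAsFactors = FALSE)
      }
      at <- rbind(per_res("N", -0.9 * tx, -0.9 * ty, -1.1),
                  per_res("CA", 0, 0, 0),
                  per_res("C", 0.9 * tx, 0.9 * ty, 1.1),
                  per_res("O", 0.9 * tx + 1.1 * ux, 0.9 * ty + 1.1 * uy,
                          1.2))
      at[order(at$res_idx, match(at$atom, c("N", "CA", "C", "O"))),
         , drop = FALSE]
    })
    AtomicModel(do.call(rbind, chains))
  })
}

#' Generate a noisy residue probability profile around a true sequence
#'
#' Emulates the per-residue amino-acid probability vectors of an automated
#' model builder by mixing the one-hot true identity with the uniform
#' distribution: P[i] = (1 - eta) * onehot(seq[i]) + eta / 20. eta = 0 is
#' a perfect prediction, eta = 1 is uninformative. Confidences are drawn
#' i.i.d. from Uniform(confRange).
#'
#' @param trueSeq amino-acid string.
#' @param eta mixing weight in [0, 1].
#' @param confRange length-2 range for sampled confidences.
#' @param seed RNG seed (confidences).
#' @param chainId chain id recorded in the profile.
#' @return a \linkS4class{ResidueProfile}; rows sum to 1 exactly.
#' @export
genProfile <- function(trueSeq, eta = 0.5, confRange = c(0.5, 1.0),
                       seed = 1L, chainId = "A") {
  if (eta < 0 || eta > 1) stopf("eta must lie in [0, 1]")
  code <- match(strsplit(toupper(trueSeq), "")[[1]], AA_ALPHABET)
  if (anyNA(code)) stopf("trueSeq contains non-standard letters")
  L <- length(code)
  P <- matrix(eta / 20, L, 20)
  P[cbind(seq_len(L), code)] <- P[cbind(seq_len(L), code)] + (1 - eta)
  conf <- with_seed(seed, runif(L, confRange[1], confRange[2]))
  ResidueProfile(chainId, P, conf)
}

#' Generate a decoy proteome with embedded true sequences
#'
#' Decoys are i.i.d. sequences from the composition with lengths from
#' \code{lenDist}. Each true sequence is embedded at a random offset
#' inside a longer random host sequence; its database id is prefixed with
#' \code{"true_"} so ground truth is recoverable, and the embedding offset
#' is recorded in the description column.
#'
#' @param trueSeqs named character vector (or list) of true sequences;
#'   unnamed entries get ids T1, T2, ...
#' @param nDecoys number of decoy sequences (>= 0).
#' @param lenDist sampler: function(n) returning n integer lengths.
#'   Default: 50 + Poisson(250), a realistic protein-length spread.
#' @param composition length-20 amino-acid distribution for decoys and
#'   host padding.
#' @param seed RNG seed.
#' @param pad mean padding (residues, Poisson on each side) around each
#'   embedded true sequence.
#' @return an \code{AAStringSet}; ground-truth ids are
#'   \code{true_<name>}, decoys \code{decoy_<k>}.
#' @export
genProteome <- function(trueSeqs, nDecoys = 100L,
                        lenDist = function(n) 50L + stats::rpois(n, 250),
                        composition = aaComposition("uniform"),
                        seed = 1L, pad = 40) {
  trueSeqs <- unlist(as.list(trueSeqs))
  nm <- names(trueSeqs)
  if (is.null(nm)) nm <- sprintf("T%d", seq_along(trueSeqs))
  blank <- !nzchar(nm)
  nm[blank] <- sprintf("T%d", which(blank))
  trueSeqs <- as.character(trueSeqs)
  with_seed(seed, {
    hosts <- vapply(seq_along(trueSeqs), function(k) {
      npre <- stats::rpois(1, pad); npost <- stats::rpois(1, pad)
      paste0(if (npre) random_aa_seq(npre, composition) else "",
             trueSeqs[k],
             if (npost) random_aa_seq(npost, composition) else "")
    }, character(1))
    offs <- vapply(seq_along(trueSeqs), function(k) {
      as.integer(regexpr(trueSeqs[k], hosts[k], fixed = TRUE))
    }, integer(1))
    decoys <- if (nDecoys > 0) {
      lens <- pmax(as.integer(lenDist(nDecoys)), 1L)
      vapply(lens, random_aa_seq, character(1), composition = composition)
    } else character(0)
    db <- Biostrings::AAStringSet(c(hosts, decoys))
    names(db) <- c(sprintf("true_%s", nm),
                   sprintf("decoy_%04d", seq_len(nDecoys)))
    S4Vectors::mcols(db)$desc <-
      c(sprintf("embedded at offset %d", offs),
        rep("", length(decoys)))
    db
  })
}

#' Render a model as a Gaussian density map
#'
#' Sum of isotropic Gaussians of width sigma and the given amplitude at
#' every atom, sampled on a grid with the given voxel size, padded around
#' the model's bounding box. Deterministic.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param voxel voxel size in Angstrom (isotropic, or length 3).
#' @param sigma Gaussian width in Angstrom.
#' @param boxPad padding around the bounding box in Angstrom.
#' @param amplitude per-atom peak amplitude.
#' @return a \linkS4class{DensityMap}.
#' @export
renderMap <- function(model, voxel = 1.0, sigma = 1.0, boxPad = 5.0,
                      amplitude = 1.0) {
  a <- model@atoms
  if (nrow(a) == 0L) stopf("empty model")
  if (length(voxel) == 1L) voxel <- rep(voxel, 3)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - boxPad
  hi <- apply(xyz, 2, max) + boxPad
  d <- pmax(ceiling((hi - lo) / voxel) + 1, 2)
  g <- array(0, dim = d)
  gx <- lo[1] + (seq_len(d[1]) - 1) * voxel[1]
  gy <- lo[2] + (seq_len(d[2]) - 1) * voxel[2]
  gz <- lo[3] + (seq_len(d[3]) - 1) * voxel[3]
  reach <- 4 * sigma
  for (k in seq_len(nrow(xyz))) {
    ix <- which(abs(gx - xyz[k, 1]) <= reach)
    iy <- which(abs(gy - xyz[k, 2]) <= reach)
    iz <- which(abs(gz - xyz[k, 3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    ex <- exp(-(gx[ix] - xyz[k, 1])^2 / (2 * sigma^2))
    ey <- exp(-(gy[iy] - xyz[k, 2])^2 / (2 * sigma^2))
    ez <- exp(-(gz[iz] - xyz[k, 3])^2 / (2 * sigma^2))
    g[ix, iy, iz] <- g[ix, iy, iz] +
      amplitude * (ex %o% ey %o% ez)
  }
  DensityMap(g, voxelSize = voxel, origin = lo)
}

#' Perturb a model with coordinate jitter and identity errors
#'
#' Adds i.i.d. Gaussian noise to every atom coordinate and resamples each
#' residue identity uniformly from the 19 other amino acids with the given
#' rate. Deterministic given the seed.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param sigmaXyz per-coordinate Gaussian sigma in Angstrom.
#' @param identityErrorRate per-residue identity error probability.
#' @param seed RNG seed.
#' @return a perturbed \linkS4class{AtomicModel}.
#' @export
perturbModel <- function(model, sigmaXyz = 0, identityErrorRate = 0,
                         seed = 1L) {
  if (identityErrorRate < 0 || identityErrorRate > 1)
    stopf("identityErrorRate must lie in [0, 1]")
  with_seed(seed, {
    a <- model@atoms
    if (sigmaXyz > 0) {
      a$x <- a$x + rnorm(nrow(a), 0, sigmaXyz)
      a$y <- a$y + rnorm(nrow(a), 0, sigmaXyz)
      a$z <- a$z + rnorm(nrow(a), 0, sigmaXyz)
    }
    if (identityErrorRate > 0) {
      rt <- residueTable(AtomicModel(a))
      prot <- which(is_protein_resname(rt$res_name))
      flip <- prot[runif(length(prot)) < identityErrorRate]
      for (r in flip) {
        cur <- AA_ONE[rt$res_name[r]]
        repl <- sample(setdiff(AA_ALPHABET, cur), 1)
        sel <- a$chain == rt$chain[r] & a$res_idx == rt$res_idx[r]
        a$res_name[sel] <- AA_THREE[repl]
      }
    }
    AtomicModel(a)
  })
}
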