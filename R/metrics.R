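#' ResidueCorrespondence: one-to-one residue pairing between two models
#'
#' @slot pairs data.frame with predicted/reference residue references and
#'   the anchor distance of each pair.
#' @slot unmatchedPred,unmatchedRef data.frames of unpaired residues.
#' @slot pred,ref the two models.
#' @slot cutoff the pairing distance cutoff (Angstrom).
#' @export
setClass("ResidueCorrespondence",
         representation(pairs = "data.frame", unmatchedPred = "data.frame",
                        unmatchedRef = "data.frame", pred = "AtomicModel",
                        ref = "AtomicModel", cutoff = "numeric"))

setMethod("show", "ResidueCorrespondence", function(object) {
  cat(sprintf(
    "ResidueCorrespondence: %d pairs (cutoff %.1f A), %d pred / %d ref unmatched\n",
    nrow(object@pairs), object@cutoff, nrow(object@unmatchedPred),
    nrow(object@unmatchedRef)))
})

#' Match residues between a predicted and a reference model
#'
#' Mutual-nearest-neighbour one-to-one pairing of residues by anchor-atom
#' (CA for protein, P for nucleotide) distance, keeping pairs within the
#' cutoff (default 3 A). Distance ties are broken by smaller distance then
#' lower reference index.
#'
#' @param pred,ref \linkS4class{AtomicModel}s in the same (map) frame.
#' @param cutoff pairing distance cutoff in Angstrom.
#' @return a \linkS4class{ResidueCorrespondence}.
#' @export
matchResidues <- function(pred, ref, cutoff = 3.0) {
  prt <- residueTable(pred); prt <- prt[!is.na(prt$ax), , drop = FALSE]
  rrt <- residueTable(ref); rrt <- rrt[!is.na(rrt$ax), , drop = FALSE]
  if (nrow(prt) == 0L || nrow(rrt) == 0L)
    stopf("anchor atoms absent from all residues of one model")
  rownames(prt) <- NULL; rownames(rrt) <- NULL
  pm <- as.matrix(prt[, c("ax", "ay", "az")])
  rm_ <- as.matrix(rrt[, c("ax", "ay", "az")])
  d2 <- outer(rowSums(pm^2), rep(1, nrow(rm_))) +
    outer(rep(1, nrow(pm)), rowSums(rm_^2)) - 2 * pm %*% t(rm_)
  dmat <- sqrt(pmax(d2, 0))
  ## nearest with ties to the lower index
  nn_ref <- apply(dmat, 1, which.min)
  nn_pred <- apply(dmat, 2, which.min)
  i <- seq_len(nrow(prt))
  mutual <- nn_pred[nn_ref[i]] == i &
    dmat[cbind(i, nn_ref[i])] <= cutoff
  pairs <- data.frame(
    pred_chain = prt$chain[mutual], pred_idx = prt$res_idx[mutual],
    ref_chain = rrt$chain[nn_ref[mutual]],
    ref_idx = rrt$res_idx[nn_ref[mutual]],
    dist = dmat[cbind(which(mutual), nn_ref[mutual])],
    pred_row = which(mutual), ref_row = nn_ref[mutual],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$dist, pairs$ref_row), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ResidueCorrespondence", pairs = pairs,
      unmatchedPred = prt[setdiff(i, pairs$pred_row), , drop = FALSE],
      unmatchedRef = rrt[setdiff(seq_len(nrow(rrt)), pairs$ref_row),
                         , drop = FALSE],
      pred = pred, ref = ref, cutoff = cutoff)
}

#' Pooled RMSD over corresponding residues
#'
#' Root mean square of per-atom distances pooled over all residue pairs,
#' with no superposition (both models are assumed to share the map's
#' coordinate frame). Only atoms named in \code{atoms} and present on both
#' sides of a pair contribute.
#'
#' @param corr a \linkS4class{ResidueCorrespondence}.
#' @param atoms atom names to pool; \code{"CA"} for C-alpha RMSD,
#'   \code{c("CA", "C", "O", "N")} for protein backbone,
#'   \code{c("OP1", "P", "OP2", "O5'")} for nucleotide backbone.
#' @return RMSD in Angstrom.
#' @export
rmsdMetrics <- function(corr, atoms = "CA") {
  if (nrow(corr@pairs) == 0L) stopf("no residue pairs to compute RMSD over")
  pa <- corr@pred@atoms; ra <- corr@ref@atoms
  pa <- pa[pa$atom %in% atoms, , drop = FALSE]
  ra <- ra[ra$atom %in% atoms, , drop = FALSE]
  pkey <- paste(pa$chain, pa$res_idx, pa$atom, sep = "\r")
  rkey <- paste(ra$chain, ra$res_idx, ra$atom, sep = "\r")
  sq <- numeric(0)
  for (k in seq_len(nrow(corr@pairs))) {
    pr <- corr@pairs[k, ]
    for (at in atoms) {
      ip <- match(paste(pr$pred_chain, pr$pred_idx, at, sep = "\r"), pkey)
      ir <- match(paste(pr$ref_chain, pr$ref_idx, at, sep = "\r"), rkey)
      if (is.na(ip) || is.na(ir)) next
      sq <- c(sq, (pa$x[ip] - ra$x[ir])^2 + (pa$y[ip] - ra$y[ir])^2 +
                (pa$z[ip] - ra$z[ir])^2)
    }
  }
  if (length(sq) == 0L)
    stopf("no atoms named %s present on both sides of any pair",
          paste(atoms, collapse = "/"))
  sqrt(mean(sq))
}

#' Recall, precision, identity accuracy and completeness
#'
#' recall = pairs / reference residues; precision = pairs / predicted
#' residues; identity accuracy = fraction of paired predicted residues
#' whose identity equals the reference (amino-acid accuracy for proteins,
#' base accuracy for nucleotides); completeness = fraction of reference
#' residues that are both paired and identity-correct. All lie in [0, 1]
#' and completeness <= recall.
#'
#' @param corr a \linkS4class{ResidueCorrespondence}.
#' @return a list with \code{recall}, \code{precision},
#'   \code{aa_accuracy}, \code{completeness}, \code{n_pairs},
#'   \code{n_pred}, \code{n_ref}, and the per-pair table
#'   \code{pair_table} with an \code{identity_correct} column.
#' @export
classificationMetrics <- function(corr) {
  prt <- residueTable(corr@pred); rrt <- residueTable(corr@ref)
  n_pred <- sum(!is.na(prt$ax)); n_ref <- sum(!is.na(rrt$ax))
  if (n_ref == 0L) stopf("empty reference model")
  p <- corr@pairs
  pk <- paste(prt$chain, prt$res_idx, sep = "\r")
  rk <- paste(rrt$chain, rrt$res_idx, sep = "\r")
  pid <- prt$res_name[match(paste(p$pred_chain, p$pred_idx, sep = "\r"), pk)]
  rid <- rrt$res_name[match(paste(p$ref_chain, p$ref_idx, sep = "\r"), rk)]
  ok <- pid == rid
  p$identity_correct <- ok
  list(recall = nrow(p) / n_ref,
       precision = if (n_pred) nrow(p) / n_pred else 0,
       aa_accuracy = if (nrow(p)) mean(ok) else NA_real_,
       completeness = sum(ok) / n_ref,
       n_pairs = nrow(p), n_pred = n_pred, n_ref = n_ref,
       pair_table = p)
}

## Trilinear interpolation of map values at Angstrom points (n x 3).
interp_map <- function(map, pts) {
  g <- map@grid; d <- dim(g); vx <- map@voxelSize
  ## continuous 1-based grid coordinates
  u <- sweep(sweep(pts, 2, map@origin, "-"), 2, vx, "/") + 1
  i0 <- pmin(pmax(floor(u), 1), matrix(rep(d - 1L, each = nrow(u)),
                                       ncol = 3))
  f <- u - i0
  f <- pmin(pmax(f, 0), 1)
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- ((if (dx == 1) f[, 1] else 1 - f[, 1]) *
          (if (dy == 1) f[, 2] else 1 - f[, 2]) *
          (if (dz == 1) f[, 3] else 1 - f[, 3]))
    v <- v + w * g[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  v
}

## Deterministic Fibonacci spherical point set (n x 3 unit vectors).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Q-score: per-atom resolvability of a model in a density map
#'
#' For each atom, map values are interpolated at deterministic points on
#' concentric spherical shells (radii 0 to \code{rMax}) around the atom;
#' points closer to any other atom than to the evaluated atom are
#' excluded. The Q-score of the atom is the Pearson correlation between
#' those map values and a reference Gaussian of width \code{sigma}
#' evaluated at the shell radii, so it is invariant to affine rescaling of
#' the map. Atoms closer than \code{rMax} to the map edge are skipped and
#' counted.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param map a \linkS4class{DensityMap} containing the model.
#' @param sigma reference Gaussian width in Angstrom.
#' @param rMax largest shell radius in Angstrom.
#' @param shellSpacing radial spacing of shells in Angstrom.
#' @param pointsPerShell points per nonzero shell (deterministic
#'   Fibonacci set).
#' @return a list with \code{atom_q} (per-atom table), \code{residue_q}
#'   (per-residue mean), \code{model_q} (mean over evaluated atoms), and
#'   \code{n_skipped}.
#' @export
qscore <- function(model, map, sigma = 0.6, rMax = 2.0,
                   shellSpacing = 0.1, pointsPerShell = 8L) {
  a <- model@atoms
  if (nrow(a) == 0L) stopf("empty model")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- dim(map@grid); vx <- map@voxelSize
  lo <- map@origin; hi <- map@origin + (d - 1) * vx
  inside <- apply(sweep(xyz, 2, lo + rMax, ">="), 1, all) &
    apply(sweep(xyz, 2, hi - rMax, "<="), 1, all)
  n_skipped <- sum(!inside)
  if (n_skipped > 0L)
    warning(sprintf("%d atom(s) closer than rMax to the map edge; skipped",
                    n_skipped))
  radii <- seq(0, rMax, by = shellSpacing)
  sph <- fibonacci_sphere(pointsPerShell)
  offs <- do.call(rbind, lapply(radii, function(r) {
    if (r == 0) matrix(0, 1, 3) else r * sph
  }))
  rvals <- rep(radii, times = ifelse(radii == 0, 1L, pointsPerShell))
  gref <- exp(-rvals^2 / (2 * sigma^2))
  qs <- rep(NA_real_, nrow(a))
  for (k in which(inside)) {
    pts <- sweep(offs, 2, xyz[k, ], "+")
    ## neighbours within 2*rMax can claim points inside the shell set
    dn <- sqrt(rowSums(sweep(xyz, 2, xyz[k, ], "-")^2))
    nb <- which(dn < 2 * rMax & seq_len(nrow(a)) != k)
    keep <- rep(TRUE, nrow(pts))
    if (length(nb)) {
      for (j in nb) {
        dj <- sqrt(rowSums(sweep(pts, 2, xyz[j, ], "-")^2))
        keep <- keep & dj >= rvals
      }
    }
    if (sum(keep) < 3L || sd(gref[keep]) == 0) next
    mv <- interp_map(map, pts[keep, , drop = FALSE])
    if (sd(mv) == 0) { qs[k] <- 0; next }
    qs[k] <- cor(mv, gref[keep])
  }
  atom_q <- data.frame(chain = a$chain, res_idx = a$res_idx,
                       atom = a$atom, q = qs, stringsAsFactors = FALSE)
  res_q <- do.call(rbind, lapply(
    split(atom_q, paste(atom_q$chain, atom_q$res_idx, sep = "\r")),
    function(g) data.frame(chain = g$chain[1], res_idx = g$res_idx[1],
                           q = mean(g$q, na.rm = TRUE),
                           stringsAsFactors = FALSE)))
  res_q <- res_q[order(match(res_q$chain, unique(a$chain)), res_q$res_idx),
                 , drop = FALSE]
  rownames(res_q) <- NULL
  list(atom_q = atom_q, residue_q = res_q,
       model_q = mean(qs, na.rm = TRUE), n_skipped = n_skipped)
}

#' Fourier shell correlation between two maps
#'
#' Per radial shell in Fourier space, the normalized cross-correlation of
#' the two discrete Fourier transforms. Returns the curve and the spatial
#' frequency of the first 0.5 crossing when one exists.
#'
#' @param mapA,mapB \linkS4class{DensityMap}s on identical grids.
#' @param shellWidth shell width in 1/Angstrom; defaults to one Fourier
#'   voxel of the largest axis extent.
#' @return a list with \code{curve} (data.frame \code{freq}, \code{fsc},
#'   \code{n}) and \code{crossing_0.5} (frequency in 1/Angstrom, or NA).
#' @export
fsc <- function(mapA, mapB, shellWidth = NULL) {
  if (!identical(dim(mapA@grid), dim(mapB@grid)))
    stopf("maps must share an identical grid")
  if (any(abs(mapA@voxelSize - mapB@voxelSize) > 1e-6))
    stopf("maps must share the same voxel size")
  d <- dim(mapA@grid); vx <- mapA@voxelSize
  FA <- fft(mapA@grid); FB <- fft(mapB@grid)
  fr <- function(n, v) {
    k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n
    k / (n * v)
  }
  fx <- fr(d[1], vx[1]); fy <- fr(d[2], vx[2]); fz <- fr(d[3], vx[3])
  fmag <- sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
  if (is.null(shellWidth)) shellWidth <- 1 / max(d * vx)
  shell <- floor(fmag / shellWidth)
  fmax <- 1 / (2 * max(vx))  # Nyquist
  keep <- fmag <= fmax
  num <- Re(FA * Conj(FB)); aa <- Mod(FA)^2; bb <- Mod(FB)^2
  idx <- shell[keep] + 1L
  s_num <- tapply(num[keep], idx, sum)
  s_aa <- tapply(aa[keep], idx, sum)
  s_bb <- tapply(bb[keep], idx, sum)
  s_n <- tapply(rep(1, sum(keep)), idx, sum)
  corr <- as.numeric(s_num / sqrt(s_aa * s_bb))
  freq <- (as.integer(names(s_num)) - 0.5) * shellWidth
  curve <- data.frame(freq = freq, fsc = corr, n = as.integer(s_n))
  curve <- curve[is.finite(curve$fsc), , drop = FALSE]
  cross <- NA_real_
  below <- which(curve$fsc < 0.5)
  if (length(below) && below[1] > 1) {
    i <- below[1]
    f1 <- curve$freq[i - 1]; f2 <- curve$freq[i]
    c1 <- curve$fsc[i - 1]; c2 <- curve$fsc[i]
    cross <- f1 + (0.5 - c1) * (f2 - f1) / (c2 - c1)
  }
  list(curve = curve, crossing_0.5 = cross)
}

#' Evaluate a predicted model against a reference model
#'
#' Convenience wrapper: residue correspondence at the cutoff, then
#' C-alpha RMSD, backbone RMSD, recall, precision, identity accuracy and
#' completeness.
#'
#' @param pred,ref \linkS4class{AtomicModel}s in the same frame.
#' @param cutoff pairing cutoff in Angstrom.
#' @return a list with the metric fields and the per-pair table.
#' @export
evaluateModels <- function(pred, ref, cutoff = 3.0) {
  corr <- matchResidues(pred, ref, cutoff = cutoff)
  cm <- classificationMetrics(corr)
  calpha <- if (nrow(corr@pairs)) rmsdMetrics(corr, "CA") else NA_real_
  backbone <- if (nrow(corr@pairs))
    rmsdMetrics(corr, c("CA", "C", "O", "N")) else NA_real_
  c(list(calpha_rmsd = calpha, backbone_rmsd = backbone), cm)
}
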