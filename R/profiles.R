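#' Build the profile-HMM transition table from per-residue confidences
#'
#' Per node i with confidence c(i), the transitions are
#' \deqn{P_{M\to M}(i) = \max(c(i) - d,\ m_{min})}
#' \deqn{P_{M\to I}(i) = P_{M\to D}(i) = (1 - P_{M\to M}(i)) / 2}
#' \deqn{P_{I\to M}(i) = P_{D\to M}(i) = 1 - d}
#' \deqn{P_{I\to I}(i) = P_{D\to D}(i) = d}
#' with \eqn{P_{I\to D} = P_{D\to I} = 0}. The constant d and the floor
#' on the match-to-match probability default to 0.5. Note that at the
#' defaults, \eqn{\max(c - 0.5, 0.5) = 0.5} for every confidence in
#' [0, 1], so the match-to-match probability is constant; lowering
#' \code{d} or \code{mmin} restores confidence dependence.
#'
#' @param conf numeric vector of per-residue confidences in [0, 1].
#' @param d decay constant in (0, 1); default 0.5.
#' @param mmin floor for the match-to-match probability; default 0.5.
#' @return an L x 7 matrix with columns \code{MM, MI, MD, IM, II, DM, DD};
#'   each of the three outgoing distributions (M, I, D) sums to 1.
#' @examples
#' buildTransitions(c(1.0, 0.3))            # MM constant 0.5 at defaults
#' buildTransitions(0.9, d = 0.2, mmin = 0) # MM = 0.7
#' @export
buildTransitions <- function(conf, d = 0.5, mmin = 0.5) {
  if (!(d > 0 && d < 1)) stopf("d must lie in (0, 1)")
  if (mmin < 0 || mmin > 1) stopf("mmin must lie in [0, 1]")
  bad <- which(conf < 0 | conf > 1 | !is.finite(conf))
  if (length(bad))
    stopf("confidence outside [0, 1] at index %d", bad[1])
  mm <- pmax(conf - d, mmin)
  tr <- cbind(MM = mm, MI = (1 - mm) / 2, MD = (1 - mm) / 2,
              IM = 1 - d, II = d, DM = 1 - d, DD = d)
  rownames(tr) <- NULL
  tr
}

#' Build a profile HMM from a residue probability profile
#'
#' Match emissions are the predicted per-residue amino-acid probabilities;
#' insert emissions are the background distribution; transitions come from
#' \code{\link{buildTransitions}} applied to the confidence vector.
#'
#' @param rp a \linkS4class{ResidueProfile}.
#' @param d,mmin transition parameters, see \code{\link{buildTransitions}}.
#' @param background length-20 background distribution; default uniform.
#' @param name profile name; defaults to the profile's chain id.
#' @return a \linkS4class{ProfileHMM} with L = \code{profileLength(rp)}.
#' @export
buildProfile <- function(rp, d = 0.5, mmin = 0.5,
                         background = rep(1 / 20, 20),
                         name = chainId(rp)) {
  validObject(rp)
  L <- profileLength(rp)
  if (L == 0L) stopf("profile has no residues")
  P <- probMatrix(rp)
  P <- P / rowSums(P)  # exact row normalization for the 1e-9 invariant
  ins <- matrix(rep(background / sum(background), each = L), nrow = L)
  ProfileHMM(name = name, matchEmit = P, insertEmit = ins,
             transitions = buildTransitions(confidences(rp), d, mmin),
             background = background / sum(background))
}

#' Map a predicted backbone RMSD to a confidence score
#'
#' Linear map from predicted backbone RMSD (Angstrom) to a score in
#' [0, 1]: 0.5 A and below maps to 1, 1.2 A and above to 0, linear in
#' between. The score is what gets stored in the B-factor column of
#' output coordinate files.
#'
#' @param rmsd non-negative predicted backbone RMSD in Angstrom
#'   (vectorized).
#' @return scores in [0, 1].
#' @examples
#' rmsdToScore(c(0.5, 0.85, 1.2))  # 1, 0.5, 0
#' @export
rmsdToScore <- function(rmsd) {
  if (any(rmsd < 0 | !is.finite(rmsd)))
    stopf("rmsd must be non-negative and finite")
  pmin(pmax((1.2 - rmsd) / (1.2 - 0.5), 0), 1)
}
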