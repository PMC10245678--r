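#' CalibrationCurve: Gumbel parameters for E-value computation
#'
#' Location/scale of the Gumbel law fitted to Forward bit scores of random
#' background sequences, in the survival parameterization
#' P(S > s) = 1 - exp(-exp(-lambda (s - mu))).
#'
#' @slot mu location (bits).
#' @slot lambda inverse scale (1/bits), > 0.
#' @slot nSamples number of random sequences used in the fit.
#' @slot seed RNG seed used.
#' @export
setClass("CalibrationCurve",
         representation(mu = "numeric", lambda = "numeric",
                        nSamples = "integer", seed = "integer"))

setValidity("CalibrationCurve", function(object) {
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@nSamples < 100L) return("nSamples must be >= 100")
  TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: mu %.3f bits, lambda %.3f (n = %d, seed %d)\n",
              object@mu, object@lambda, object@nSamples, object@seed))
})

## Encode an amino-acid string as 0-based column indices; X (background
## emission in every state) becomes -1.
encode_seq <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  code <- match(ch, AA_ALPHABET) - 1L
  isx <- ch == "X"
  code[isx] <- -1L
  if (anyNA(code))
    stopf("invalid amino-acid letter '%s' at position %d",
          ch[which(is.na(code))[1]], which(is.na(code))[1])
  code
}

hmm_log_tables <- function(hmm) {
  bg <- bgFrequencies(hmm)
  list(mlod = log(sweep(matchEmissions(hmm), 2, bg, "/")),
       ilod = log(sweep(insertEmissions(hmm), 2, bg, "/")),
       ltr = log(transitionTable(hmm)))
}

#' Forward bit score of a sequence under a profile HMM
#'
#' Log2 of the ratio of the total probability of the sequence under the
#' profile (local alignment, summed over all paths: entry 1/L into any
#' match node at any position, free exit from any match state, flanking
#' residues emitted by the background) to its probability under the
#' background null.
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param seq amino-acid string (X emits background in all states).
#' @return bit score (finite for all valid inputs).
#' @export
forwardScore <- function(hmm, seq) {
  if (!nzchar(seq)) stopf("empty sequence")
  lt <- hmm_log_tables(hmm)
  c_forward(lt$mlod, lt$ilod, lt$ltr, encode_seq(seq))
}

#' Viterbi bit score and alignment of a sequence under a profile HMM
#'
#' The single highest-probability local alignment path under the same model
#' as \code{\link{forwardScore}}; its M-state entries define the matched
#' residues used downstream for mutation. Score ties are broken by state
#' priority M > D > I. The Viterbi bit score never exceeds the Forward bit
#' score.
#'
#' @inheritParams forwardScore
#' @return a list with \code{bits} and \code{alignment}, a data.frame with
#'   columns \code{node} (profile node), \code{pos} (target position, NA
#'   for delete states), \code{state} ("M", "I" or "D").
#' @export
viterbiAlign <- function(hmm, seq) {
  if (!nzchar(seq)) stopf("empty sequence")
  lt <- hmm_log_tables(hmm)
  v <- c_viterbi(lt$mlod, lt$ilod, lt$ltr, encode_seq(seq))
  ali <- as.data.frame(v$path)
  ali$state <- c("M", "I", "D")[ali$state]
  list(bits = v$bits, alignment = ali)
}

#' Calibrate E-values by a Gumbel fit to random-sequence scores
#'
#' Draws n i.i.d. sequences from the profile's background composition,
#' scores them with \code{\link{forwardScore}}, and fits a Gumbel law by
#' maximum likelihood. Deterministic given the seed.
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param n number of random sequences (>= 100).
#' @param len sequence length: a single integer, or a function of one
#'   argument returning that many integer lengths.
#' @param seed RNG seed.
#' @return a \linkS4class{CalibrationCurve}.
#' @export
calibrate <- function(hmm, n = 1000L, len = 150L, seed = 1L) {
  n <- as.integer(n)
  if (n < 100L) stopf("calibration needs n >= 100 sequences")
  bg <- bgFrequencies(hmm)
  scores <- with_seed(seed, {
    lens <- if (is.function(len)) as.integer(len(n)) else rep(as.integer(len), n)
    lt <- hmm_log_tables(hmm)
    seqs <- lapply(lens, function(l) {
      as.integer(sample.int(20L, l, replace = TRUE, prob = bg) - 1L)
    })
    c_forward_batch(lt$mlod, lt$ilod, lt$ltr, seqs)
  })
  if (sd(scores) < 1e-12)
    stopf("degenerate score distribution (zero variance); cannot calibrate")
  beta0 <- sd(scores) * sqrt(6) / pi
  mu0 <- mean(scores) - 0.5772156649 * beta0
  nll <- function(p) {
    beta <- exp(p[2])
    z <- (scores - p[1]) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  new("CalibrationCurve", mu = fit$par[1], lambda = 1 / exp(fit$par[2]),
      nSamples = n, seed = as.integer(seed))
}

#' Gumbel survival probability of a bit score
#'
#' @param cal a \linkS4class{CalibrationCurve}.
#' @param bits bit score(s).
#' @return P(S > bits) under the fitted Gumbel law.
#' @export
gumbelSurvival <- function(cal, bits) {
  ## -expm1(-exp(.)) keeps precision in the far tail
  -expm1(-exp(-cal@lambda * (bits - cal@mu)))
}

#' Search a profile HMM against a sequence database
#'
#' Scores every database sequence with \code{\link{forwardScore}},
#' converts to E-values (database size times the Gumbel survival of the
#' bit score), keeps hits with E <= \code{eMax} sorted by ascending
#' E-value, and attaches the Viterbi alignment of each kept hit.
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param db an \code{AAStringSet} (see \code{\link{readFastaDb}}).
#' @param cal a \linkS4class{CalibrationCurve} from \code{\link{calibrate}}.
#' @param eMax E-value threshold; hits above it are dropped.
#' @return a data.frame with columns \code{query_chain}, \code{target_id},
#'   \code{bit_score}, \code{e_value}, \code{ali_from}, \code{ali_to}
#'   (target positions), \code{node_from}, \code{node_to}, and a
#'   list-column \code{alignment} of Viterbi path data.frames. Zero rows is
#'   a valid result.
#' @export
searchDb <- function(hmm, db, cal, eMax = 10) {
  if (length(db) == 0L) stopf("empty sequence database")
  lt <- hmm_log_tables(hmm)
  seqs <- lapply(as.character(db), encode_seq)
  bits <- c_forward_batch(lt$mlod, lt$ilod, lt$ltr, seqs)
  ev <- length(db) * gumbelSurvival(cal, bits)
  keep <- which(ev <= eMax)
  keep <- keep[order(ev[keep], -bits[keep])]
  ali <- lapply(keep, function(k) viterbiAlign(hmm, as.character(db[[k]])))
  out <- data.frame(
    query_chain = rep(hmm@name, length(keep)),
    target_id = names(db)[keep],
    bit_score = bits[keep],
    e_value = ev[keep],
    ali_from = vapply(ali, function(a) {
      p <- a$alignment$pos[a$alignment$state != "D"]
      if (length(p)) min(p) else NA_integer_
    }, integer(1)),
    ali_to = vapply(ali, function(a) {
      p <- a$alignment$pos[a$alignment$state != "D"]
      if (length(p)) max(p) else NA_integer_
    }, integer(1)),
    node_from = vapply(ali, function(a) min(a$alignment$node), integer(1)),
    node_to = vapply(ali, function(a) max(a$alignment$node), integer(1)),
    stringsAsFactors = FALSE)
  out$alignment <- lapply(ali, `[[`, "alignment")
  rownames(out) <- NULL
  out
}

#' Cross-reference per-chain hits into a consensus table
#'
#' Pseudo-symmetric copies of the same protein in one map each produce a
#' hit list; grouping chains by their best-hit target and summing bit
#' scores bootstraps weak individual hits that agree across copies.
#'
#' @param hitsPerChain named list (chain id -> hit data.frame from
#'   \code{\link{searchDb}}); chains with zero hits are allowed.
#' @return a data.frame with one row per best-hit target: \code{target_id},
#'   \code{k} (number of chains), \code{chains}, \code{combined_bits} (sum
#'   of best bit scores), \code{e_best}, \code{e_worst}; sorted by
#'   descending combined score.
#' @export
aggregateHits <- function(hitsPerChain) {
  if (length(hitsPerChain) == 0L) stopf("need hits for at least one chain")
  if (is.null(names(hitsPerChain)))
    stopf("hitsPerChain must be a named list (chain id -> hit table)")
  best <- lapply(names(hitsPerChain), function(ch) {
    h <- hitsPerChain[[ch]]
    if (is.null(h) || nrow(h) == 0L) return(NULL)
    data.frame(chain = ch, target_id = h$target_id[1],
               bit_score = h$bit_score[1], e_value = h$e_value[1],
               stringsAsFactors = FALSE)
  })
  best <- do.call(rbind, best)
  if (is.null(best)) {
    return(data.frame(target_id = character(), k = integer(),
                      chains = character(), combined_bits = numeric(),
                      e_best = numeric(), e_worst = numeric()))
  }
  out <- do.call(rbind, lapply(split(best, best$target_id), function(g) {
    data.frame(target_id = g$target_id[1], k = nrow(g),
               chains = paste(g$chain, collapse = ","),
               combined_bits = sum(g$bit_score),
               e_best = min(g$e_value), e_worst = max(g$e_value),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$combined_bits), , drop = FALSE]
  rownames(out) <- NULL
  out
}
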