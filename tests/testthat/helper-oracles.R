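## Independent oracles, deliberately written as plain enumeration in R,
## sharing no code with the package's DP engine.

## Enumerate every local alignment path of a profile HMM against a
## sequence and return the summed (forward) and maximal (viterbi) log2
## odds. Model: entry 1/L into any match node at any position, free exit
## from any match state, background-emitting flanks cancel in the odds.
enumerate_paths <- function(hmm, seq) {
  L <- profileLength(hmm)
  me <- matchEmissions(hmm); ie <- insertEmissions(hmm)
  tr <- transitionTable(hmm); bg <- bgFrequencies(hmm)
  code <- match(strsplit(seq, "")[[1]], densid:::AA_ALPHABET)
  n <- length(code)
  em <- function(i, j) log(me[i, code[j]] / bg[code[j]])
  il <- function(i, j) log(ie[i, code[j]] / bg[code[j]])
  logs <- c()
  recurse <- function(i, j, state, lp) {
    if (!is.finite(lp)) return()
    if (state == "M") logs <<- c(logs, lp)  # free exit after any match
    if (state == "M") {
      if (i < L && j < n)
        recurse(i + 1, j + 1, "M", lp + log(tr[i, "MM"]) + em(i + 1, j + 1))
      if (j < n)
        recurse(i, j + 1, "I", lp + log(tr[i, "MI"]) + il(i, j + 1))
      if (i < L)
        recurse(i + 1, j, "D", lp + log(tr[i, "MD"]))
    } else if (state == "I") {
      if (i < L && j < n)
        recurse(i + 1, j + 1, "M", lp + log(tr[i, "IM"]) + em(i + 1, j + 1))
      if (j < n)
        recurse(i, j + 1, "I", lp + log(tr[i, "II"]) + il(i, j + 1))
    } else {  # D
      if (i < L && j < n)
        recurse(i + 1, j + 1, "M", lp + log(tr[i, "DM"]) + em(i + 1, j + 1))
      if (i < L)
        recurse(i + 1, j, "D", lp + log(tr[i, "DD"]))
    }
  }
  for (i0 in seq_len(L)) for (j0 in seq_len(n))
    recurse(i0, j0, "M", -log(L) + em(i0, j0))
  if (length(logs) == 0L) return(list(forward = -Inf, viterbi = -Inf))
  m <- max(logs)
  list(forward = (m + log(sum(exp(logs - m)))) / log(2),
       viterbi = m / log(2))
}

## Brute-force k-nearest-neighbour lists by full pairwise distance sort,
## ties broken by lower index.
brute_knn <- function(xyz, k) {
  n <- nrow(xyz)
  lapply(seq_len(n), function(i) {
    d <- numeric(n)
    for (j in seq_len(n))
      d[j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(min(k, n - 1))]
  })
}
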