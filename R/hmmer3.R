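## HMMER3/f text serialization. Scores are negative natural logs of
## probabilities; probability 0 is "*", probability 1 is "0.00000".

fmt_score <- function(p) {
  ifelse(p <= 0, sprintf("%8s", "*"), sprintf("%8.5f", abs(-log(p))))
}

parse_score <- function(tok) {
  out <- numeric(length(tok))
  num <- tok != "*"
  out[num] <- exp(-as.numeric(tok[num]))
  out
}

#' Write a profile HMM in HMMER3 text format
#'
#' Produces an HMMER3/f file readable by stock HMMER3 tooling. Per node,
#' three lines hold the 20 match-emission scores, the 20 insert-emission
#' scores, and the 7 transition scores (M->M, M->I, M->D, I->M, I->I,
#' D->M, D->D); the I->D and D->I transitions are identically zero and have
#' no columns in the format.
#'
#' Boundary conventions on write: the begin-state line (node 0) reuses the
#' node-1 transition values; at the last node the end state is reached from
#' M with probability 1, so its M->M score is 0.00000 and M->I, M->D and
#' D->D are "*", as HMMER requires. Nominal STATS lines are written so that
#' external HMMER accepts the file; E-values computed by external HMMER
#' from them are advisory (the internal engine calibrates its own).
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeHMMER3 <- function(hmm, path) {
  validObject(hmm)
  L <- profileLength(hmm)
  me <- matchEmissions(hmm); ie <- insertEmissions(hmm)
  tr <- transitionTable(hmm); bg <- bgFrequencies(hmm)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  nm <- gsub("[[:space:]]+", "_", hmm@name)
  w("HMMER3/f [densid | profile predictions]")
  w("NAME  ", nm)
  w("LENG  ", L)
  w("ALPH  amino")
  w("RF    no")
  w("MM    no")
  w("CONS  yes")
  w("CS    no")
  w("MAP   no")
  w("STATS LOCAL MSV       -9.0000  0.70000")
  w("STATS LOCAL VITERBI   -9.5000  0.70000")
  w("STATS LOCAL FORWARD   -4.0000  0.70000")
  w("HMM    ", paste(sprintf("%8s", AA_ALPHABET), collapse = " "))
  w("       ", paste(sprintf("%8s", c("m->m", "m->i", "m->d", "i->m",
                                      "i->i", "d->m", "d->d")),
                     collapse = " "))
  w("  COMPO ", paste(fmt_score(bg), collapse = " "))
  w("        ", paste(fmt_score(ie[1, ]), collapse = " "))
  ## node 0: B->M1, B->I0, B->D1, I0->M1, I0->I0, then D0 placeholders
  w("        ", paste(c(fmt_score(tr[1, c("MM", "MI", "MD", "IM", "II")]),
                        fmt_score(1), fmt_score(0)), collapse = " "))
  cons <- AA_ALPHABET[apply(me, 1, which.max)]
  for (i in seq_len(L)) {
    w(sprintf("%7d ", i), paste(fmt_score(me[i, ]), collapse = " "),
      sprintf(" %6s %s %s %s %s", "-", cons[i], "-", "-", "-"))
    w("        ", paste(fmt_score(ie[i, ]), collapse = " "))
    if (i < L) {
      w("        ", paste(fmt_score(tr[i, ]), collapse = " "))
    } else {
      ## end state reached from the last M with probability 1
      w("        ", paste(c(fmt_score(1), fmt_score(0), fmt_score(0),
                            fmt_score(tr[i, c("IM", "II")]),
                            fmt_score(1), fmt_score(0)), collapse = " "))
    }
  }
  w("//")
  invisible(path)
}

#' Read a profile HMM from an HMMER3 text file
#'
#' Inverse of \code{\link{writeHMMER3}}: probabilities are recovered to
#' within 1e-5. The background distribution is taken from the node-0 insert
#' emissions. The last node's M-state and D-state transitions are fixed by
#' the end-state convention (M->M = 1, D->M = 1), as in the file.
#'
#' @param path an HMMER3/f file (single profile).
#' @return a \linkS4class{ProfileHMM}.
#' @export
readHMMER3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^HMMER3", lines[1]))
    stopf("%s: line 1: not an HMMER3 text file", path)
  grab <- function(key) {
    i <- grep(paste0("^", key, "\\s"), lines)
    if (!length(i)) stopf("%s: missing %s line", path, key)
    strsplit(trimws(lines[i[1]]), "\\s+")[[1]][2]
  }
  name <- grab("NAME")
  L <- as.integer(grab("LENG"))
  if (!identical(grab("ALPH"), "amino"))
    stopf("%s: only the amino alphabet is supported", path)
  hmm_i <- grep("^HMM\\s", lines)[1]
  if (is.na(hmm_i)) stopf("%s: missing HMM header line", path)
  i <- hmm_i + 2L  # skip transition-order line
  toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  if (identical(toks(i)[1], "COMPO")) i <- i + 1L
  ins0 <- toks(i)
  if (length(ins0) != 20L)
    stopf("%s: line %d: expected 20 insert scores", path, i)
  background <- parse_score(ins0)
  background <- background / sum(background)
  i <- i + 2L  # skip node-0 transitions
  me <- matrix(0, L, 20); ie <- matrix(0, L, 20); tr <- matrix(0, L, 7)
  for (k in seq_len(L)) {
    mt <- toks(i)
    if (length(mt) < 21L || suppressWarnings(as.integer(mt[1])) != k)
      stopf("%s: line %d: expected node %d match line", path, i, k)
    me[k, ] <- parse_score(mt[2:21])
    it <- toks(i + 1L)
    if (length(it) != 20L)
      stopf("%s: line %d: expected 20 insert scores", path, i + 1L)
    ie[k, ] <- parse_score(it)
    tt <- toks(i + 2L)
    if (length(tt) != 7L)
      stopf("%s: line %d: expected 7 transition scores", path, i + 2L)
    tr[k, ] <- parse_score(tt)
    i <- i + 3L
  }
  if (i > length(lines) || trimws(lines[i]) != "//")
    stopf("%s: line %d: expected terminating //", path, i)
  ## exact renormalization within serialization tolerance
  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  tr[, 1:3] <- tr[, 1:3] / rowSums(tr[, 1:3, drop = FALSE])
  tr[, 4:5] <- tr[, 4:5] / rowSums(tr[, 4:5, drop = FALSE])
  tr[, 6:7] <- tr[, 6:7] / rowSums(tr[, 6:7, drop = FALSE])
  ProfileHMM(name = name, matchEmit = me, insertEmit = ie,
             transitions = tr, background = background)
}
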