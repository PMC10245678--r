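#' Read per-residue probability profiles from a tab-separated table
#'
#' One row per residue: \code{chain_id}, \code{residue_index},
#' \code{confidence}, then 20 probabilities in fixed alphabetical one-letter
#' amino-acid order (A, C, D, ..., Y). Rows are grouped by chain in file
#' order. Probability rows are renormalized to sum exactly 1 when their sum
#' is within 1e-3 of 1; larger deviations are an error.
#'
#' @param path tab-separated file; lines starting with \code{#} are ignored.
#' @return a list of \linkS4class{ResidueProfile}, one per chain.
#' @export
readProfileTable <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) != 23L)
    stopf("profile table must have 23 columns (chain, index, confidence, 20 probabilities); found %d",
          ncol(tab))
  names(tab) <- c("chain_id", "residue_index", "confidence", AA_ALPHABET)
  P <- as.matrix(tab[, AA_ALPHABET])
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > 1e-3)
  if (length(bad))
    stopf("probability row %d (chain %s, residue %s) sums to %.6f, not 1",
          bad[1], tab$chain_id[bad[1]], tab$residue_index[bad[1]], rs[bad[1]])
  badc <- which(tab$confidence < 0 | tab$confidence > 1)
  if (length(badc))
    stopf("confidence %.4f outside [0, 1] at row %d", tab$confidence[badc[1]],
          badc[1])
  P <- P / rs
  chains <- unique(tab$chain_id)
  lapply(chains, function(ch) {
    sel <- tab$chain_id == ch
    ResidueProfile(ch, P[sel, , drop = FALSE], tab$confidence[sel])
  })
}

#' Write residue profiles to the tab-separated table format
#'
#' @param profiles a list of \linkS4class{ResidueProfile} (or a single one).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeProfileTable <- function(profiles, path) {
  if (is(profiles, "ResidueProfile")) profiles <- list(profiles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# chain_id\tresidue_index\tconfidence\t",
                    paste(AA_ALPHABET, collapse = "\t")), con)
  for (rp in profiles) {
    P <- probMatrix(rp)
    for (i in seq_len(nrow(P))) {
      writeLines(paste(c(chainId(rp), i,
                         sprintf("%.8g", confidences(rp)[i]),
                         sprintf("%.8g", P[i, ])), collapse = "\t"), con)
    }
  }
  invisible(path)
}
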