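#' Read a protein sequence database from FASTA
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' the remainder of the header is retained as a description in
#' \code{mcols(db)$desc}. Sequences are uppercased on read.
#'
#' @param path FASTA file.
#' @return an \code{AAStringSet} with unique names.
#' @export
readFastaDb <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stopf("duplicate sequence id(s): %s", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(raw) == 0L)) stopf("empty sequence in %s", path)
  db <- Biostrings::AAStringSet(toupper(as.character(raw)))
  names(db) <- ids
  S4Vectors::mcols(db)$desc <- desc
  db
}

#' Write a protein sequence database to FASTA
#'
#' @param db an \code{AAStringSet}; \code{mcols(db)$desc}, when present, is
#'   appended to each header after the id.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeFastaDb <- function(db, path) {
  ids <- names(db)
  desc <- S4Vectors::mcols(db)$desc
  hdr <- if (!is.null(desc)) {
    ifelse(nzchar(desc), paste(ids, desc), ids)
  } else ids
  seqs <- as.character(db)
  writeLines(paste0(">", hdr, "\n", seqs), path)
  invisible(path)
}
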