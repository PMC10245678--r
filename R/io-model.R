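#' Read an atomic model from PDB or mmCIF
#'
#' Chains and residues are kept in file order. The B-factor column of the
#' anchor atoms (CA for protein residues, P for nucleotides) is surfaced as
#' the per-residue score when all values lie in [0, 1]; otherwise scores are
#' left unset (NA).
#'
#' @param path file path.
#' @param format one of \code{"auto"} (by extension), \code{"pdb"},
#'   \code{"mmcif"}.
#' @return an \linkS4class{AtomicModel}.
#' @export
readModel <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  at <- if (format == "pdb") read_pdb_atoms(path) else read_mmcif_atoms(path)
  if (nrow(at) == 0L) stopf("empty model in %s", path)
  ## renumber residues 1..n per chain in file order
  key <- paste(at$chain, at$resno, sep = "\r")
  res_idx <- integer(nrow(at))
  for (ch in unique(at$chain)) {
    sel <- at$chain == ch
    res_idx[sel] <- cumsum(!duplicated(key[sel]))
  }
  atoms <- data.frame(chain = at$chain, res_idx = res_idx,
                      res_name = at$resid, seq_pos = NA_integer_,
                      atom = at$elety, x = at$x, y = at$y, z = at$z,
                      score = NA_real_, stringsAsFactors = FALSE)
  m <- AtomicModel(atoms)
  ## surface anchor-atom B-factors as scores when all are in [0,1]
  rt <- residueTable(m)
  idx <- match(paste(rt$chain, rt$res_idx, rt$anchor, sep = "\r"),
               paste(atoms$chain, atoms$res_idx, atoms$atom, sep = "\r"))
  miss <- is.na(idx)
  idx[miss] <- match(paste(rt$chain, rt$res_idx, sep = "\r")[miss],
                     paste(atoms$chain, atoms$res_idx, sep = "\r"))
  b <- at$b[idx]
  if (all(!is.na(b)) && all(b >= 0 & b <= 1)) {
    a2 <- m@atoms
    rkey <- paste(rt$chain, rt$res_idx, sep = "\r")
    a2$score <- b[match(paste(a2$chain, a2$res_idx, sep = "\r"), rkey)]
    m <- AtomicModel(a2)
  }
  m
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stopf("cannot parse PDB file %s: %s", path,
                              conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type %in% c("ATOM", "HETATM") & a$resid != "HOH", , drop = FALSE]
  a$chain[is.na(a$chain)] <- "A"
  data.frame(chain = as.character(a$chain), resno = a$resno,
             resid = as.character(a$resid), elety = as.character(a$elety),
             x = a$x, y = a$y, z = a$z, b = a$b, stringsAsFactors = FALSE)
}

## Minimal header-driven mmCIF atom_site loop parser.
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_i <- grep("^_atom_site\\.", lines)
  if (length(hdr_i) == 0L)
    stopf("cannot parse mmCIF file %s: no _atom_site loop", path)
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_i]))
  body_start <- max(hdr_i) + 1L
  rows <- list()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "_") || startsWith(ln, "loop_") ||
        startsWith(ln, "data_")) break
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) != length(cols))
      stopf("mmCIF parse error at line %d of %s: %d fields, expected %d",
            i, path, length(tok), length(cols))
    rows[[length(rows) + 1L]] <- tok
  }
  if (length(rows) == 0L) stopf("empty model in %s", path)
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- cols
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% cols) return(tab[[nm]])
    NULL
  }
  grp <- pick("group_PDB")
  keep <- if (is.null(grp)) rep(TRUE, nrow(tab)) else grp %in% c("ATOM", "HETATM")
  chain <- pick("auth_asym_id", "label_asym_id")
  resno <- pick("auth_seq_id", "label_seq_id")
  out <- data.frame(chain = chain, resno = as.integer(resno),
                    resid = pick("label_comp_id", "auth_comp_id"),
                    elety = pick("label_atom_id", "auth_atom_id"),
                    x = as.numeric(pick("Cartn_x")),
                    y = as.numeric(pick("Cartn_y")),
                    z = as.numeric(pick("Cartn_z")),
                    b = as.numeric(pick("B_iso_or_equiv")),
                    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Write an atomic model to PDB or mmCIF
#'
#' The per-residue score is written into the B-factor column of every atom
#' of that residue (2 decimals in PDB); residues with unset scores get 0.00.
#'
#' @param model an \linkS4class{AtomicModel}.
#' @param path output file path.
#' @param format \code{"pdb"}, \code{"mmcif"}, or \code{"auto"}
#'   (by extension).
#' @return invisibly, \code{path}.
#' @export
writeModel <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  a <- model@atoms
  if (nrow(a) == 0L) stopf("refusing to write an empty model")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  b <- ifelse(is.na(a$score), 0, a$score)
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$res_idx, chain = a$chain, resid = a$res_name,
                     elety = a$atom, eleno = seq_len(nrow(a)),
                     o = rep(1, nrow(a)), b = b)
  } else {
    write_mmcif(a, b, path)
  }
  invisible(path)
}

write_mmcif <- function(a, b, path) {
  hdr <- c("data_model", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
                    "pdbx_PDB_model_num")))
  elem <- substr(gsub("[^A-Za-z]", "", a$atom), 1, 1)
  body <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.4f %d %s 1",
    seq_len(nrow(a)), elem, a$atom, a$res_name, a$chain, a$res_idx,
    a$x, a$y, a$z, b, a$res_idx, a$chain)
  writeLines(c(hdr, body, "#"), path)
}
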