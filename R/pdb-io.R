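# Fixed-column PDB reader/writer covering the record types this package
# needs: CRYST1, REMARK 290 SMTRY (symmetry operators), ATOM/HETATM, LINK.
# Hydrogens are kept on read; downstream geometry/density code ignores them.

substr_trim <- function(x, i, j) trimws(substr(x, i, j))

read_pdb_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cell <- c(1, 1, 1, 90, 90, 90)
  resolution <- NA_real_
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) >= 1) {
    cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                         substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                         substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
    if (any(is.na(cell))) stop("unparseable CRYST1 record: ", cr[1])
  }
  rr <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(rr) >= 1) {
    v <- suppressWarnings(as.numeric(substr_trim(rr[1], 24, 30)))
    if (!is.na(v)) resolution <- v
  }
  sym_ops <- parse_smtry(grep("^REMARK 290   SMTRY", lines, value = TRUE))

  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  atoms <- if (length(at) == 0L) empty_atoms() else {
    xs <- suppressWarnings(as.numeric(substr(at, 31, 38)))
    ys <- suppressWarnings(as.numeric(substr(at, 39, 46)))
    zs <- suppressWarnings(as.numeric(substr(at, 47, 54)))
    if (any(is.na(xs) | is.na(ys) | is.na(zs)))
      stop("unparseable coordinates at line(s): ",
           paste(which(is.na(xs) | is.na(ys) | is.na(zs))[1], collapse = ", "))
    occ <- suppressWarnings(as.numeric(substr(at, 55, 60)))
    bfac <- suppressWarnings(as.numeric(substr(at, 61, 66)))
    el <- substr_trim(at, 77, 78)
    nm <- substr_trim(at, 13, 16)
    data.frame(
      chain = substr_trim(at, 22, 22),
      seq = as.integer(substr_trim(at, 23, 26)),
      ins = substr_trim(at, 27, 27),
      comp = substr_trim(at, 18, 20),
      name = nm,
      element = ifelse(el == "", guess_element(nm), el),
      x = xs, y = ys, z = zs,
      occ = ifelse(is.na(occ), 1, occ),
      b = ifelse(is.na(bfac), 0, bfac),
      altloc = substr_trim(at, 17, 17),
      het = substr(at, 1, 6) == "HETATM",
      stringsAsFactors = FALSE)
  }

  lk <- grep("^LINK", lines, value = TRUE)
  links <- if (length(lk) == 0L) empty_links() else {
    d <- suppressWarnings(as.numeric(substr(lk, 74, 78)))
    data.frame(
      chain1 = substr_trim(lk, 22, 22), seq1 = as.integer(substr_trim(lk, 23, 26)),
      ins1 = substr_trim(lk, 27, 27), atom1 = substr_trim(lk, 13, 16),
      chain2 = substr_trim(lk, 52, 52), seq2 = as.integer(substr_trim(lk, 53, 56)),
      ins2 = substr_trim(lk, 57, 57), atom2 = substr_trim(lk, 43, 46),
      dist = d, stringsAsFactors = FALSE)
  }
  glyco_model(atoms, links, cell, sym_ops, resolution)
}

parse_smtry <- function(lines) {
  if (length(lines) == 0L) return(list())
  opno <- as.integer(substr_trim(lines, 21, 23))
  rowno <- as.integer(substr(lines, 19, 19))
  ops <- list()
  for (k in sort(unique(opno))) {
    sel <- lines[opno == k][order(rowno[opno == k])]
    if (length(sel) != 3L) next
    vals <- t(vapply(sel, function(l)
      as.numeric(c(substr(l, 24, 33), substr(l, 34, 43),
                   substr(l, 44, 53), substr(l, 54, 68))), numeric(4)))
    ops[[length(ops) + 1L]] <- list(R = unname(vals[, 1:3]), t = unname(vals[, 4]))
  }
  ops
}

fmt_atom_name <- function(name, element) {
  # single-letter elements start in column 14 unless the name is 4 chars
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 2) sprintf("%-4s", name) else sprintf(" %-3s", name)
}

write_pdb_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cl <- model$cell
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     cl[1], cl[2], cl[3], cl[4], cl[5], cl[6]), con)
  if (!is.na(model$resolution))
    writeLines(sprintf("REMARK   2 RESOLUTION.    %5.2f ANGSTROMS.",
                       model$resolution), con)
  for (k in seq_along(model$sym_ops)) {
    op <- model$sym_ops[[k]]
    for (r in 1:3) {
      writeLines(sprintf("REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
                         r, k, op$R[r, 1], op$R[r, 2], op$R[r, 3], op$t[r]), con)
    }
  }
  lk <- model$links
  for (i in seq_len(nrow(lk))) {
    writeLines(sprintf("LINK        %-4s %3s %1s%4d%1s               %-4s %3s %1s%4d%1s  1555   1555 %5.2f",
                       lk$atom1[i], comp_of(model, lk$chain1[i], lk$seq1[i], lk$ins1[i]),
                       lk$chain1[i], lk$seq1[i], blank1(lk$ins1[i]),
                       lk$atom2[i], comp_of(model, lk$chain2[i], lk$seq2[i], lk$ins2[i]),
                       lk$chain2[i], lk$seq2[i], blank1(lk$ins2[i]),
                       ifelse(is.na(lk$dist[i]), 0, lk$dist[i])), con)
  }
  a <- model$atoms
  for (i in seq_len(nrow(a))) {
    writeLines(sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       ifelse(a$het[i], "HETATM", "ATOM"),
                       (i - 1L) %% 99999L + 1L,
                       fmt_atom_name(a$name[i], a$element[i]),
                       blank1(a$altloc[i]), a$comp[i], a$chain[i], a$seq[i],
                       blank1(a$ins[i]), a$x[i], a$y[i], a$z[i],
                       a$occ[i], a$b[i], toupper(a$element[i])), con)
  }
  writeLines("END", con)
  invisible(NULL)
}

blank1 <- function(x) ifelse(is.na(x) | x == "", " ", substr(x, 1, 1))

comp_of <- function(model, chain, seq, ins) {
  cp <- residue_comp(model, res_key(chain, seq, ins))
  if (is.na(cp)) "UNK" else cp
}
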