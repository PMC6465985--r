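# Minimal but conforming mmCIF reader/writer for the categories this
# package round-trips: _cell, _symmetry / _space_group_symop, _atom_site,
# _struct_conn (covalent entries) and _reflns.d_resolution_high.

cif_tokenize <- function(lines) {
  toks <- character()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, ";")) {           # multi-line value
      buf <- substring(ln, 2)
      i <- i + 1L
      while (i <= n && !startsWith(lines[i], ";")) {
        buf <- paste0(buf, "\n", lines[i]); i <- i + 1L
      }
      toks <- c(toks, buf)
      i <- i + 1L
      next
    }
    ln <- sub("^\\s+", "", ln)
    if (ln == "" || startsWith(ln, "#")) { i <- i + 1L; next }
    while (nchar(ln) > 0) {
      if (startsWith(ln, "#")) break
      ch <- substr(ln, 1, 1)
      if (ch == "'" || ch == "\"") {
        m <- regexpr(paste0(ch, "(\\s|$)"), substring(ln, 2))
        if (m == -1) { toks <- c(toks, substring(ln, 2)); ln <- "" }
        else {
          toks <- c(toks, substr(ln, 2, m))
          ln <- sub("^\\s+", "", substring(ln, m + 2))
        }
      } else {
        m <- regexpr("\\s", ln)
        if (m == -1) { toks <- c(toks, ln); ln <- "" }
        else { toks <- c(toks, substr(ln, 1, m - 1)); ln <- sub("^\\s+", "", substring(ln, m)) }
      }
    }
    i <- i + 1L
  }
  toks
}

# Parse tokens into: items (name -> value) and loops (list of data.frames).
cif_parse <- function(lines) {
  toks <- cif_tokenize(lines)
  items <- list(); loops <- list()
  i <- 1L; n <- length(toks)
  while (i <= n) {
    tk <- toks[i]
    if (grepl("^data_", tk, ignore.case = TRUE)) { i <- i + 1L; next }
    if (tolower(tk) == "loop_") {
      i <- i + 1L
      hdr <- character()
      while (i <= n && startsWith(toks[i], "_")) { hdr <- c(hdr, toks[i]); i <- i + 1L }
      vals <- character()
      while (i <= n && !startsWith(toks[i], "_") &&
             tolower(toks[i]) != "loop_" &&
             !grepl("^data_", toks[i], ignore.case = TRUE)) {
        vals <- c(vals, toks[i]); i <- i + 1L
      }
      if (length(hdr) > 0 && length(vals) %% length(hdr) == 0 && length(vals) > 0) {
        m <- matrix(vals, ncol = length(hdr), byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- tolower(hdr)
        loops[[length(loops) + 1L]] <- df
      }
      next
    }
    if (startsWith(tk, "_") && i + 1L <= n) {
      items[[tolower(tk)]] <- toks[i + 1L]
      i <- i + 2L
      next
    }
    i <- i + 1L
  }
  list(items = items, loops = loops)
}

cif_find_loop <- function(parsed, prefix) {
  for (df in parsed$loops) {
    if (any(startsWith(names(df), tolower(prefix)))) return(df)
  }
  NULL
}

cif_num <- function(x) suppressWarnings(as.numeric(gsub("\\(.*\\)", "", x)))

cif_item <- function(parsed, name, default = NA) {
  v <- parsed$items[[tolower(name)]]
  if (is.null(v) || v %in% c(".", "?")) default else v
}

read_mmcif_model <- function(path) {
  parsed <- cif_parse(readLines(path, warn = FALSE))
  cell <- c(cif_num(cif_item(parsed, "_cell.length_a", 1)),
            cif_num(cif_item(parsed, "_cell.length_b", 1)),
            cif_num(cif_item(parsed, "_cell.length_c", 1)),
            cif_num(cif_item(parsed, "_cell.angle_alpha", 90)),
            cif_num(cif_item(parsed, "_cell.angle_beta", 90)),
            cif_num(cif_item(parsed, "_cell.angle_gamma", 90)))
  resolution <- cif_num(cif_item(parsed, "_reflns.d_resolution_high", NA))

  sym_ops <- list()
  sl <- cif_find_loop(parsed, "_space_group_symop")
  if (is.null(sl)) sl <- cif_find_loop(parsed, "_symmetry_equiv")
  if (!is.null(sl)) {
    col <- intersect(c("_space_group_symop.operation_xyz",
                       "_symmetry_equiv.pos_as_xyz"), names(sl))
    if (length(col) >= 1) sym_ops <- lapply(sl[[col[1]]], parse_symop_xyz)
  } else {
    one <- cif_item(parsed, "_symmetry_equiv.pos_as_xyz", NA)
    if (!is.na(one)) sym_ops <- list(parse_symop_xyz(one))
  }

  as_df <- cif_find_loop(parsed, "_atom_site.")
  atoms <- empty_atoms()
  if (!is.null(as_df)) {
    g <- function(nm, def = "") {
      v <- as_df[[paste0("_atom_site.", nm)]]
      if (is.null(v)) rep(def, nrow(as_df)) else ifelse(v %in% c(".", "?"), def, v)
    }
    nm <- g("auth_atom_id", NA); if (all(is.na(nm))) nm <- g("label_atom_id")
    comp <- g("auth_comp_id", NA); if (all(is.na(comp))) comp <- g("label_comp_id")
    ch <- g("auth_asym_id", NA); if (all(is.na(ch))) ch <- g("label_asym_id")
    sq <- g("auth_seq_id", NA); if (all(is.na(sq))) sq <- g("label_seq_id")
    el <- g("type_symbol")
    atoms <- data.frame(
      chain = ch, seq = as.integer(sq), ins = g("pdbx_pdb_ins_code"),
      comp = comp, name = nm,
      element = ifelse(el == "", guess_element(nm), el),
      x = cif_num(g("cartn_x", "0")), y = cif_num(g("cartn_y", "0")),
      z = cif_num(g("cartn_z", "0")),
      occ = ifelse(is.na(cif_num(g("occupancy", "1"))), 1, cif_num(g("occupancy", "1"))),
      b = ifelse(is.na(cif_num(g("b_iso_or_equiv", "0"))), 0, cif_num(g("b_iso_or_equiv", "0"))),
      altloc = g("label_alt_id"),
      het = g("group_pdb", "HETATM") == "HETATM",
      stringsAsFactors = FALSE)
    if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z)))
      stop("unparseable _atom_site coordinates in ", path)
  }

  links <- empty_links()
  sc <- cif_find_loop(parsed, "_struct_conn.")
  if (!is.null(sc)) {
    g2 <- function(nm, def = "") {
      v <- sc[[paste0("_struct_conn.", nm)]]
      if (is.null(v)) rep(def, nrow(sc)) else ifelse(v %in% c(".", "?"), def, v)
    }
    keep <- tolower(g2("conn_type_id", "covale")) %in% c("covale", "metalc", "link")
    if (any(keep)) {
      links <- data.frame(
        chain1 = g2("ptnr1_auth_asym_id")[keep],
        seq1 = as.integer(g2("ptnr1_auth_seq_id")[keep]),
        ins1 = g2("pdbx_ptnr1_pdb_ins_code")[keep],
        atom1 = g2("ptnr1_label_atom_id")[keep],
        chain2 = g2("ptnr2_auth_asym_id")[keep],
        seq2 = as.integer(g2("ptnr2_auth_seq_id")[keep]),
        ins2 = g2("pdbx_ptnr2_pdb_ins_code")[keep],
        atom2 = g2("ptnr2_label_atom_id")[keep],
        dist = cif_num(g2("pdbx_dist_value", NA)[keep]),
        stringsAsFactors = FALSE)
    }
  }
  glyco_model(atoms, links, cell, sym_ops, resolution)
}

# "x,y,z"-style operator strings -> list(R, t) in fractional space.
parse_symop_xyz <- function(s) {
  parts <- strsplit(tolower(gsub(" ", "", s)), ",")[[1]]
  if (length(parts) != 3) stop("bad symmetry operator: ", s)
  R <- matrix(0, 3, 3); tv <- numeric(3)
  for (r in 1:3) {
    expr <- parts[r]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (grepl("[xyz]", body)) {
        ax <- match(regmatches(body, regexpr("[xyz]", body)), c("x", "y", "z"))
        coef <- sub("\\*?[xyz]", "", body)
        cv <- if (coef == "") 1 else eval_frac(coef)
        R[r, ax] <- R[r, ax] + sign * cv
      } else {
        tv[r] <- tv[r] + sign * eval_frac(body)
      }
    }
  }
  list(R = R, t = tv)
}

eval_frac <- function(s) {
  if (grepl("/", s)) {
    p <- as.numeric(strsplit(s, "/")[[1]])
    p[1] / p[2]
  } else as.numeric(s)
}

symop_to_xyz <- function(op) {
  axes <- c("X", "Y", "Z")
  out <- character(3)
  for (r in 1:3) {
    terms <- character()
    for (cx in 1:3) {
      v <- op$R[r, cx]
      if (abs(v) < 1e-9) next
      co <- if (abs(abs(v) - 1) < 1e-9) "" else sub("0+$", "", sprintf("%g*", abs(v)))
      terms <- c(terms, paste0(if (v < 0) "-" else if (length(terms)) "+" else "",
                               co, axes[cx]))
    }
    tv <- op$t[r]
    if (abs(tv) > 1e-9) {
      fr <- frac_string(tv)
      terms <- c(terms, paste0(if (tv < 0) "-" else "+", fr))
    }
    out[r] <- paste(terms, collapse = "")
  }
  paste(out, collapse = ",")
}

frac_string <- function(v) {
  av <- abs(v)
  for (den in c(2, 3, 4, 6)) {
    num <- av * den
    if (abs(num - round(num)) < 1e-6) return(sprintf("%d/%d", as.integer(round(num)), den))
  }
  sprintf("%g", av)
}

write_mmcif_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_recarb")
  w("#")
  cl <- model$cell
  w("_cell.length_a    %.4f", cl[1]); w("_cell.length_b    %.4f", cl[2])
  w("_cell.length_c    %.4f", cl[3]); w("_cell.angle_alpha %.4f", cl[4])
  w("_cell.angle_beta  %.4f", cl[5]); w("_cell.angle_gamma %.4f", cl[6])
  if (!is.na(model$resolution)) w("_reflns.d_resolution_high %.3f", model$resolution)
  w("#")
  w("loop_")
  w("_space_group_symop.id")
  w("_space_group_symop.operation_xyz")
  for (k in seq_along(model$sym_ops))
    w("%d '%s'", k, symop_to_xyz(model$sym_ops[[k]]))
  lk <- model$links
  if (nrow(lk) > 0) {
    w("#")
    w("loop_")
    for (f in c("id", "conn_type_id", "ptnr1_auth_asym_id", "ptnr1_auth_seq_id",
                "pdbx_ptnr1_pdb_ins_code", "ptnr1_label_atom_id",
                "ptnr2_auth_asym_id", "ptnr2_auth_seq_id",
                "pdbx_ptnr2_pdb_ins_code", "ptnr2_label_atom_id",
                "pdbx_dist_value"))
      w("_struct_conn.%s", f)
    for (i in seq_len(nrow(lk)))
      w("link%d covale %s %d %s %s %s %d %s %s %s", i,
        lk$chain1[i], lk$seq1[i], dotify(lk$ins1[i]), lk$atom1[i],
        lk$chain2[i], lk$seq2[i], dotify(lk$ins2[i]), lk$atom2[i],
        if (is.na(lk$dist[i])) "." else sprintf("%.3f", lk$dist[i]))
  }
  w("#")
  w("loop_")
  for (f in c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
              "label_comp_id", "label_asym_id", "label_seq_id",
              "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
              "occupancy", "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
              "auth_asym_id", "auth_atom_id"))
    w("_atom_site.%s", f)
  a <- model$atoms
  for (i in seq_len(nrow(a)))
    w("%-6s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s",
      ifelse(a$het[i], "HETATM", "ATOM"), i, toupper(a$element[i]),
      cifq(a$name[i]), dotify(a$altloc[i]), a$comp[i], a$chain[i], a$seq[i],
      dotify(a$ins[i]), a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i],
      a$seq[i], a$comp[i], a$chain[i], cifq(a$name[i]))
  w("#")
  invisible(NULL)
}

dotify <- function(x) ifelse(is.na(x) | x == "", ".", x)

cifq <- function(x) ifelse(grepl("'", x), sprintf("\"%s\"", x), x)

#' Read a structure model
#'
#' Loads coordinates, covalent-link records, cell parameters and symmetry
#' operators from a PDB or mmCIF file. Missing symmetry information yields
#' the identity operator only.
#'
#' @param path file to read
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension)
#' @return a [glyco_model]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  switch(format, pdb = read_pdb_model(path), mmcif = read_mmcif_model(path))
}

#' Write a structure model
#'
#' Emits a model such that [read_structure()] on the output reproduces the
#' residues, links and cell. Refuses to write a model with duplicated
#' (chain, seq, ins) residue identifiers.
#'
#' @param model a [glyco_model]
#' @param path output file
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension)
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  rs <- model_residues(model)   # one row per contiguous residue block
  dup <- duplicated(rs$key)
  if (any(dup))
    stop("duplicated residue identifiers, refusing to write: ",
         paste(unique(rs$key[dup]), collapse = ", "))
  switch(format,
         pdb = write_pdb_model(model, path),
         mmcif = write_mmcif_model(model, path))
  invisible(NULL)
}
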