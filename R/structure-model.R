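#' @title Crystallographic structure container
#'
#' @description A `glyco_model` is the universe every operation in this
#' package acts on: an ordered atom table, a covalent-link table, unit-cell
#' parameters, fractional-space symmetry operators and (optionally) the data
#' resolution. Residues are identified by the author triple
#' (chain, seq, ins); atoms by their PDB atom name within a residue.
#'
#' @details The atom table has columns `chain`, `seq` (integer author
#' numbering), `ins` (insertion code, "" if none), `comp` (3-letter component
#' code), `name` (atom name), `element`, `x`, `y`, `z` (Angstrom), `occ`,
#' `b` (isotropic B factor, Angstrom^2), `altloc` and `het` (logical,
#' HETATM). The link table has columns `chain1`, `seq1`, `ins1`, `atom1`,
#' `chain2`, `seq2`, `ins2`, `atom2`, `dist`.
#'
#' @param atoms atom data.frame as described above
#' @param links link data.frame (zero rows allowed)
#' @param cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees)
#' @param sym_ops list of symmetry operators, each `list(R = 3x3, t = len-3)`
#'   acting on fractional coordinates; the identity is always ensured
#' @param resolution d_min in Angstrom or `NA`
#' @param flat_b single overall B value if the deposited model used a flat
#'   B-factor parameterisation, else `NULL`
#' @return an object of class `glyco_model`
#' @export
glyco_model <- function(atoms, links = empty_links(), cell = c(1, 1, 1, 90, 90, 90),
                        sym_ops = list(), resolution = NA_real_, flat_b = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("chain", "seq", "ins", "comp", "name", "element",
              "x", "y", "z", "occ", "b", "altloc", "het")
  for (cc in setdiff(needed, names(atoms))) {
    atoms[[cc]] <- switch(cc,
      ins = "", altloc = "", het = TRUE, occ = 1, b = 30,
      element = guess_element(atoms$name),
      stop("atom table lacks column ", cc))
  }
  atoms <- atoms[, needed]
  atoms$seq <- as.integer(atoms$seq)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  stopifnot(all(atoms$b >= 0), all(atoms$occ >= 0 & atoms$occ <= 1))
  stopifnot(length(cell) == 6, all(cell[1:3] > 0),
            all(cell[4:6] > 0 & cell[4:6] < 180))
  m <- structure(list(
    atoms = atoms,
    links = normalize_links(links),
    cell = as.numeric(cell),
    sym_ops = ensure_identity_op(sym_ops),
    resolution = resolution,
    flat_b = flat_b
  ), class = "glyco_model")
  m
}

empty_atoms <- function() {
  data.frame(chain = character(), seq = integer(), ins = character(),
             comp = character(), name = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), altloc = character(),
             het = logical(), stringsAsFactors = FALSE)
}

empty_links <- function() {
  data.frame(chain1 = character(), seq1 = integer(), ins1 = character(),
             atom1 = character(), chain2 = character(), seq2 = integer(),
             ins2 = character(), atom2 = character(), dist = numeric(),
             stringsAsFactors = FALSE)
}

normalize_links <- function(links) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links) == 0L) return(empty_links())
  tmpl <- empty_links()
  for (cc in names(tmpl)) {
    if (is.null(links[[cc]])) links[[cc]] <- if (cc == "dist") NA_real_ else ""
  }
  links <- links[, names(tmpl)]
  links$seq1 <- as.integer(links$seq1)
  links$seq2 <- as.integer(links$seq2)
  links
}

identity_op <- function() list(R = diag(3), t = c(0, 0, 0))

is_identity_op <- function(op) {
  max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t %% 1)) < 1e-9
}

ensure_identity_op <- function(ops) {
  if (length(ops) == 0L || !any(vapply(ops, is_identity_op, logical(1)))) {
    ops <- c(list(identity_op()), ops)
  }
  ops
}

#' @export
print.glyco_model <- function(x, ...) {
  cat(sprintf("glyco_model: %d atoms, %d residues, %d links\n",
              nrow(x$atoms), length(unique(res_key_of(x$atoms))), nrow(x$links)))
  cat(sprintf("  cell: %.2f %.2f %.2f  %.1f %.1f %.1f  (%d sym ops)\n",
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6],
              length(x$sym_ops)))
  if (!is.na(x$resolution)) cat(sprintf("  resolution: %.2f A\n", x$resolution))
  invisible(x)
}

# ---- residue addressing -----------------------------------------------------

res_key <- function(chain, seq, ins = "") paste(chain, seq, ins, sep = "|")

res_key_of <- function(atoms) res_key(atoms$chain, atoms$seq, atoms$ins)

split_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  lapply(parts, function(p) list(chain = p[1], seq = as.integer(p[2]),
                                 ins = if (length(p) >= 3) p[3] else ""))
}

#' Per-residue summary of a model
#'
#' @param model a `glyco_model`
#' @return data.frame with one row per residue: `key`, `chain`, `seq`, `ins`,
#'   `comp`, `natoms`, in file order
#' @export
model_residues <- function(model) {
  a <- model$atoms
  if (nrow(a) == 0L)
    return(data.frame(key = character(), chain = character(), seq = integer(),
                      ins = character(), comp = character(), natoms = integer(),
                      stringsAsFactors = FALSE))
  key <- res_key_of(a)
  runs <- rle(key)
  first <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  data.frame(key = runs$values, chain = a$chain[first], seq = a$seq[first],
             ins = a$ins[first], comp = a$comp[first],
             natoms = runs$lengths, stringsAsFactors = FALSE)
}

residue_atoms <- function(model, key) {
  model$atoms[res_key_of(model$atoms) == key, , drop = FALSE]
}

residue_comp <- function(model, key) {
  a <- residue_atoms(model, key)
  if (nrow(a) == 0L) NA_character_ else a$comp[1]
}

# Highest-occupancy conformer per atom name within each residue; ties keep
# the first in file order. All geometry and density code goes through this.
dominant_atoms <- function(atoms) {
  if (nrow(atoms) == 0L) return(atoms)
  pos <- seq_len(nrow(atoms))
  id <- paste(res_key_of(atoms), atoms$name)
  ord <- order(id, -atoms$occ, pos)
  keep <- pos[ord][!duplicated(id[ord])]
  atoms[sort(keep), , drop = FALSE]
}

# Non-hydrogen dominant atoms of one residue.
heavy_atoms <- function(atoms) {
  atoms <- dominant_atoms(atoms)
  atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
}

atom_xyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

get_atom <- function(model, key, name) {
  a <- residue_atoms(model, key)
  a <- a[a$name == name, , drop = FALSE]
  if (nrow(a) == 0L) return(NULL)
  a <- a[order(-a$occ), , drop = FALSE]
  c(a$x[1], a$y[1], a$z[1])
}

guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "NA", "CL", "BR", "CA"),
         two, one)
}

# ---- cell algebra -----------------------------------------------------------

# Orthogonalisation matrix (PDB convention: a along x, b in the xy plane);
# columns transform fractional -> Cartesian.
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), c_ * cos(be),
    0, b * sin(ga), c_ * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, c_ * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

frac_matrix <- function(cell) solve(orth_matrix(cell))

cart_to_frac <- function(xyz, cell) t(frac_matrix(cell) %*% t(xyz))

frac_to_cart <- function(frac, cell) t(orth_matrix(cell) %*% t(frac))

# ---- symmetry-aware minimum distance ---------------------------------------

#' Minimum symmetry-expanded distance between two atom sets
#'
#' Minimum over all symmetry operators and lattice translations in
#' \{-1,0,1\}^3 of the pairwise Cartesian distances between `probe` atoms and
#' transformed `target` atoms. Pairs of the *same* atom under the pure
#' identity (no rotation, no translation) are excluded so a set can be
#' checked against a superset of itself.
#'
#' @param model a `glyco_model` providing cell and symmetry operators
#' @param probe,target atom data.frames (subsets of `model$atoms` or
#'   compatible tables)
#' @param exclude_identity if `TRUE`, skip the untranslated identity operator
#'   entirely: only genuine symmetry images are considered
#' @return `list(dist =, probe_idx =, target_idx =, op =, shift =)`; `dist`
#'   is `Inf` with a warning-free undefined marker if either set is empty
#' @export
min_symmetry_distance <- function(model, probe, target, exclude_identity = FALSE) {
  undef <- list(dist = Inf, probe_idx = NA_integer_, target_idx = NA_integer_,
                op = NA_integer_, shift = c(NA, NA, NA), defined = FALSE)
  if (is.null(probe) || is.null(target) || nrow(probe) == 0L || nrow(target) == 0L)
    return(undef)
  Om <- orth_matrix(model$cell)
  pxyz <- atom_xyz(probe)
  tfrac <- cart_to_frac(atom_xyz(target), model$cell)
  pid <- paste(res_key_of(probe), probe$name, probe$altloc)
  tid <- paste(res_key_of(target), target$name, target$altloc)
  same <- outer(pid, tid, "==")
  shifts <- as.matrix(expand.grid(u = -1:1, v = -1:1, w = -1:1))
  best <- undef
  for (k in seq_along(model$sym_ops)) {
    op <- model$sym_ops[[k]]
    ident <- is_identity_op(op)
    base <- t(op$R %*% t(tfrac)) + matrix(op$t, nrow(tfrac), 3, byrow = TRUE)
    for (s in seq_len(nrow(shifts))) {
      sh <- shifts[s, ]
      pure_identity <- ident && all(sh == 0)
      if (exclude_identity && pure_identity) next
      txyz <- t(Om %*% t(base + matrix(sh, nrow(tfrac), 3, byrow = TRUE)))
      d2 <- cross_dist2(pxyz, txyz)
      if (pure_identity) d2[same] <- Inf
      mn <- suppressWarnings(min(d2))
      if (is.finite(mn) && sqrt(mn) < best$dist) {
        w <- which(d2 == mn, arr.ind = TRUE)[1, ]
        best <- list(dist = sqrt(mn), probe_idx = unname(w[1]),
                     target_idx = unname(w[2]), op = k,
                     shift = unname(sh), defined = TRUE)
      }
    }
  }
  best
}
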