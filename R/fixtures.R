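#' @title Synthetic glycosite fixtures
#'
#' @description Generates ground-truth glycoprotein fragments, observed
#' density maps synthesized from them, and degraded working models, so that
#' every stage of the curation pipeline can be exercised without
#' experimental data. The peptide scaffold uses ideal backbone geometry
#' (fixed phi/psi, extended strand); the noise model is white Gaussian on
#' the map grid. Both idealizations are adequate for density and sequon
#' logic and claim no Ramachandran or crystallographic-noise realism.
#' @name fixtures
NULL

BACKBONE_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                      ang_n_ca_c = 111, ang_ca_c_n = 117, ang_c_n_ca = 121,
                      phi = -140, psi = 135, omega = 180)

# Ideal extended peptide; returns an atom data.frame. Side chains: CB for
# all non-Gly, full amide for Asn, OG1/CG2 for Thr, OG for Ser.
build_peptide <- function(sequence = c("GLY", "ALA", "ASN", "ALA", "THR", "ALA"),
                          chain = "A", seq_start = 21L) {
  g <- BACKBONE_GEOM
  atoms <- list()
  push <- function(resno, comp, name, el, p)
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain, seq = resno, ins = "", comp = comp, name = name,
      element = el, x = p[1], y = p[2], z = p[3], occ = 1, b = 20,
      altloc = "", het = FALSE, stringsAsFactors = FALSE)
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, g$ca_c, g$ang_n_ca_c, 55)
  prev <- NULL
  for (i in seq_along(sequence)) {
    comp <- sequence[i]
    resno <- seq_start + i - 1L
    if (i > 1) {
      N <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, g$psi)
      CA <- place_atom(prev$CA, prev$C, N, g$n_ca, g$ang_c_n_ca, g$omega)
      C <- place_atom(prev$C, N, CA, g$ca_c, g$ang_n_ca_c, g$phi)
    }
    O <- place_atom(N, CA, C, g$c_o, 121, g$psi + 180)
    push(resno, comp, "N", "N", N)
    push(resno, comp, "CA", "C", CA)
    push(resno, comp, "C", "C", C)
    push(resno, comp, "O", "O", O)
    if (comp != "GLY") {
      CB <- place_atom(C, N, CA, 1.53, 110.5, -122.5)
      push(resno, comp, "CB", "C", CB)
      if (comp == "ASN") {
        CG <- place_atom(N, CA, CB, 1.52, 113, -65)
        OD1 <- place_atom(CA, CB, CG, 1.23, 121, -60)
        ND2 <- place_atom(CA, CB, CG, 1.33, 117, 120)
        push(resno, comp, "CG", "C", CG)
        push(resno, comp, "OD1", "O", OD1)
        push(resno, comp, "ND2", "N", ND2)
      } else if (comp == "THR") {
        push(resno, comp, "OG1", "O", place_atom(N, CA, CB, 1.43, 109, 60))
        push(resno, comp, "CG2", "C", place_atom(N, CA, CB, 1.52, 111, 180))
      } else if (comp == "SER") {
        push(resno, comp, "OG", "O", place_atom(N, CA, CB, 1.43, 110, 60))
      }
    }
    prev <- list(N = N, CA = CA, C = C)
  }
  do.call(rbind, atoms)
}

# Grow an ideal glycan tree of `n_residues` at `asn_key` using the grammar's
# breadth-first order and the ideal torsion of each linkage; no map is
# consulted. Returns list(model, keys, edges).
build_ideal_tree <- function(model, asn_key, typedef, n_residues,
                             templates = sugar_templates()) {
  chain <- split_key(asn_key)[[1]]$chain
  depth <- stats::setNames(0L, asn_key)
  comp_map <- character()
  keys <- character()
  edges <- data.frame(parent = character(), child = character(),
                      parent_atom = character(), child_atom = character(),
                      position = integer(), anomer = character(),
                      stringsAsFactors = FALSE)
  queue <- asn_key
  fucose_q <- list()
  while ((length(queue) > 0 || length(fucose_q) > 0) && length(keys) < n_residues) {
    if (length(queue) == 0) {
      item <- fucose_q[[1]]; fucose_q <- fucose_q[-1]
      pkey <- item$pkey; prow <- item$prow
      res <- try_ideal_place(model, pkey, prow, templates)
      if (is.null(res)) next
      model <- res$model; ck <- res$key
      depth[ck] <- depth[[pkey]] + 1L; comp_map[ck] <- prow$child
      keys <- c(keys, ck); edges <- rbind(edges, res$edge)
      next
    }
    pkey <- queue[1]; queue <- queue[-1]
    pcomp <- if (depth[[pkey]] == 0L) "ASN" else unname(comp_map[pkey])
    prods <- open_productions(typedef, pcomp, depth[[pkey]])
    for (i in seq_len(nrow(prods))) {
      if (length(keys) >= n_residues) break
      prow <- prods[i, , drop = FALSE]
      if (prow$class == "fucose") {
        fucose_q[[length(fucose_q) + 1L]] <- list(pkey = pkey, prow = prow)
        next
      }
      res <- try_ideal_place(model, pkey, prow, templates)
      if (is.null(res)) next
      model <- res$model; ck <- res$key
      depth[ck] <- depth[[pkey]] + 1L; comp_map[ck] <- prow$child
      keys <- c(keys, ck); edges <- rbind(edges, res$edge)
      queue <- c(queue, ck)
    }
  }
  list(model = model, keys = keys, edges = edges)
}

try_ideal_place <- function(model, pkey, prow, templates) {
  tor <- LINKAGE_TORSIONS[[as.character(prow$position)]]$ideal
  at <- place_template(model, pkey, prow$position, prow$child,
                       tor[1], tor[2], templates)
  if (is.null(at)) return(NULL)
  att_name <- ATTACH_TABLE[[as.character(prow$position)]]$oxy
  other <- model$atoms[!(res_key_of(model$atoms) == pkey &
                           model$atoms$name == att_name), , drop = FALSE]
  if (nrow(other) > 0 &&
      min_cross_dist(as.matrix(at[, c("x", "y", "z")]), atom_xyz(other)) < 2.1)
    return(NULL)
  chain <- split_key(pkey)[[1]]$chain
  seqno <- next_free_seq(model, chain)
  newat <- data.frame(chain = chain, seq = seqno, ins = "", comp = prow$child,
                      name = at$name, element = at$element,
                      x = at$x, y = at$y, z = at$z, occ = 1, b = 25,
                      altloc = "", het = TRUE, stringsAsFactors = FALSE)
  model$atoms <- rbind(model$atoms, newat)
  ck <- res_key(chain, seqno, "")
  patom <- ATTACH_TABLE[[as.character(prow$position)]]$oxy
  pp <- split_key(pkey)[[1]]
  d <- vnorm(get_atom(model, pkey, patom) - get_atom(model, ck, "C1"))
  edge <- data.frame(parent = pkey, child = ck, parent_atom = patom,
                     child_atom = "C1", position = prow$position,
                     anomer = prow$anomer, stringsAsFactors = FALSE)
  model$links <- rbind(model$links, data.frame(
    chain1 = pp$chain, seq1 = pp$seq, ins1 = pp$ins, atom1 = patom,
    chain2 = chain, seq2 = seqno, ins2 = "", atom2 = "C1", dist = d,
    stringsAsFactors = FALSE))
  list(model = model, key = ck, edge = edge)
}

# Center atoms in an orthogonal P1 box with `pad` Angstrom of margin.
box_model <- function(atoms, links, pad = 8, resolution = NA) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  size <- hi - lo + 2 * pad
  shift <- pad - lo
  atoms$x <- atoms$x + shift[1]
  atoms$y <- atoms$y + shift[2]
  atoms$z <- atoms$z + shift[3]
  glyco_model(atoms, links, cell = c(size, 90, 90, 90),
              resolution = resolution)
}

#' Generate a synthetic glycosite fixture
#'
#' Builds an idealized peptide containing an Asn-Ala-Thr sequon, attaches an
#' ideal glycan tree, synthesizes a sigma-normalized "observed" map from the
#' ground truth at the requested resolution with white Gaussian noise, and
#' derives a working model by cropping tree residues and optionally
#' jittering coordinates. With the same seed the output is bit-identical.
#'
#' @param tree_type grammar name (default `"high-mannose"`)
#' @param n_residues tree size of the ground truth (5 = common core)
#' @param resolution map resolution (d_min) in Angstrom
#' @param noise_sd white-noise level in sigma units
#' @param crop `"none"`, `"all"`, or integer indices (in build order) of
#'   tree residues to remove from the working model (descendants of a
#'   cropped residue are cropped too)
#' @param perturb coordinate jitter (Angstrom, normal sd per coordinate) for
#'   the working model; the default of 0.1 Angstrom emulates the typical
#'   positional error of a refined model at ~2 Angstrom resolution
#' @param seed integer seed; fixes all randomness
#' @param spacing map grid spacing in Angstrom
#' @return list with `truth`, `map` (sigma-normalized observed), `working`,
#'   `asn` (sequon key), `tree_keys` (build order), `edges`
#' @export
make_glycosite <- function(tree_type = "high-mannose", n_residues = 5,
                           resolution = 2.0, noise_sd = 0.1, crop = "none",
                           perturb = 0.1, seed = 1, spacing = 0.5) {
  stopifnot(n_residues >= 1, resolution > 0)
  set.seed(seed)
  pep <- build_peptide()
  m0 <- glyco_model(pep, cell = c(100, 100, 100, 90, 90, 90))
  asn_key <- model_residues(m0)$key[model_residues(m0)$comp == "ASN"][1]
  typedef <- load_tree_types()[[tree_type]]
  grown <- build_ideal_tree(m0, asn_key, typedef, n_residues)
  truth <- box_model(grown$model$atoms, grown$model$links,
                     pad = 8, resolution = resolution)
  map <- calc_model_map(truth, d_min = resolution, spacing = spacing)
  map <- map_normalize(map)
  if (noise_sd > 0) {
    map <- map_add_noise(map, noise_sd)
    map <- map_normalize(map)
  }
  tree_keys <- grown$keys
  crop_keys <- character()
  if (identical(crop, "all")) crop_keys <- tree_keys
  else if (is.numeric(crop)) {
    idx <- as.integer(crop)
    if (any(idx < 1 | idx > length(tree_keys))) stop("crop index out of range")
    crop_keys <- tree_keys[idx]
    # propagate along the tree
    repeat {
      more <- grown$edges$child[grown$edges$parent %in% crop_keys &
                                  !(grown$edges$child %in% crop_keys)]
      if (length(more) == 0) break
      crop_keys <- c(crop_keys, more)
    }
  } else if (!identical(crop, "none")) stop("bad crop spec")
  watoms <- truth$atoms[!(res_key_of(truth$atoms) %in% crop_keys), , drop = FALSE]
  lk <- truth$links
  lkey1 <- res_key(lk$chain1, lk$seq1, lk$ins1)
  lkey2 <- res_key(lk$chain2, lk$seq2, lk$ins2)
  wlinks <- lk[!(lkey1 %in% crop_keys) & !(lkey2 %in% crop_keys), , drop = FALSE]
  if (perturb > 0) {
    n <- nrow(watoms)
    watoms$x <- watoms$x + stats::rnorm(n, 0, perturb)
    watoms$y <- watoms$y + stats::rnorm(n, 0, perturb)
    watoms$z <- watoms$z + stats::rnorm(n, 0, perturb)
  }
  working <- glyco_model(watoms, wlinks, truth$cell,
                         resolution = resolution)
  list(truth = truth, map = map, working = working, asn = asn_key,
       tree_keys = tree_keys, edges = grown$edges)
}

# Place a NAG/NDG template with its C1 at distance `d` from the Asn ND2,
# oriented either with C2 pointing back toward ND2 ("toward") or with the
# whole ring pointing away ("away"); the leaving atom is kept or dropped.
place_sugar_near <- function(model, asn_key, d, orient = c("away", "toward"),
                             comp = "NAG", keep_leaving = TRUE,
                             chain = "A", seqno = 401L) {
  orient <- match.arg(orient)
  nd2 <- get_atom(model, asn_key, "ND2")
  cg <- get_atom(model, asn_key, "CG")
  u <- unitv(nd2 - cg)
  c1_target <- nd2 + d * u
  tmpl <- sugar_template(comp)
  txyz <- as.matrix(tmpl[, c("x", "y", "z")]); rownames(txyz) <- tmpl$name
  ctr <- colMeans(txyz[RING_ATOM_ORDER, ])
  vdir <- if (orient == "away") unitv(ctr - txyz["C1", ]) else
    unitv(txyz["C2", ] - txyz["C1", ])
  # rotate so vdir maps onto +u (pointing away from / toward ND2)
  tgt <- if (orient == "away") u else -u
  ax <- vcross(vdir, tgt)
  R <- if (vnorm(ax) < 1e-9) diag(3) else
    rotmat_axis(ax, rad2deg(atan2(vnorm(ax), sum(vdir * tgt))))
  moved <- sweep(t(R %*% t(sweep(txyz, 2, txyz["C1", ]))), 2, c1_target, "+")
  keep <- tmpl$name != template_leaving_atom(comp) | keep_leaving
  at <- data.frame(chain = chain, seq = seqno, ins = "", comp = comp,
                   name = tmpl$name[keep],
                   element = tmpl$element[keep],
                   x = moved[keep, 1], y = moved[keep, 2], z = moved[keep, 3],
                   occ = 1, b = 30, altloc = "", het = TRUE,
                   stringsAsFactors = FALSE)
  model$atoms <- rbind(model$atoms, at)
  model
}

#' Battery of constructed link-detection cases
#'
#' Builds small models probing each filter of the Asn-linking
#' algorithm: direct bonds under 4 Angstrom, the 4-6 Angstrom band with and
#' without a secondary atom within 3.5 Angstrom, the amide-flip case,
#' non-sequon asparagines, proline at X, two-asparagine ambiguity, an
#' already-linked C1 and the NDG leaving atom. Expected outcomes accompany
#' each case.
#'
#' @param seed integer seed (cases are deterministic; the seed only feeds
#'   the cell box placement jitter, kept for API symmetry)
#' @return list of cases: `list(name =, model =, carb =, expected = list(...))`
#' @export
make_link_cases <- function(seed = 1) {
  set.seed(seed)
  base_seq <- function(sequence) {
    pep <- build_peptide(sequence)
    box_model(pep, empty_links(), pad = 12)
  }
  sequon <- c("GLY", "ALA", "ASN", "ALA", "THR", "ALA")
  cases <- list()
  addcase <- function(name, model, expected, carb = "A|401|")
    cases[[length(cases) + 1L]] <<- list(name = name, model = model,
                                         carb = carb, expected = expected)
  asn_of <- function(m) model_residues(m)$key[model_residues(m)$comp == "ASN"][1]

  m <- base_seq(sequon)
  m1 <- place_sugar_near(m, asn_of(m), 3.2, "away", keep_leaving = TRUE)
  addcase("direct_bond_with_leaving_atom", m1,
          list(outcome = "linked", flipped = FALSE, removed = "O1",
               asn = asn_of(m)))

  m2 <- place_sugar_near(m, asn_of(m), 4.5, "toward", keep_leaving = FALSE)
  addcase("secondary_atom_rescue", m2,
          list(outcome = "linked", flipped = FALSE, removed = character(),
               asn = asn_of(m)))

  m3 <- place_sugar_near(m, asn_of(m), 5.0, "away", keep_leaving = FALSE)
  addcase("too_far_no_secondary", m3,
          list(outcome = "rejected_distance", flipped = FALSE,
               removed = character(), asn = NA))

  m4 <- place_sugar_near(m, asn_of(m), 3.2, "away", keep_leaving = FALSE)
  m4$atoms <- swap_amide(m4$atoms, asn_of(m))
  addcase("amide_flip", m4,
          list(outcome = "linked", flipped = TRUE, removed = character(),
               asn = asn_of(m)))

  m5 <- base_seq(c("GLY", "ALA", "ASN", "ALA", "LYS", "ALA"))
  m5 <- place_sugar_near(m5, asn_of(m5), 3.2, "away", keep_leaving = FALSE)
  addcase("motif_violated", m5,
          list(outcome = "rejected_no_sequon", flipped = FALSE,
               removed = character(), asn = NA))

  m6 <- base_seq(c("GLY", "ALA", "ASN", "PRO", "SER", "ALA"))
  m6 <- place_sugar_near(m6, asn_of(m6), 3.2, "away", keep_leaving = FALSE)
  addcase("proline_at_x", m6,
          list(outcome = "rejected_no_sequon", flipped = FALSE,
               removed = character(), asn = NA))

  m7 <- two_asn_case(3.2, 3.4)
  addcase("two_asparagines_ambiguous", m7,
          list(outcome = "rejected_ambiguous", flipped = FALSE,
               removed = character(), asn = NA))

  m8 <- place_sugar_near(m, asn_of(m), 3.2, "away", keep_leaving = FALSE)
  ak <- split_key(asn_of(m))[[1]]
  m8$links <- rbind(m8$links, data.frame(
    chain1 = ak$chain, seq1 = ak$seq, ins1 = ak$ins, atom1 = "ND2",
    chain2 = "A", seq2 = 401L, ins2 = "", atom2 = "C1", dist = 3.2,
    stringsAsFactors = FALSE))
  addcase("c1_already_linked", m8,
          list(outcome = NA, flipped = FALSE, removed = character(), asn = NA))

  m9 <- place_sugar_near(m, asn_of(m), 3.2, "away", comp = "NDG",
                         keep_leaving = TRUE)
  addcase("ndg_leaving_atom", m9,
          list(outcome = "linked", flipped = FALSE, removed = "O1L",
               asn = asn_of(m)))

  m10 <- place_sugar_near(m, asn_of(m), 6.5, "away", keep_leaving = FALSE)
  addcase("out_of_search_radius", m10,
          list(outcome = "no_candidate", flipped = FALSE,
               removed = character(), asn = NA))

  m11 <- place_sugar_near(m, asn_of(m), 4.5, "away", keep_leaving = FALSE)
  addcase("band_without_secondary", m11,
          list(outcome = "rejected_distance", flipped = FALSE,
               removed = character(), asn = NA))

  m12 <- place_sugar_near(m, asn_of(m), 3.9, "away", keep_leaving = FALSE)
  addcase("just_under_direct_max", m12,
          list(outcome = "linked", flipped = FALSE, removed = character(),
               asn = asn_of(m)))

  m13 <- place_sugar_near(m, asn_of(m), 3.2, "away", keep_leaving = FALSE)
  m13$atoms <- m13$atoms[!(res_key_of(m13$atoms) == "A|401|" &
                             m13$atoms$name == "C1"), ]
  addcase("carb_missing_c1", m13,
          list(outcome = "no_candidate", flipped = FALSE,
               removed = character(), asn = NA))

  cases
}

swap_amide <- function(atoms, asn_key) {
  sel <- res_key_of(atoms) == asn_key
  i_od <- which(sel & atoms$name == "OD1")
  i_nd <- which(sel & atoms$name == "ND2")
  tmp <- atoms[i_od, c("x", "y", "z")]
  atoms[i_od, c("x", "y", "z")] <- atoms[i_nd, c("x", "y", "z")]
  atoms[i_nd, c("x", "y", "z")] <- tmp
  atoms
}

two_asn_case <- function(d1, d2) {
  pepA <- build_peptide(chain = "A")
  pepB <- build_peptide(chain = "B", seq_start = 61L)
  mA <- glyco_model(pepA, cell = c(200, 200, 200, 90, 90, 90))
  asnA <- model_residues(mA)$key[model_residues(mA)$comp == "ASN"][1]
  nd2A <- get_atom(mA, asnA, "ND2")
  cgA <- get_atom(mA, asnA, "CG")
  u <- unitv(nd2A - cgA)
  c1 <- nd2A + d1 * u
  # move chain B so its ND2 sits at c1 + d2 * u
  mB <- glyco_model(pepB, cell = c(200, 200, 200, 90, 90, 90))
  asnB <- model_residues(mB)$key[model_residues(mB)$comp == "ASN"][1]
  nd2B <- get_atom(mB, asnB, "ND2")
  shift <- (c1 + d2 * u) - nd2B
  pepB$x <- pepB$x + shift[1]; pepB$y <- pepB$y + shift[2]
  pepB$z <- pepB$z + shift[3]
  allat <- rbind(pepA, pepB)
  m <- box_model(allat, empty_links(), pad = 12)
  # recompute positions after boxing, then drop the sugar at the midpoint
  asnA <- model_residues(m)$key[model_residues(m)$comp == "ASN"][1]
  m <- place_sugar_near(m, asnA, d1, "away", keep_leaving = FALSE)
  m
}
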