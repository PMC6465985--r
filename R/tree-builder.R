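#' @title Template-based carbohydrate placement and greedy tree extension
#'
#' @description Single carbohydrate residues are placed by rigidly
#' transforming an idealized template so that its anomeric C1 bonds the
#' parent attachment atom (a hydroxyl oxygen, or Asn ND2 for the root) at
#' ideal length and angle, enumerating candidate glycosidic torsion pairs
#' (phi, psi) drawn from published torsion preferences and refining around
#' the best-fitting candidate. A placement is locally accepted when the mean
#' density level over its atoms reaches a (deliberately permissive)
#' threshold and it does not clash hard with existing atoms; the pipeline's
#' stricter density filters are the real gate. Tree extension is a
#' deterministic breadth-first walk over the open productions of the
#' selected tree grammar.
#' @name tree-builder
NULL

# attachment chemistry per linkage position: the parent attachment atom,
# its anchor carbon and the torsion-reference atom on the parent
ATTACH_TABLE <- list(
  `0` = list(oxy = "ND2", anchor = "CG", ref = "CB", bond = 1.44, angle = 124),
  `2` = list(oxy = "O2", anchor = "C2", ref = "C1", bond = 1.43, angle = 117),
  `3` = list(oxy = "O3", anchor = "C3", ref = "C2", bond = 1.43, angle = 117),
  `4` = list(oxy = "O4", anchor = "C4", ref = "C3", bond = 1.43, angle = 117),
  `6` = list(oxy = "O6", anchor = "C6", ref = "C5", bond = 1.43, angle = 117)
)

# ideal glycosidic torsions per linkage position (phi = O5'-C1'-O-Cx about
# the new bond, psi = placement torsion ref-anchor-O-C1'); the first pair of
# each candidate list is the ideal used by the fixture generator
LINKAGE_TORSIONS <- list(
  `0` = list(ideal = c(-95, 175),
             candidates = rbind(c(-95, 175), c(-95, -100), c(-95, 80),
                                c(95, 175), c(180, 175), c(-95, -175))),
  `2` = list(ideal = c(-75, 120),
             candidates = rbind(c(-75, 120), c(-75, -120), c(-75, 180),
                                c(75, 120), c(180, 120), c(75, -120))),
  `3` = list(ideal = c(80, 100),
             candidates = rbind(c(80, 100), c(-80, 100), c(80, -100),
                                c(180, 100), c(80, 180), c(-75, -120))),
  `4` = list(ideal = c(-75, -110),
             candidates = rbind(c(-75, -110), c(-75, 110), c(-75, 180),
                                c(75, -110), c(180, -110), c(75, 110))),
  `6` = list(ideal = c(-70, 180),
             candidates = rbind(c(-70, 180), c(-70, -90), c(-70, 90),
                                c(70, 180), c(180, 180), c(70, -90)))
)

# Rigid placement of a template as the child of `parent_key` through the
# production's attachment position, at torsions (phi, psi). Returns the
# transformed atom table (leaving atom dropped) or NULL when the parent
# lacks the needed frame atoms.
place_template <- function(model, parent_key, position, comp, phi, psi,
                           templates = sugar_templates()) {
  att <- ATTACH_TABLE[[as.character(position)]]
  if (is.null(att)) return(NULL)
  A1 <- get_atom(model, parent_key, att$ref)
  A2 <- get_atom(model, parent_key, att$anchor)
  A3 <- get_atom(model, parent_key, att$oxy)
  if (is.null(A1) || is.null(A2) || is.null(A3)) return(NULL)
  tmpl <- templates[[comp]]
  if (is.null(tmpl)) return(NULL)
  c1_new <- place_atom(A1, A2, A3, att$bond, att$angle, psi)
  txyz <- as.matrix(tmpl[, c("x", "y", "z")])
  rownames(txyz) <- tmpl$name
  lv <- template_leaving_atom(comp)
  # align template C1->O1 axis onto C1_new->A3
  u <- unitv(txyz[lv, ] - txyz["C1", ])
  v <- unitv(A3 - c1_new)
  ax <- vcross(u, v)
  if (vnorm(ax) < 1e-9) {
    R1 <- if (sum(u * v) > 0) diag(3) else rotmat_axis(orthogonal_of(u), 180)
  } else {
    R1 <- rotmat_axis(ax, rad2deg(atan2(vnorm(ax), sum(u * v))))
  }
  moved <- t(R1 %*% t(sweep(txyz, 2, txyz["C1", ])))
  moved <- sweep(moved, 2, c1_new, "+")
  # set phi: torsion O5 - C1 - A3(oxy) - anchor
  cur <- torsion4(moved["O5", ], moved["C1", ], A3, A2)
  R2 <- rotmat_axis(v, phi - cur)
  moved2 <- sweep(t(R2 %*% t(sweep(moved, 2, c1_new))), 2, c1_new, "+")
  chk <- torsion4(moved2["O5", ], moved2["C1", ], A3, A2)
  if (abs(angdiff(chk, phi)) > 1e-3) {
    R2 <- rotmat_axis(v, -(phi - cur))
    moved2 <- sweep(t(R2 %*% t(sweep(moved, 2, c1_new))), 2, c1_new, "+")
  }
  out <- tmpl
  out$x <- moved2[, 1]; out$y <- moved2[, 2]; out$z <- moved2[, 3]
  out[out$name != lv, , drop = FALSE]
}

angdiff <- function(a, b) ((a - b + 180) %% 360) - 180

# Greedy local rigid-body refinement of a placed residue against the map:
# rotations about the anomeric C1 (which preserves the bond to the parent)
# and small translations, with the C1 displacement capped so the glycosidic
# bond is only modestly strained. Deterministic coordinate ascent with
# step-halving; maximizes the mean sigma-level over the residue atoms.
refine_rigid <- function(atoms, map_obs, max_shift = 0.35) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  c1_ideal <- xyz[atoms$name == "C1", , drop = FALSE][1, ]
  fitv <- function(m) mean(map_interpolate(map_obs, m))
  best <- fitv(xyz)
  step_r <- 4; step_t <- 0.12
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (iter in 1:60) {
    improved <- FALSE
    ctr <- xyz[atoms$name == "C1", , drop = FALSE][1, ]
    for (ax in axes) for (sg in c(-1, 1)) {
      R <- rotmat_axis(ax, sg * step_r)
      cand <- sweep(t(R %*% t(sweep(xyz, 2, ctr))), 2, ctr, "+")
      f <- fitv(cand)
      if (f > best + 1e-9) { xyz <- cand; best <- f; improved <- TRUE }
    }
    for (ax in axes) for (sg in c(-1, 1)) {
      cand <- sweep(xyz, 2, sg * step_t * unlist(ax), "+")
      c1n <- cand[atoms$name == "C1", , drop = FALSE][1, ]
      if (vnorm(c1n - c1_ideal) > max_shift) next
      f <- fitv(cand)
      if (f > best + 1e-9) { xyz <- cand; best <- f; improved <- TRUE }
    }
    if (!improved) {
      if (step_r <= 1.01) break
      step_r <- step_r / 2; step_t <- step_t / 2
    }
  }
  out <- atoms
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}

orthogonal_of <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(vcross(u, v))
}

#' Place one carbohydrate residue against a density map
#'
#' Tries every candidate torsion pair for the linkage, scores each placement
#' by the mean interpolated sigma-level over its atoms, refines a +/- 20
#' degree local grid around the best candidate, and applies the local
#' acceptance rule: both the mean and the median atom sigma-level must reach
#' `local_threshold` (the median guards against placements supported only by
#' a neighbouring residue's density skirt) and there must be no hard clash
#' with existing non-parent atoms.
#'
#' @param model a [glyco_model] holding the parent
#' @param parent_key residue key of the parent (Asn for the root linkage)
#' @param production `list(position =, child =)`; position 0 = root
#' @param map_obs sigma-normalized observed [density_map]
#' @param local_threshold minimum mean sigma-level to accept locally
#' @param clash_dist hard-clash distance in Angstrom
#' @param templates template set from [sugar_templates()]
#' @return `list(atoms =, fit =, accepted =, phi =, psi =)`, or `NULL` when
#'   the attachment frame cannot be resolved
#' @export
place_residue <- function(model, parent_key, production, map_obs,
                          local_threshold = 0.6, clash_dist = 2.1,
                          templates = sugar_templates()) {
  pos <- production$position
  tor <- LINKAGE_TORSIONS[[as.character(pos)]]
  if (is.null(tor)) return(NULL)
  best <- NULL
  try_one <- function(phi, psi) {
    at <- place_template(model, parent_key, pos, production$child, phi, psi,
                         templates)
    if (is.null(at)) return(NULL)
    v <- map_interpolate(map_obs, as.matrix(at[, c("x", "y", "z")]))
    list(atoms = at, fit = mean(v), med = stats::median(v), phi = phi, psi = psi)
  }
  for (i in seq_len(nrow(tor$candidates))) {
    r <- try_one(tor$candidates[i, 1], tor$candidates[i, 2])
    if (is.null(r)) return(NULL)
    if (is.null(best) || r$fit > best$fit) best <- r
  }
  if (is.null(best)) return(NULL)
  for (dphi in seq(-20, 20, 10)) for (dpsi in seq(-20, 20, 10)) {
    if (dphi == 0 && dpsi == 0) next
    r <- try_one(best$phi + dphi, best$psi + dpsi)
    if (!is.null(r) && r$fit > best$fit) best <- r
  }
  # local rigid-body polish against the map (robust to anchor-frame error in
  # the parent coordinates; bond to the parent preserved up to max_shift)
  best$atoms <- refine_rigid(best$atoms, map_obs)
  v <- map_interpolate(map_obs, as.matrix(best$atoms[, c("x", "y", "z")]))
  best$fit <- mean(v)
  best$med <- stats::median(v)
  # hard-clash test against all existing atoms except the bonded attachment
  # atom itself (C1 sits at bond length from it by construction)
  att_name <- ATTACH_TABLE[[as.character(pos)]]$oxy
  other <- model$atoms[!(res_key_of(model$atoms) == parent_key &
                           model$atoms$name == att_name), , drop = FALSE]
  other <- other[!(toupper(other$element) %in% c("H", "D")), , drop = FALSE]
  clash <- FALSE
  if (nrow(other) > 0) {
    dmin <- min_cross_dist(as.matrix(best$atoms[, c("x", "y", "z")]),
                           atom_xyz(other))
    clash <- dmin < clash_dist
  }
  # both the mean and the median atom support must reach the contour: the
  # median guards against placements living entirely in the density skirt
  # of a neighbouring residue (half the atoms must be individually supported)
  best$accepted <- is.finite(best$fit) && best$fit >= local_threshold &&
    best$med >= local_threshold && !clash
  best
}

# productions of `typedef` applicable at a parent of given comp and depth
open_productions <- function(typedef, parent_comp, depth) {
  p <- typedef$productions
  sel <- p$parent == parent_comp &
    (p$depth == depth | (p$depth == -1 & depth >= 4))
  p <- p[sel, , drop = FALSE]
  # deterministic order: non-fucose first, position 4 before 3 before 6
  ordpos <- match(p$position, c(4, 3, 6, 2, 0))
  p[order(p$class == "fucose", ordpos), , drop = FALSE]
}

#' Extend a glycan tree (possibly from a bare asparagine) against a map
#'
#' Breadth-first growth over the open productions of the tree grammar at the
#' current leaves: the core is attempted before branches, position 4 before
#' 3 before 6, fucoses last; each accepted placement adds a node and
#' enqueues its own productions; growth stops when every possibility has
#' been attempted.
#'
#' @param model a [glyco_model] (is modified and returned)
#' @param root_asn residue key of the sequon asparagine
#' @param tree existing tree rooted there (`NULL` for whole-tree addition)
#' @param typedef selected tree grammar
#' @param map_obs sigma-normalized observed [density_map]
#' @param local_threshold,clash_dist see [place_residue()]
#' @param templates template set
#' @return `list(model =, new_keys =, edges =)`
#' @export
extend_tree <- function(model, root_asn, tree = NULL, typedef, map_obs,
                        local_threshold = 0.6, clash_dist = 2.1,
                        templates = sugar_templates()) {
  rs <- model_residues(model)
  comp_map <- stats::setNames(rs$comp, rs$key)
  depth <- c(stats::setNames(0L, root_asn),
             if (!is.null(tree)) tree_node_depths(tree))
  occupied <- character()   # "parentkey@position" already bonded
  if (!is.null(tree)) {
    occupied <- paste0(tree$edges$parent, "@", tree$edges$position)
  }
  new_keys <- character()
  new_edges <- data.frame(parent = character(), child = character(),
                          parent_atom = character(), child_atom = character(),
                          position = integer(), anomer = character(),
                          stringsAsFactors = FALSE)
  queue <- c(root_asn, if (!is.null(tree)) tree$nodes)
  fucose_q <- character()
  chain <- split_key(root_asn)[[1]]$chain

  attempt <- function(pkey, prod_row) {
    res <- place_residue(model, pkey, list(position = prod_row$position,
                                           child = prod_row$child),
                         map_obs, local_threshold, clash_dist, templates)
    if (is.null(res) || !res$accepted) return(FALSE)
    seqno <- next_free_seq(model, chain)
    at <- res$atoms
    newat <- data.frame(chain = chain, seq = seqno, ins = "",
                        comp = prod_row$child, name = at$name,
                        element = at$element, x = at$x, y = at$y, z = at$z,
                        occ = 1, b = 30, altloc = "", het = TRUE,
                        stringsAsFactors = FALSE)
    ckey <- res_key(chain, seqno, "")
    model$atoms <<- rbind(model$atoms, newat)
    patom <- ATTACH_TABLE[[as.character(prod_row$position)]]$oxy
    pp <- split_key(pkey)[[1]]
    d <- vnorm(get_atom(model, pkey, patom) - get_atom(model, ckey, "C1"))
    model$links <<- rbind(model$links, data.frame(
      chain1 = pp$chain, seq1 = pp$seq, ins1 = pp$ins, atom1 = patom,
      chain2 = chain, seq2 = seqno, ins2 = "", atom2 = "C1", dist = d,
      stringsAsFactors = FALSE))
    depth[ckey] <<- depth[[pkey]] + 1L
    comp_map[ckey] <<- prod_row$child
    occupied <<- c(occupied, paste0(pkey, "@", prod_row$position))
    new_keys <<- c(new_keys, ckey)
    new_edges <<- rbind(new_edges, data.frame(
      parent = pkey, child = ckey, parent_atom = patom, child_atom = "C1",
      position = prod_row$position, anomer = prod_row$anomer,
      stringsAsFactors = FALSE))
    queue <<- c(queue, ckey)
    TRUE
  }

  while (length(queue) > 0) {
    pkey <- queue[1]; queue <- queue[-1]
    pcomp <- if (depth[[pkey]] == 0L) "ASN" else unname(comp_map[pkey])
    prods <- open_productions(typedef, pcomp, depth[[pkey]])
    for (i in seq_len(nrow(prods))) {
      if (paste0(pkey, "@", prods$position[i]) %in% occupied) next
      if (prods$class[i] == "fucose") {
        fucose_q <- c(fucose_q, paste0(pkey, ":", i))
        next
      }
      attempt(pkey, prods[i, , drop = FALSE])
    }
    if (length(queue) == 0 && length(fucose_q) > 0) {
      for (fq in fucose_q) {
        parts <- strsplit(fq, ":", fixed = TRUE)[[1]]
        pkey2 <- parts[1]
        pcomp2 <- if (depth[[pkey2]] == 0L) "ASN" else unname(comp_map[pkey2])
        prods2 <- open_productions(typedef, pcomp2, depth[[pkey2]])
        i2 <- as.integer(parts[2])
        if (paste0(pkey2, "@", prods2$position[i2]) %in% occupied) next
        attempt(pkey2, prods2[i2, , drop = FALSE])
      }
      fucose_q <- character()
    }
  }
  list(model = model, new_keys = new_keys, edges = new_edges)
}

next_free_seq <- function(model, chain, from = 401L) {
  used <- unique(model$atoms$seq[model$atoms$chain == chain])
  s <- from
  while (s %in% used) s <- s + 1L
  s
}
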