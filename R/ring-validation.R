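#' @title Pyranose ring puckering and three-tier quality status
#'
#' @description Cremer-Pople analysis of six-membered sugar rings and a
#' three-tier yes/check/no status combining ring conformation, anomeric
#' configuration and ring completeness. D-pyranoses in the expected chair
#' have a polar pucker angle theta near 0 degrees; L-fucoses, whose ring is
#' traversed in the same canonical O5,C1..C5 order, invert the pucker pole
#' and sit near 180 degrees.
#' @name ring-validation
NULL

RING_ATOM_ORDER <- c("O5", "C1", "C2", "C3", "C4", "C5")

PYRANOSE_COMPS <- c("NAG", "NDG", "MAN", "BMA", "FUC", "FUL", "BGC", "GLC",
                    "GAL", "NGA", "LXZ", "GL0")

L_SUGAR_COMPS <- c("FUC", "FUL")

# Declared anomer per component code; alpha/beta is part of the comp_id in
# the PDB chemical dictionary.
COMP_ANOMER <- c(NAG = "beta", NDG = "alpha", MAN = "alpha", BMA = "beta",
                 FUC = "alpha", FUL = "beta", BGC = "beta", GLC = "alpha",
                 GAL = "beta", NGA = "beta")

#' Pick the six ring atoms of a pyranose residue
#'
#' @param atoms atom data.frame of a single residue
#' @return 6x3 coordinate matrix in O5, C1, C2, C3, C4, C5 order, or an
#'   object of class `incomplete_ring` naming the missing atoms
#' @export
pick_ring_atoms <- function(atoms) {
  atoms <- dominant_atoms(atoms)
  idx <- match(RING_ATOM_ORDER, atoms$name)
  if (anyNA(idx)) {
    return(structure(list(missing = RING_ATOM_ORDER[is.na(idx)]),
                     class = "incomplete_ring"))
  }
  xyz <- atom_xyz(atoms[idx, , drop = FALSE])
  rownames(xyz) <- RING_ATOM_ORDER
  xyz
}

#' Cremer-Pople puckering parameters of a six-membered ring
#'
#' Standard mean-plane decomposition for N = 6: out-of-plane displacements
#' z_j are taken along the unit normal of the Cremer-Pople mean plane
#' (constructed from the two Fourier sums R' and R'' about the geometric
#' centre, guaranteeing sum(z_j) = 0), then
#' q2, phi2 from the second Fourier component, q3 from the alternating sum,
#' Q = sqrt(q2^2 + q3^2), theta = acos(q3 / Q).
#'
#' @param ring_xyz 6x3 matrix of ring-atom positions in O5,C1..C5 order
#' @return `list(Q =, theta =, phi =, z =)` with theta in [0, 180] degrees and
#'   phi in [0, 360); for a planar ring (Q ~ 0) theta and phi are `NA` and
#'   `degenerate` is `TRUE`
#' @export
cremer_pople <- function(ring_xyz) {
  stopifnot(is.matrix(ring_xyz), nrow(ring_xyz) == 6, ncol(ring_xyz) == 3)
  if (!all(is.finite(ring_xyz))) stop("non-finite ring coordinates")
  N <- 6L
  ctr <- colMeans(ring_xyz)
  r <- sweep(ring_xyz, 2, ctr)
  j <- 0:(N - 1)
  Rp <- colSums(r * sin(2 * pi * j / N))
  Rpp <- colSums(r * cos(2 * pi * j / N))
  # normal oriented so the canonical 4C1 chair (O5 displaced above the
  # plane, alternating signs around the ring) scores theta = 0
  nvec <- vcross(Rpp, Rp)
  nn <- vnorm(nvec)
  if (nn < 1e-10) stop("degenerate ring geometry: no mean plane")
  nvec <- nvec / nn
  z <- as.numeric(r %*% nvec)
  q2c <- sqrt(2 / N) * sum(z * cos(2 * pi * 2 * j / N))
  q2s <- -sqrt(2 / N) * sum(z * sin(2 * pi * 2 * j / N))
  q3 <- sqrt(1 / N) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  if (Q < 1e-8) {
    return(list(Q = 0, theta = NA_real_, phi = NA_real_, z = z,
                degenerate = TRUE))
  }
  theta <- rad2deg(acos(max(-1, min(1, q3 / Q))))
  phi <- rad2deg(atan2(q2s, q2c)) %% 360
  list(Q = Q, theta = theta, phi = phi, z = z, degenerate = FALSE)
}

# Geometric anomer at C1: chirality of the (O5, C2, substituent) arrangement
# around C1, measured as the sign of det[O5-C1, C2-C1, X-C1] where X is the
# exocyclic anomeric substituent (glycosidic O, ND2 of Asn, or O1).
# The sign depends only on configuration, not conformation. Reference signs
# are fixed by the package's ideal templates: beta-D gives a negative
# determinant, alpha-D positive; L-sugars (mirror images) swap the signs.
anomer_sign <- function(ring_xyz, subst_xyz) {
  v1 <- ring_xyz["O5", ] - ring_xyz["C1", ]
  v2 <- ring_xyz["C2", ] - ring_xyz["C1", ]
  v3 <- subst_xyz - ring_xyz["C1", ]
  det(rbind(v1, v2, v3))
}

geometric_anomer <- function(ring_xyz, subst_xyz, comp) {
  s <- anomer_sign(ring_xyz, subst_xyz)
  is_l <- comp %in% L_SUGAR_COMPS
  if (is_l) s <- -s
  if (abs(s) < 1e-6) return(NA_character_)
  if (s < 0) "beta" else "alpha"
}

# Exocyclic substituent position at C1 for a residue inside a model: the
# link partner of C1 if a covalent link record names it, else an O1 atom in
# the residue. NULL if neither exists (the anomer check is then skipped).
find_anomeric_substituent <- function(model, key) {
  lk <- model$links
  parts <- split_key(key)[[1]]
  for (i in seq_len(nrow(lk))) {
    k1 <- res_key(lk$chain1[i], lk$seq1[i], lk$ins1[i])
    k2 <- res_key(lk$chain2[i], lk$seq2[i], lk$ins2[i])
    if (k1 == key && lk$atom1[i] == "C1") {
      p <- get_atom(model, k2, lk$atom2[i]); if (!is.null(p)) return(p)
    }
    if (k2 == key && lk$atom2[i] == "C1") {
      p <- get_atom(model, k1, lk$atom1[i]); if (!is.null(p)) return(p)
    }
  }
  get_atom(model, key, "O1")
}

#' Three-tier ring quality status
#'
#' Combines the chair test (theta window appropriate to the sugar series),
#' the geometric anomer check at C1 and ring completeness into a
#' yes/check/no status. "yes" requires a correct chair, matching anomer and
#' a complete ring; "check" is granted when the only failure is a pucker in
#' the soft band next to the chair window (30-45 degrees from the expected
#' pole); anything else is "no".
#'
#' @param comp component code (e.g. "NAG"); FUC/FUL expect theta near 180
#' @param pucker result of [cremer_pople()], or an `incomplete_ring` object
#' @param expected_anomer `"alpha"`, `"beta"`, or `NA` to take the anomer
#'   declared by the component code
#' @param observed_anomer geometric anomer (`"alpha"`/`"beta"`) or `NA` if no
#'   anomeric substituent is resolvable (check skipped)
#' @return `list(status = "yes"|"check"|"no", reasons = character())`
#' @export
assign_status <- function(comp, pucker, expected_anomer = NA,
                          observed_anomer = NA) {
  reasons <- character()
  if (inherits(pucker, "incomplete_ring")) {
    return(list(status = "no",
                reasons = paste0("missing_ring_atom:", paste(pucker$missing, collapse = "+"))))
  }
  if (is.na(expected_anomer)) expected_anomer <- unname(COMP_ANOMER[comp])
  if (isTRUE(pucker$degenerate) || is.na(pucker$theta)) {
    return(list(status = "no", reasons = "degenerate_ring"))
  }
  # distance of theta from the expected chair pole
  pole <- if (comp %in% L_SUGAR_COMPS) 180 else 0
  dev <- abs(pucker$theta - pole)
  conf <- if (dev <= 30) "yes" else if (dev < 45) "check" else "no"
  if (conf != "yes") reasons <- c(reasons, sprintf("pucker_theta:%.1f", pucker$theta))
  anomer_ok <- TRUE
  if (!is.na(observed_anomer) && !is.na(expected_anomer) &&
      observed_anomer != expected_anomer) {
    anomer_ok <- FALSE
    reasons <- c(reasons, sprintf("anomer:%s_expected_%s", observed_anomer, expected_anomer))
  }
  status <- if (conf == "yes" && anomer_ok) "yes"
            else if (conf == "check" && anomer_ok) "check"
            else "no"
  list(status = status, reasons = reasons)
}

#' Validate every carbohydrate residue of a model
#'
#' @param model a [glyco_model]
#' @param keys residue keys to validate; default: all residues whose comp is
#'   a supported pyranose
#' @return data.frame: `key`, `comp`, `Q`, `theta`, `phi`, `status`, `reasons`
#' @export
validate_rings <- function(model, keys = NULL) {
  rs <- model_residues(model)
  if (is.null(keys)) keys <- rs$key[rs$comp %in% PYRANOSE_COMPS]
  if (length(keys) == 0L)
    return(data.frame(key = character(), comp = character(), Q = numeric(),
                      theta = numeric(), phi = numeric(), status = character(),
                      reasons = character(), stringsAsFactors = FALSE))
  out <- data.frame(key = keys, comp = NA_character_, Q = NA_real_,
                    theta = NA_real_, phi = NA_real_, status = NA_character_,
                    reasons = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    at <- residue_atoms(model, keys[i])
    out$comp[i] <- if (nrow(at)) at$comp[1] else NA_character_
    ring <- pick_ring_atoms(at)
    if (inherits(ring, "incomplete_ring")) {
      st <- assign_status(out$comp[i], ring)
    } else {
      cp <- tryCatch(cremer_pople(ring), error = function(e)
        list(Q = 0, theta = NA_real_, phi = NA_real_, degenerate = TRUE))
      out$Q[i] <- cp$Q; out$theta[i] <- cp$theta; out$phi[i] <- cp$phi
      sub <- find_anomeric_substituent(model, keys[i])
      obs <- if (is.null(sub)) NA_character_
             else geometric_anomer(ring, sub, out$comp[i])
      st <- assign_status(out$comp[i], cp, observed_anomer = obs)
    }
    out$status[i] <- st$status
    out$reasons[i] <- paste(st$reasons, collapse = ";")
  }
  out
}
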