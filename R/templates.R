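#' @title Idealized monosaccharide templates
#'
#' @description Templates are generated once, in code, from canonical chair
#' internal coordinates: a six-membered ring with alternating out-of-plane
#' displacements (the 4C1 chair for D-pyranoses; L-fucoses are built as the
#' mirror image and therefore sit in 1C4), with exocyclic substituents on
#' ideal tetrahedral axial/equatorial directions. All heavy atoms of each
#' monosaccharide are present; the anomeric O1 (O1L for NDG) is included and
#' is the leaving atom that is removed when a glycosidic or N-glycosidic
#' bond is formed.
#' @name templates
NULL

# configuration per supported component: anomer, N-acetyl at C2, O2 and O4
# axial/equatorial, 6-deoxy (fucose), L-series (mirrored)
SUGAR_CONFIG <- list(
  NAG = list(anomer = "beta",  n2 = TRUE,  o2 = NA,   o4 = "eq", deoxy6 = FALSE, lsugar = FALSE, leaving = "O1"),
  NDG = list(anomer = "alpha", n2 = TRUE,  o2 = NA,   o4 = "eq", deoxy6 = FALSE, lsugar = FALSE, leaving = "O1L"),
  MAN = list(anomer = "alpha", n2 = FALSE, o2 = "ax", o4 = "eq", deoxy6 = FALSE, lsugar = FALSE, leaving = "O1"),
  BMA = list(anomer = "beta",  n2 = FALSE, o2 = "ax", o4 = "eq", deoxy6 = FALSE, lsugar = FALSE, leaving = "O1"),
  GLC = list(anomer = "alpha", n2 = FALSE, o2 = "eq", o4 = "eq", deoxy6 = FALSE, lsugar = FALSE, leaving = "O1"),
  BGC = list(anomer = "beta",  n2 = FALSE, o2 = "eq", o4 = "eq", deoxy6 = FALSE, lsugar = FALSE, leaving = "O1"),
  FUC = list(anomer = "alpha", n2 = FALSE, o2 = "eq", o4 = "ax", deoxy6 = TRUE,  lsugar = TRUE,  leaving = "O1"),
  FUL = list(anomer = "beta",  n2 = FALSE, o2 = "eq", o4 = "ax", deoxy6 = TRUE,  lsugar = TRUE,  leaving = "O1")
)

# ideal chair ring in the canonical frame: hexagon radius and alternating
# displacement chosen so all ring bonds are ~1.43 A and theta is exactly 0
RING_RADIUS <- 1.35
RING_Z <- 0.23

chair_ring <- function() {
  k <- 0:5
  xyz <- cbind(RING_RADIUS * cos(k * pi / 3),
               RING_RADIUS * sin(k * pi / 3),
               RING_Z * (-1)^k)
  rownames(xyz) <- RING_ATOM_ORDER
  xyz
}

# the two tetrahedral exocyclic directions of ring atom `idx` (1-based in
# O5,C1..C5 order); returns list(ax =, eq =) unit vectors
exocyclic_dirs <- function(ring, idx) {
  at <- ring[idx, ]
  prev <- ring[(idx - 2) %% 6 + 1, ]
  nxt <- ring[idx %% 6 + 1, ]
  u1 <- unitv(prev - at); u2 <- unitv(nxt - at)
  s <- -unitv(u1 + u2)
  t <- unitv(vcross(u1, u2))
  half <- deg2rad(109.47 / 2)
  d1 <- unitv(cos(half) * s + sin(half) * t)
  d2 <- unitv(cos(half) * s - sin(half) * t)
  if (abs(d1[3]) >= abs(d2[3])) list(ax = d1, eq = d2) else list(ax = d2, eq = d1)
}

#' Idealized template for one monosaccharide
#'
#' @param comp component code (NAG, NDG, MAN, BMA, GLC, BGC, FUC, FUL)
#' @return data.frame with `name`, `element`, `x`, `y`, `z`; includes the
#'   anomeric leaving atom (O1, or O1L for NDG)
#' @export
sugar_template <- function(comp) {
  cfg <- SUGAR_CONFIG[[comp]]
  if (is.null(cfg)) stop("no template for component ", comp)
  ring <- chair_ring()
  pos <- list()
  for (nm in RING_ATOM_ORDER) pos[[nm]] <- ring[nm, ]
  add <- function(name, xyz) pos[[name]] <<- xyz

  dir1 <- exocyclic_dirs(ring, 2)  # C1
  anom_dir <- if (cfg$anomer == "beta") dir1$eq else dir1$ax
  add(cfg$leaving, pos$C1 + 1.43 * anom_dir)

  dir2 <- exocyclic_dirs(ring, 3)  # C2
  if (cfg$n2) {
    n2 <- pos$C2 + 1.45 * dir2$eq
    add("N2", n2)
    c7 <- place_atom(pos$C1, pos$C2, n2, 1.33, 122, 180)
    add("C7", c7)
    add("O7", place_atom(pos$C2, n2, c7, 1.23, 122, 0))
    add("C8", place_atom(pos$C2, n2, c7, 1.50, 115, 180))
  } else {
    add("O2", pos$C2 + 1.43 * (if (cfg$o2 == "ax") dir2$ax else dir2$eq))
  }

  dir3 <- exocyclic_dirs(ring, 4)  # C3
  add("O3", pos$C3 + 1.43 * dir3$eq)

  dir4 <- exocyclic_dirs(ring, 5)  # C4
  add("O4", pos$C4 + 1.43 * (if (cfg$o4 == "ax") dir4$ax else dir4$eq))

  dir5 <- exocyclic_dirs(ring, 6)  # C5
  c6 <- pos$C5 + 1.52 * dir5$eq
  add("C6", c6)
  if (!cfg$deoxy6) {
    add("O6", place_atom(pos$O5, pos$C5, c6, 1.43, 109.5, -60))
  }

  out <- data.frame(
    name = names(pos),
    element = substr(gsub("[0-9L]", "", names(pos)), 1, 1),
    x = vapply(pos, `[`, numeric(1), 1),
    y = vapply(pos, `[`, numeric(1), 2),
    z = vapply(pos, `[`, numeric(1), 3),
    stringsAsFactors = FALSE, row.names = NULL)
  if (cfg$lsugar) out$x <- -out$x
  out
}

#' All shipped templates
#' @return named list of template data.frames
#' @export
sugar_templates <- function() {
  nms <- names(SUGAR_CONFIG)
  stats::setNames(lapply(nms, sugar_template), nms)
}

template_leaving_atom <- function(comp) SUGAR_CONFIG[[comp]]$leaving
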