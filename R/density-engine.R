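#' @title Real-space density maps and per-residue density metrics
#'
#' @description Model maps are computed as sums of per-atom Gaussians using
#' published multi-Gaussian X-ray form factors, B-smeared and occupancy
#' weighted, accumulated on a periodic grid over the unit cell, optionally
#' band-limited to the data resolution by a discrete Fourier transform.
#' Residues are scored with the real-space correlation coefficient (RSCC),
#' an electron-density-support metric per atom (EDIA) aggregated with a
#' power mean of exponent -2 (EDIAm), and the density ratio between a
#' residue and the protein main chain. During scoring, carbohydrate B
#' factors are overridden with a constant (default 30.0 Angstrom^2) so that
#' good metrics require density at decent contour levels.
#' @name density-engine
NULL

# Cromer-Mann 4-Gaussian X-ray form-factor coefficients (International
# Tables Vol. C); the constant term is treated as a fourth narrow Gaussian
# broadened by the atomic B factor.
CROMER_MANN <- list(
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490)
)

element_coeffs <- function(element) {
  el <- toupper(element)
  if (el %in% c("H", "D")) return(NULL)
  cf <- CROMER_MANN[[el]]
  if (is.null(cf)) {
    warning("unknown element '", element, "', using nitrogen-like form factors",
            call. = FALSE)
    cf <- CROMER_MANN[["N"]]
  }
  cf
}

#' Construct a density map object
#'
#' @param grid 3-D numeric array over one unit cell (fractional axes a, b, c)
#' @param cell cell parameters (length 6)
#' @return object of class `density_map`
#' @export
density_map <- function(grid, cell) {
  stopifnot(length(dim(grid)) == 3, all(dim(grid) >= 2), all(is.finite(grid)))
  structure(list(grid = grid, cell = as.numeric(cell), dim = dim(grid)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d x %d grid, cell %.2f %.2f %.2f A\n",
              x$dim[1], x$dim[2], x$dim[3], x$cell[1], x$cell[2], x$cell[3]))
  cat(sprintf("  mean %.4f sd %.4f min %.3f max %.3f\n",
              mean(x$grid), stats::sd(as.numeric(x$grid)),
              min(x$grid), max(x$grid)))
  invisible(x)
}

map_spacing <- function(map) map$cell[1:3] / map$dim

#' Calculate a model density map
#'
#' Sum of per-atom B-smeared Gaussians on a periodic grid; each Cromer-Mann
#' term contributes a real-space Gaussian
#' a_i (4 pi / (b_i + B))^(3/2) exp(-4 pi^2 r^2 / (b_i + B)).
#' If `d_min` is given, the grid is band-limited by zeroing Fourier
#' coefficients beyond 1/d_min.
#'
#' @param model a [glyco_model]; hydrogens are skipped
#' @param d_min resolution cutoff in Angstrom, or `NA` for no band limit
#' @param spacing approximate grid step in Angstrom
#' @param dim explicit grid dimensions (overrides `spacing`)
#' @return a [density_map]
#' @export
calc_model_map <- function(model, d_min = NA, spacing = 0.5, dim = NULL) {
  cell <- model$cell
  if (is.null(dim)) dim <- pmax(4L, as.integer(round(cell[1:3] / spacing)))
  grid <- array(0, dim)
  atoms <- model$atoms
  atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
  Om <- orth_matrix(cell)
  Fm <- frac_matrix(cell)
  # per-axis fractional margin for a Cartesian radius of 1 A
  ax_margin <- sqrt(rowSums(Fm^2))
  for (i in seq_len(nrow(atoms))) {
    cf <- element_coeffs(atoms$element[i])
    if (is.null(cf)) next
    B <- max(atoms$b[i], 1)
    bb <- c(cf$b + B, max(B, 4))
    aa <- c(cf$a, cf$c)
    # cutoff where the widest Gaussian falls to ~1e-4 of its peak
    r_cut <- sqrt(log(1e4) * max(bb)) / (2 * pi)
    fr <- as.numeric(Fm %*% c(atoms$x[i], atoms$y[i], atoms$z[i]))
    lo <- floor((fr - r_cut * ax_margin) * dim)
    hi <- ceiling((fr + r_cut * ax_margin) * dim)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    dfrac <- sweep(box / matrix(dim, nrow(box), 3, byrow = TRUE), 2, fr)
    dcart <- t(Om %*% t(dfrac))
    r2 <- rowSums(dcart^2)
    keep <- r2 <= r_cut^2
    if (!any(keep)) next
    box <- box[keep, , drop = FALSE]
    r2 <- r2[keep]
    rho <- numeric(length(r2))
    for (g in seq_along(aa)) {
      rho <- rho + aa[g] * (4 * pi / bb[g])^1.5 * exp(-4 * pi^2 * r2 / bb[g])
    }
    rho <- rho * atoms$occ[i]
    idx <- cbind(box[, 1] %% dim[1] + 1L, box[, 2] %% dim[2] + 1L,
                 box[, 3] %% dim[3] + 1L)
    # accumulate (duplicates cannot occur inside one atom's box unless the
    # box exceeds the cell; fold duplicates explicitly to stay safe)
    lin <- (idx[, 3] - 1L) * dim[1] * dim[2] + (idx[, 2] - 1L) * dim[1] + idx[, 1]
    add <- rowsum(rho, lin)
    grid[as.integer(rownames(add))] <- grid[as.integer(rownames(add))] + add[, 1]
  }
  out <- density_map(grid, cell)
  if (!is.na(d_min)) out <- band_limit(out, d_min)
  out
}

# Zero all Fourier coefficients with |s| > 1/d_min.
band_limit <- function(map, d_min) {
  dim <- map$dim
  Fm <- frac_matrix(map$cell)
  G <- Fm %*% t(Fm)     # reciprocal metric
  hs <- function(n) { h <- 0:(n - 1); h[h > n / 2] <- h[h > n / 2] - n; h }
  h <- hs(dim[1]); k <- hs(dim[2]); l <- hs(dim[3])
  s2 <- outer(outer(h^2 * G[1, 1], k^2 * G[2, 2], "+"), l^2 * G[3, 3], "+")
  # cross terms (vanish for orthogonal cells)
  if (abs(G[1, 2]) > 1e-12 || abs(G[1, 3]) > 1e-12 || abs(G[2, 3]) > 1e-12) {
    s2 <- s2 + 2 * G[1, 2] * outer(outer(h, k, "*"), rep(1, dim[3]), "*") +
      2 * G[1, 3] * outer(outer(h, rep(1, dim[2]), "*"), l, "*") +
      2 * G[2, 3] * outer(outer(rep(1, dim[1]), k, "*"), l, "*")
  }
  ft <- stats::fft(map$grid)
  ft[s2 > 1 / d_min^2] <- 0
  map$grid <- Re(stats::fft(ft, inverse = TRUE)) / prod(dim)
  map
}

#' Normalize a map to sigma units (mean 0, sd 1 over the cell)
#' @param map a [density_map]
#' @return the normalized [density_map]
#' @export
map_normalize <- function(map) {
  m <- mean(map$grid)
  s <- stats::sd(as.numeric(map$grid))
  if (s < 1e-12) stop("cannot sigma-normalize a flat map")
  map$grid <- (map$grid - m) / s
  map
}

#' Add white Gaussian noise to a map
#' @param map a [density_map]
#' @param sd noise standard deviation (same units as the map values)
#' @return the noisy map
#' @export
map_add_noise <- function(map, sd) {
  map$grid <- map$grid + array(stats::rnorm(prod(map$dim), 0, sd), map$dim)
  map
}

#' Tri-linear periodic interpolation of map values at Cartesian points
#' @param map a [density_map]
#' @param xyz n x 3 matrix of Cartesian positions
#' @return numeric vector of interpolated values
#' @export
map_interpolate <- function(map, xyz) {
  if (is.null(nrow(xyz))) xyz <- matrix(xyz, ncol = 3)
  if (nrow(xyz) == 0L) return(numeric(0))
  fr <- cart_to_frac(xyz, map$cell)
  dim <- map$dim
  g <- sweep(fr, 2, dim, "*")
  i0 <- floor(g)
  w <- g - i0
  val <- numeric(nrow(xyz))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    idx <- cbind((i0[, 1] + dx) %% dim[1] + 1L,
                 (i0[, 2] + dy) %% dim[2] + 1L,
                 (i0[, 3] + dz) %% dim[3] + 1L)
    val <- val + wt * map$grid[idx]
  }
  val
}

# Linear grid indices within `radius` of any of the given Cartesian points.
mask_indices <- function(map, xyz, radius) {
  dim <- map$dim
  Om <- orth_matrix(map$cell)
  Fm <- frac_matrix(map$cell)
  ax_margin <- sqrt(rowSums(Fm^2))
  sel <- integer(0)
  for (i in seq_len(nrow(xyz))) {
    fr <- as.numeric(Fm %*% xyz[i, ])
    lo <- floor((fr - radius * ax_margin) * dim)
    hi <- ceiling((fr + radius * ax_margin) * dim)
    box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    dfrac <- sweep(box / matrix(dim, nrow(box), 3, byrow = TRUE), 2, fr)
    r2 <- rowSums((t(Om %*% t(dfrac)))^2)
    box <- box[r2 <= radius^2, , drop = FALSE]
    if (nrow(box) == 0L) next
    lin <- (box[, 3] %% dim[3]) * dim[1] * dim[2] +
      (box[, 2] %% dim[2]) * dim[1] + (box[, 1] %% dim[1]) + 1L
    sel <- c(sel, lin)
  }
  unique(sel)
}

#' Real-space correlation coefficient of a residue
#'
#' Pearson correlation between observed and calculated map values over grid
#' points within `mask_radius` of any residue atom.
#'
#' @param residue_atoms atom data.frame of the residue (hydrogens ignored)
#' @param map_obs,map_calc [density_map]s on the same grid over the same cell
#' @param mask_radius mask radius in Angstrom
#' @return correlation in [-1, 1], or `NA` with an empty mask
#' @export
rscc <- function(residue_atoms, map_obs, map_calc, mask_radius = 2.0) {
  stopifnot(all(map_obs$dim == map_calc$dim))
  xyz <- atom_xyz(heavy_atoms(residue_atoms))
  if (nrow(xyz) == 0L) return(NA_real_)
  idx <- mask_indices(map_obs, xyz, mask_radius)
  if (length(idx) < 4L) return(NA_real_)
  o <- map_obs$grid[idx]; c_ <- map_calc$grid[idx]
  if (stats::sd(o) < 1e-12 || stats::sd(c_) < 1e-12) return(NA_real_)
  stats::cor(o, c_)
}

# EDIA electron-density radius, computed on the fly from the resolution and
# B factor: the radius where a single-Gaussian atom of total width
# B + B0 + 4 d_min^2 falls to ~5% of its peak. B0 = 15 A^2 approximates the
# intrinsic form-factor width of light elements.
edia_radius <- function(b, resolution) {
  stopifnot(is.finite(resolution), resolution > 0)
  btot <- max(b, 1) + 15 + 4 * resolution^2
  sqrt(log(20) * btot) / (2 * pi)
}

# Radial weight: parabolic positive lobe inside r, negative penumbra to 2r.
edia_weight <- function(d, r) {
  w <- numeric(length(d))
  core <- d <= r
  w[core] <- 1 - (d[core] / r)^2
  pen <- d > r & d <= 2 * r
  x <- d[pen] / r
  w[pen] <- -1.6 * (x - 1) * (2 - x)
  w
}

#' Electron-density support for an individual atom (EDIA)
#'
#' Distance-weighted positive density support within the atom's
#' electron-density radius, with ownership weighting against other model
#' atoms and a penalty for unclaimed density in the penumbra (between one
#' and two radii). Density values are read from a sigma-normalized observed
#' map and capped at 1.2 sigma. The result is floored at zero.
#'
#' @param atom one-row atom data.frame
#' @param map_obs sigma-normalized observed [density_map]
#' @param resolution d_min in Angstrom (required)
#' @param model_atoms heavy-atom table of the full model, used for density
#'   ownership; may be `NULL` to skip ownership weighting
#' @return EDIA value, roughly in [0, 1.2]
#' @export
edia_atom <- function(atom, map_obs, resolution, model_atoms = NULL) {
  if (is.na(resolution)) stop("EDIA needs the data resolution (d_min)")
  r <- edia_radius(atom$b[1], resolution)
  ctr <- c(atom$x[1], atom$y[1], atom$z[1])
  dim <- map_obs$dim
  Om <- orth_matrix(map_obs$cell)
  Fm <- frac_matrix(map_obs$cell)
  ax_margin <- sqrt(rowSums(Fm^2))
  fr <- as.numeric(Fm %*% ctr)
  lo <- floor((fr - 2 * r * ax_margin) * dim)
  hi <- ceiling((fr + 2 * r * ax_margin) * dim)
  box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  dfrac <- sweep(box / matrix(dim, nrow(box), 3, byrow = TRUE), 2, fr)
  pcart <- t(Om %*% t(dfrac))
  dd <- sqrt(rowSums(pcart^2))
  keep <- dd <= 2 * r
  box <- box[keep, , drop = FALSE]; dd <- dd[keep]; pcart <- pcart[keep, , drop = FALSE]
  if (nrow(box) == 0L) return(0)
  lin <- (box[, 3] %% dim[3]) * dim[1] * dim[2] +
    (box[, 2] %% dim[2]) * dim[1] + (box[, 1] %% dim[1]) + 1L
  z <- map_obs$grid[lin]
  zc <- pmax(pmin(z / 1.2, 1), -1)
  w <- edia_weight(dd, r)
  # ownership: a core point belongs to this atom unless another model atom
  # is relatively closer (smaller d / r_b); penumbra density is unclaimed
  # when no model atom covers the point within its own radius.
  own <- rep(1, length(dd))
  covered_by_other <- rep(FALSE, length(dd))
  if (!is.null(model_atoms) && nrow(model_atoms) > 0) {
    oxyz <- atom_xyz(model_atoms)
    # periodic-free treatment: models used here fit inside the cell
    near <- which(rowSums(sweep(oxyz, 2, ctr)^2) < (4 * r)^2)
    same <- abs(oxyz[near, 1] - ctr[1]) < 1e-9 &
      abs(oxyz[near, 2] - ctr[2]) < 1e-9 & abs(oxyz[near, 3] - ctr[3]) < 1e-9
    near <- near[!same]
    if (length(near) > 0) {
      pabs <- sweep(pcart, 2, ctr, "+")
      d_other <- sqrt(cross_dist2(pabs, oxyz[near, , drop = FALSE]))
      r_other <- vapply(near, function(j)
        edia_radius(model_atoms$b[j], resolution), numeric(1))
      rel_other <- sweep(d_other, 2, r_other, "/")
      own[apply(rel_other, 1, min) < dd / r] <- 0
      covered_by_other <- apply(rel_other <= 1, 1, any)
    }
  }
  unclaimed <- (dd > r) & !covered_by_other
  core <- w > 0
  den <- sum(w[core])
  if (den < 1e-9) return(0)
  support <- sum(w[core] * own[core] * zc[core]) / den
  pen_idx <- w < 0 & unclaimed
  pen_den <- sum(abs(w[w < 0]))
  penalty <- if (pen_den > 1e-9)
    sum(abs(w[pen_idx]) * pmax(zc[pen_idx], 0)) / pen_den else 0
  max(0, support - 0.5 * penalty)
}

#' Power-mean EDIA aggregate over a residue (EDIAm)
#'
#' @param edias per-atom EDIA values
#' @param p power-mean exponent (published definition: -2)
#' @return EDIAm; 0 if any atom has (near) zero support
#' @export
ediam <- function(edias, p = -2) {
  edias <- edias[is.finite(edias)]
  if (length(edias) == 0L) return(NA_real_)
  if (any(edias < 1e-6)) return(0)
  mean(edias^p)^(1 / p)
}

#' Score configuration for carbohydrate acceptance
#'
#' Defaults encode the empirical acceptance rules: RSCC at least 0.70, or
#' RSCC + EDIAm greater than 1.20, or (at resolution better than 3.0
#' Angstrom) RSCC in [0.60, 0.70) with a density ratio of at least 0.25;
#' plus rejection on a < 2.1 Angstrom clash with symmetry copies. All
#' metrics are computed with carbohydrate B factors set to 30.0 Angstrom^2.
#'
#' @param b_override B factor applied to carbohydrates during scoring
#' @param rscc_accept unconditional RSCC acceptance threshold
#' @param sum_accept threshold on RSCC + EDIAm
#' @param rscc_borderline_low lower edge of the borderline RSCC band
#' @param ratio_accept density-ratio threshold in the borderline band
#' @param ratio_resolution_cutoff borderline rule only applies at resolution
#'   better than this (Angstrom)
#' @param sym_clash symmetry-clash rejection distance (Angstrom)
#' @return list of class `score_config`
#' @export
score_config <- function(b_override = 30.0, rscc_accept = 0.70,
                         sum_accept = 1.20, rscc_borderline_low = 0.60,
                         ratio_accept = 0.25, ratio_resolution_cutoff = 3.0,
                         sym_clash = 2.1) {
  stopifnot(rscc_borderline_low < rscc_accept)
  structure(list(b_override = b_override, rscc_accept = rscc_accept,
                 sum_accept = sum_accept,
                 rscc_borderline_low = rscc_borderline_low,
                 ratio_accept = ratio_accept,
                 ratio_resolution_cutoff = ratio_resolution_cutoff,
                 sym_clash = sym_clash), class = "score_config")
}

#' Density scores for carbohydrate residues
#'
#' Recomputes a model map with every carbohydrate B factor overridden to
#' `cfg$b_override`, then reports per residue the RSCC against the observed
#' map, EDIAm over the residue's heavy atoms, and the density ratio (mean
#' observed density at residue atoms over mean observed density at protein
#' main-chain N, CA, C, O atoms).
#'
#' @param model a [glyco_model]
#' @param keys residue keys to score
#' @param map_obs observed [density_map] (sigma-normalized internally)
#' @param cfg a [score_config()]
#' @param d_min resolution; defaults to `model$resolution`
#' @param mask_radius RSCC mask radius
#' @return data.frame: `key`, `rscc`, `ediam`, `density_ratio`, `b_override`
#' @export
score_residues <- function(model, keys, map_obs, cfg = score_config(),
                           d_min = model$resolution, mask_radius = 2.0) {
  if (length(keys) == 0L)
    return(data.frame(key = character(), rscc = numeric(), ediam = numeric(),
                      density_ratio = numeric(), b_override = numeric(),
                      stringsAsFactors = FALSE))
  work <- model
  is_carb <- work$atoms$comp %in% PYRANOSE_COMPS
  work$atoms$b[is_carb] <- cfg$b_override
  obs <- map_normalize(map_obs)
  mcalc <- calc_model_map(work, d_min = d_min, dim = map_obs$dim)
  mc_atoms <- work$atoms[!work$atoms$het &
                           work$atoms$comp %in% AMINO_ACIDS &
                           work$atoms$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  mc_mean <- if (nrow(mc_atoms) == 0) NA_real_ else
    mean(map_interpolate(obs, atom_xyz(mc_atoms)))
  heavy_all <- heavy_atoms(work$atoms)
  out <- data.frame(key = keys, rscc = NA_real_, ediam = NA_real_,
                    density_ratio = NA_real_, b_override = cfg$b_override,
                    stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    at <- heavy_atoms(residue_atoms(work, keys[i]))
    if (nrow(at) == 0L) next
    out$rscc[i] <- rscc(at, obs, mcalc, mask_radius)
    ed <- vapply(seq_len(nrow(at)), function(j)
      edia_atom(at[j, , drop = FALSE], obs, d_min, heavy_all), numeric(1))
    out$ediam[i] <- ediam(ed)
    if (!is.na(mc_mean) && abs(mc_mean) > 1e-9)
      out$density_ratio[i] <- mean(map_interpolate(obs, atom_xyz(at))) / mc_mean
  }
  out
}
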