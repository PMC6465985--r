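one_atom_model <- function(pos = c(10, 10, 10), element = "C", b = 30,
                           cell = c(20, 20, 20, 90, 90, 90), occ = 1) {
  at <- point_atoms(matrix(pos, 1), comp = "LIG", name = "C1",
                    element = element, b = b)
  at$occ <- occ
  glyco_model(at, cell = cell)
}

test_that("a single atom gives a peak at its site that weakens with B", {
  m <- one_atom_model(b = 30)
  mp <- calc_model_map(m, spacing = 0.4)
  ctr <- map_interpolate(mp, matrix(c(10, 10, 10), 1))
  expect_gt(ctr, map_interpolate(mp, matrix(c(11.5, 10, 10), 1)))
  # spherical symmetry: equal values at equal radii
  probes <- rbind(c(11, 10, 10), c(10, 11, 10), c(10, 10, 11))
  v <- map_interpolate(mp, probes)
  expect_lt(diff(range(v)), 0.02 * max(v))
  # doubling B lowers the peak and widens the profile
  mp2 <- calc_model_map(one_atom_model(b = 60), spacing = 0.4)
  expect_lt(max(mp2$grid), max(mp$grid))
  hm <- function(map, peak) {   # radius where density halves
    r <- seq(0.1, 3, 0.05)
    v <- map_interpolate(map, cbind(10 + r, 10, 10))
    r[which.min(abs(v - peak / 2))]
  }
  expect_gt(hm(mp2, max(mp2$grid)), hm(mp, max(mp$grid)))
})

test_that("map synthesis is linear: two disjoint atoms equal the sum of singles", {
  m1 <- one_atom_model(c(6, 10, 10))
  m2 <- one_atom_model(c(14, 10, 10))
  both <- glyco_model(rbind(m1$atoms, point_atoms(matrix(c(14, 10, 10), 1),
                                                  comp = "LIG", name = "C1",
                                                  element = "C", b = 30,
                                                  seq_start = 2L)),
                      cell = m1$cell)
  g12 <- calc_model_map(both, spacing = 0.5)$grid
  gsum <- calc_model_map(m1, spacing = 0.5)$grid +
    calc_model_map(m2, spacing = 0.5)$grid
  expect_lt(max(abs(g12 - gsum)), 1e-10)
})

test_that("occupancy scales density linearly and band-limiting keeps the peak centred", {
  g1 <- calc_model_map(one_atom_model(occ = 1), spacing = 0.5)$grid
  gh <- calc_model_map(one_atom_model(occ = 0.5), spacing = 0.5)$grid
  expect_lt(max(abs(g1 / 2 - gh)), 1e-10)
  mp <- calc_model_map(one_atom_model(), d_min = 2.0, spacing = 0.5)
  idx <- which(mp$grid == max(mp$grid), arr.ind = TRUE)[1, ]
  expect_equal(unname(idx), c(21, 21, 21))   # grid point at (10,10,10)
})

test_that("an unknown element falls back to nitrogen-like factors with a warning", {
  m <- one_atom_model(element = "XX")
  expect_warning(mp <- calc_model_map(m, spacing = 0.6), "nitrogen-like")
  mn <- suppressWarnings(calc_model_map(one_atom_model(element = "N"), spacing = 0.6))
  expect_equal(mp$grid, mn$grid)
})

test_that("model-map synthesis is equivariant under rigid motion of the model", {
  fx <- cached_fixture(11)
  m <- fx$truth
  # a grid-commensurate translation makes the check exact up to accumulation
  dims <- pmax(4L, as.integer(round(m$cell[1:3] / 0.5)))
  shift <- 2 * m$cell[1:3] / dims
  m2 <- m
  m2$atoms$x <- m2$atoms$x + shift[1]
  m2$atoms$y <- m2$atoms$y + shift[2]
  m2$atoms$z <- m2$atoms$z + shift[3]
  mp1 <- calc_model_map(m, spacing = 0.5)
  mp2 <- calc_model_map(m2, spacing = 0.5)
  probes <- recarb:::atom_xyz(m$atoms[seq(1, nrow(m$atoms), 7), ])
  v1 <- map_interpolate(mp1, probes)
  v2 <- map_interpolate(mp2, sweep(probes, 2, shift, "+"))
  expect_lt(max(abs(v1 - v2)), 1e-3 * max(abs(v1)))
})

test_that("RSCC is 1 against the map's own model and invariant to affine rescaling", {
  fx <- cached_fixture(11)
  m <- fx$truth
  mp <- calc_model_map(m, d_min = 2.0, spacing = 0.5)
  res_at <- recarb:::residue_atoms(m, fx$tree_keys[1])
  expect_gte(rscc(res_at, mp, mp), 0.999)
  mp2 <- mp; mp2$grid <- 3.7 * mp2$grid + 1.2
  expect_gte(rscc(res_at, mp2, mp), 0.999)
})

test_that("RSCC against pure noise is near zero", {
  fx <- cached_fixture(11)
  m <- fx$truth
  mp <- calc_model_map(m, d_min = 2.0, spacing = 0.5)
  set.seed(5)
  noise <- density_map(array(stats::rnorm(prod(mp$dim)), mp$dim), mp$cell)
  res_at <- recarb:::residue_atoms(m, fx$tree_keys[1])
  idx <- recarb:::mask_indices(mp, recarb:::atom_xyz(recarb:::heavy_atoms(res_at)), 2.5)
  expect_gt(length(idx), 500)
  expect_lt(abs(rscc(res_at, noise, mp, mask_radius = 2.5)), 0.2)
})

test_that("empty residues give an undefined RSCC rather than a number", {
  fx <- cached_fixture(11)
  mp <- calc_model_map(fx$truth, spacing = 0.7)
  empty <- fx$truth$atoms[0, ]
  expect_true(is.na(rscc(empty, mp, mp)))
})

test_that("EDIA rewards self-density and floors at zero elsewhere", {
  m <- one_atom_model(b = 30)
  mp <- map_normalize(calc_model_map(m, d_min = 2.0, spacing = 0.4))
  at <- m$atoms[1, ]
  expect_gt(edia_atom(at, mp, 2.0, m$atoms), 0.8)
  zero <- density_map(array(stats::rnorm(40^3, 0, 1e-3), c(40, 40, 40)), m$cell)
  expect_lt(edia_atom(at, zero, 2.0, m$atoms), 0.05)
  neg <- density_map(array(-1, c(40, 40, 40)) +
                       array(stats::rnorm(40^3, 0, 1e-3), c(40, 40, 40)), m$cell)
  expect_equal(edia_atom(at, neg, 2.0, m$atoms), 0)
  expect_error(edia_atom(at, mp, NA), "resolution|d_min")
})

test_that("EDIAm is a power mean with exponent -2: bounded by min and max", {
  e <- c(0.9, 0.8, 0.5, 0.7)
  v <- ediam(e)
  expect_lt(v, max(e))
  expect_gt(v, min(e) - 1e-12)
  expect_lte(v, mean(e))
  # dominated by a weak atom; removing the minimum never decreases it
  expect_gte(ediam(e[-which.min(e)]), v)
  expect_equal(ediam(c(0.8, 0)), 0)
  expect_equal(ediam(c(0.6, 0.6, 0.6)), 0.6, tolerance = 1e-12)
})

test_that("scores are independent of incoming carbohydrate B factors", {
  fx <- cached_fixture(11)
  m <- fx$working
  sc1 <- score_residues(m, fx$tree_keys[1:2], fx$map, d_min = 2.0)
  m2 <- m
  sel <- m2$atoms$comp %in% recarb:::PYRANOSE_COMPS
  m2$atoms$b[sel] <- stats::runif(sum(sel), 5, 150)
  sc2 <- score_residues(m2, fx$tree_keys[1:2], fx$map, d_min = 2.0)
  expect_equal(sc1$rscc, sc2$rscc, tolerance = 1e-12)
  expect_equal(sc1$ediam, sc2$ediam, tolerance = 1e-12)
  expect_equal(sc1$density_ratio, sc2$density_ratio, tolerance = 1e-12)
})

test_that("scores separate residues on their true density from displaced ones", {
  fx <- cached_fixture(11)
  sc <- score_residues(fx$working, fx$tree_keys, fx$map, d_min = 2.0)
  expect_true(all(sc$rscc >= 0.9))
  # displace one residue into bulk solvent
  m2 <- fx$working
  k <- fx$tree_keys[5]
  sel <- rkeys_of(m2$atoms) == k
  ctr_all <- colMeans(recarb:::atom_xyz(m2$atoms))
  ctr_res <- colMeans(recarb:::atom_xyz(m2$atoms[sel, ]))
  u <- (ctr_res - ctr_all) / sqrt(sum((ctr_res - ctr_all)^2))
  m2$atoms$x[sel] <- m2$atoms$x[sel] + 5 * u[1]
  m2$atoms$y[sel] <- m2$atoms$y[sel] + 5 * u[2]
  m2$atoms$z[sel] <- m2$atoms$z[sel] + 5 * u[3]
  sc2 <- score_residues(m2, k, fx$map, d_min = 2.0)
  expect_lt(sc2$rscc, 0.3)
})

test_that("the density ratio of main-chain atoms against themselves is 1", {
  fx <- cached_fixture(11)
  m <- fx$working
  obs <- map_normalize(fx$map)
  mc <- m$atoms[!m$atoms$het & m$atoms$name %in% c("N", "CA", "C", "O"), ]
  v <- mean(map_interpolate(obs, recarb:::atom_xyz(mc)))
  expect_equal(v / v, 1.0)
  # and score_residues uses exactly that denominator
  sc <- score_residues(m, fx$tree_keys[1], fx$map, d_min = 2.0)
  at <- recarb:::heavy_atoms(recarb:::residue_atoms(m, fx$tree_keys[1]))
  expect_equal(sc$density_ratio,
               mean(map_interpolate(obs, recarb:::atom_xyz(at))) / v,
               tolerance = 1e-9)
})
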