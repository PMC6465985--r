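test_that("place_residue recovers a beta1-4 NAG from a map synthesized at its true position", {
  fx <- cached_fixture(11)
  obs <- fx$map            # already sigma-normalized
  parent <- fx$tree_keys[1]
  truth_child <- fx$tree_keys[2]
  m <- fx$truth
  # remove the true child and everything downstream (as cropping would)
  m2 <- recarb:::remove_residues(m, fx$tree_keys[2:5])
  res <- place_residue(m2, parent, list(position = 4, child = "NAG"), obs)
  expect_true(res$accepted)
  ta <- recarb:::residue_atoms(fx$truth, truth_child)
  common <- intersect(res$atoms$name, ta$name)
  d <- as.matrix(res$atoms[match(common, res$atoms$name), c("x", "y", "z")]) -
    as.matrix(ta[match(common, ta$name), c("x", "y", "z")])
  expect_lt(sqrt(mean(rowSums(d^2))), 0.8)
})

test_that("placement into an empty map is rejected with near-zero fit", {
  fx <- cached_fixture(11)
  m2 <- recarb:::remove_residues(fx$truth, fx$tree_keys[2:5])
  zero <- density_map(array(stats::rnorm(prod(fx$map$dim), 0, 1e-4), fx$map$dim),
                      fx$map$cell)
  res <- place_residue(m2, fx$tree_keys[1], list(position = 4, child = "NAG"), zero)
  expect_false(res$accepted)
  expect_lt(res$fit, 0.1)
})

test_that("a placement that collides with existing structure is rejected by the clash rule", {
  fx <- cached_fixture(11)
  m2 <- recarb:::remove_residues(fx$truth, fx$tree_keys[2:5])
  # drop blocking atoms right onto the true child's site
  ta <- recarb:::residue_atoms(fx$truth, fx$tree_keys[2])
  blocker <- point_atoms(recarb:::atom_xyz(ta)[1:4, ], chain = "Z",
                         comp = "HOH", name = "O", element = "O")
  m2$atoms <- rbind(m2$atoms, blocker)
  res <- place_residue(m2, fx$tree_keys[1], list(position = 4, child = "NAG"),
                       fx$map)
  expect_false(res$accepted)
})

test_that("extend_tree rebuilds the core from a bare sequon and terminates", {
  fx <- cached_fixture(11, crop = "all")
  td <- load_tree_types()[["high-mannose"]]
  gr <- extend_tree(fx$working, fx$asn, NULL, td, fx$map)
  expect_gte(length(gr$new_keys), 4L)
  # every built residue validates as a correct chair
  v <- recarb:::validate_rings(gr$model, gr$new_keys)
  expect_true(all(v$status == "yes"))
  # determinism: identical inputs give identical trees
  gr2 <- extend_tree(fx$working, fx$asn, NULL, td, fx$map)
  expect_identical(gr$model$atoms, gr2$model$atoms)
  expect_identical(gr$new_keys, gr2$new_keys)
})

test_that("a tree already complete for its grammar grows by nothing new at core positions", {
  fx <- cached_fixture(11)
  td <- load_tree_types()[["high-mannose"]]
  ext <- extract_trees(fx$truth)
  gr <- extend_tree(fx$truth, fx$asn, ext$trees[[1]], td, fx$map)
  # core is closed; anything extra must be non-core (arm mannose or fucose)
  expect_true(all(!(gr$edges$position %in% 4) |
                    gr$edges$parent != fx$asn))
  comps <- vapply(gr$new_keys, function(k)
    recarb:::residue_comp(gr$model, k), "")
  expect_true(all(comps %in% c("MAN", "FUC")))
})

test_that("growth stops where the density stops: a truncated map yields only the first NAG", {
  fx <- cached_fixture(13, crop = "all")
  # build a map from the root NAG alone
  m_nag <- fx$truth
  keep <- c(setdiff(unique(rkeys_of(m_nag$atoms)), fx$tree_keys), fx$tree_keys[1])
  m_nag <- recarb:::remove_residues(m_nag, setdiff(fx$tree_keys, fx$tree_keys[1]))
  map1 <- map_normalize(calc_model_map(m_nag, d_min = 2.0, spacing = 0.5))
  td <- load_tree_types()[["high-mannose"]]
  gr <- extend_tree(fx$working, fx$asn, NULL, td, map1)
  comps <- vapply(gr$new_keys, function(k) recarb:::residue_comp(gr$model, k), "")
  expect_equal(unname(comps), "NAG")
  expect_equal(gr$edges$position, 0L)
})

test_that("monotone map response: added density never demotes an accepted placement", {
  fx <- cached_fixture(11)
  m2 <- recarb:::remove_residues(fx$truth, fx$tree_keys[2:5])
  res <- place_residue(m2, fx$tree_keys[1], list(position = 4, child = "NAG"),
                       fx$map)
  boosted <- fx$map
  boosted$grid <- boosted$grid + 0.5
  res2 <- place_residue(m2, fx$tree_keys[1], list(position = 4, child = "NAG"),
                        boosted)
  expect_true(res$accepted)
  expect_true(res2$accepted)
  expect_gt(res2$fit, res$fit)
})

test_that("a missing attachment frame yields a placement-impossible signal", {
  fx <- cached_fixture(11)
  m <- fx$truth
  # strip the O4 from the root NAG
  sel <- rkeys_of(m$atoms) == fx$tree_keys[1] & m$atoms$name == "O4"
  m$atoms <- m$atoms[!sel, ]
  res <- place_residue(m, fx$tree_keys[1], list(position = 4, child = "NAG"),
                       fx$map)
  expect_null(res)
})

test_that("templates close their rings and carry all heavy atoms", {
  for (comp in names(recarb:::SUGAR_CONFIG)) {
    t1 <- sugar_template(comp)
    rownames(t1) <- t1$name
    d <- recarb:::vnorm(as.numeric(t1["O5", c("x", "y", "z")]) -
                          as.numeric(t1["C1", c("x", "y", "z")]))
    expect_gt(d, 1.3); expect_lt(d, 1.5)
    expect_true(all(c("O5", "C1", "C2", "C3", "C4", "C5", "C6", "O3") %in% t1$name),
                info = comp)
    # adjacent ring bonds all near 1.43
    ring <- as.matrix(t1[recarb:::RING_ATOM_ORDER, c("x", "y", "z")])
    for (i in 1:6) {
      j <- i %% 6 + 1
      expect_equal(recarb:::vnorm(ring[i, ] - ring[j, ]), 1.43, tolerance = 0.02)
    }
  }
})
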