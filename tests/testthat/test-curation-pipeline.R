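# Helpers building controlled tree/status scenarios from the fixture.

fixture_tree <- function(fx) extract_trees(fx$truth)$trees[[1]]

fake_statuses <- function(keys, statuses) {
  data.frame(key = keys, comp = NA, Q = NA, theta = NA, phi = NA,
             status = statuses, reasons = "", stringsAsFactors = FALSE)
}

test_that("cropping removes check/no residues and all their descendants", {
  fx <- cached_fixture(11)
  tr <- fixture_tree(fx)
  # linear chain: root NAG yes, second NAG no, BMA yes -> 2..5 go
  st <- fake_statuses(fx$tree_keys, c("yes", "no", "yes", "yes", "yes"))
  cr <- crop_poor_residues(fx$truth, list(tr), st)
  expect_setequal(cr$deleted, fx$tree_keys[2:5])
  expect_length(cr$full_delete_sites, 0L)
  left <- recarb:::model_residues(cr$model)
  expect_true(fx$tree_keys[1] %in% left$key)
  expect_equal(unname(cr$delete_reason[fx$tree_keys[2]]), "poor_or_nonstandard")
  expect_equal(unname(cr$delete_reason[fx$tree_keys[3]]), "descendant_of_deleted")

  # all-yes tree: nothing deleted
  st2 <- fake_statuses(fx$tree_keys, rep("yes", 5))
  cr2 <- crop_poor_residues(fx$truth, list(tr), st2)
  expect_length(cr2$deleted, 0L)

  # poor root: whole tree deleted, site queued for whole-tree addition
  st3 <- fake_statuses(fx$tree_keys, c("no", "yes", "yes", "yes", "yes"))
  cr3 <- crop_poor_residues(fx$truth, list(tr), st3)
  expect_setequal(cr3$deleted, fx$tree_keys)
  expect_equal(cr3$full_delete_sites, fx$asn)
})

test_that("nonstandard residues are cropped even when their rings are pristine", {
  fx <- cached_fixture(11)
  m <- fx$truth
  m$atoms$comp[rkeys_of(m$atoms) == fx$tree_keys[4]] <- "LXZ"
  tr <- extract_trees(m)$trees[[1]]
  st <- fake_statuses(fx$tree_keys, rep("yes", 5))
  cr <- crop_poor_residues(m, list(tr), st)
  expect_true(fx$tree_keys[4] %in% cr$deleted)
  expect_false(fx$tree_keys[5] %in% cr$deleted)  # MAN alpha1-6 is a sibling
})

test_that("blocking molecules are parked by type and proximity; waters always", {
  fx <- cached_fixture(11)
  m <- fx$truth
  nd2 <- recarb:::get_atom(m, fx$asn, "ND2")
  # unlinked MAN 2 A away: parked; unlinked GLC: kept; waters: all parked
  man <- sugar_template("MAN")
  m <- recarb:::place_sugar_near(m, fx$asn, 2.0, "away", comp = "MAN",
                                 keep_leaving = TRUE, seqno = 501L)
  glc <- sugar_template("GLC")
  m$atoms <- rbind(m$atoms,
                   data.frame(chain = "A", seq = 502L, ins = "", comp = "GLC",
                              name = glc$name, element = glc$element,
                              x = glc$x + 5, y = glc$y + 5, z = glc$z + 5,
                              occ = 1, b = 30, altloc = "", het = TRUE,
                              stringsAsFactors = FALSE),
                   water_atom("W", 1, 2, 2, 2),
                   water_atom("W", 2, 30, 20, 30))
  cb <- clear_blocking_molecules(m, fx$asn)
  expect_true("A|501|" %in% cb$parked$single_carbs)
  expect_false("A|502|" %in% cb$parked$single_carbs)
  expect_setequal(cb$parked$waters, c("W|1|", "W|2|"))
  left <- recarb:::model_residues(cb$model)
  expect_false(any(left$comp == "HOH"))
  expect_true("A|502|" %in% left$key)
})

test_that("a detached carbohydrate chain is parked only when near a site of interest", {
  fx <- cached_fixture(11)
  m <- fx$truth
  # fabricate a detached NAG-NAG chain right next to the Asn
  nd2 <- recarb:::get_atom(m, fx$asn, "ND2")
  t1 <- sugar_template("NAG")
  mk <- function(seq, off) data.frame(
    chain = "D", seq = seq, ins = "", comp = "NAG", name = t1$name,
    element = t1$element, x = t1$x + off[1], y = t1$y + off[2],
    z = t1$z + off[3], occ = 1, b = 30, altloc = "", het = TRUE,
    stringsAsFactors = FALSE)
  m$atoms <- rbind(m$atoms, mk(1L, nd2 + c(2.2, 0, 0)), mk(2L, nd2 + c(2.2, 0, 6)))
  m$links <- rbind(m$links, link_row("D", 1, "O6", "D", 2, "C1"))
  cb <- clear_blocking_molecules(m, fx$asn)
  expect_length(cb$parked$chains, 1L)
  expect_setequal(cb$parked$chains[[1]], c("D|1|", "D|2|"))

  # far away: stays
  m2 <- fx$truth
  m2$atoms <- rbind(m2$atoms, mk(1L, nd2 + c(12, 0, 0)), mk(2L, nd2 + c(12, 0, 6)))
  m2$links <- rbind(m2$links, link_row("D", 1, "O6", "D", 2, "C1"))
  cb2 <- clear_blocking_molecules(m2, fx$asn)
  expect_length(cb2$parked$chains, 0L)
})

test_that("the density acceptance rule matches its published cutoffs", {
  cfg <- score_config()
  expect_true(accept_density_rule(0.70, 0.10, 0, 2.0, cfg))
  expect_true(accept_density_rule(0.55, 0.70, 0, 2.0, cfg))    # sum 1.25
  expect_false(accept_density_rule(0.55, 0.60, 0, 2.0, cfg))   # sum 1.15
  expect_true(accept_density_rule(0.65, 0.20, 0.30, 2.2, cfg)) # borderline band
  expect_false(accept_density_rule(0.65, 0.20, 0.30, 3.5, cfg))# low resolution
  expect_false(accept_density_rule(0.65, 0.20, 0.20, 2.2, cfg))# ratio too low
  expect_false(accept_density_rule(NA, 0.9, 0.9, 2.0, cfg))
})

test_that("best-tree choice follows yes, then check, then size, then prefers new", {
  expect_equal(choose_best_tree(c(3, 0, 3), c(4, 0, 4)), "new")
  expect_equal(choose_best_tree(c(4, 0, 4), c(3, 0, 3)), "old")
  expect_equal(choose_best_tree(c(3, 1, 4), c(3, 0, 3)), "old")
  expect_equal(choose_best_tree(c(3, 0, 3), c(3, 1, 4)), "new")
  expect_equal(choose_best_tree(c(3, 1, 5), c(3, 1, 4)), "old")
  expect_equal(choose_best_tree(c(3, 1, 4), c(3, 1, 5)), "new")
  expect_equal(choose_best_tree(c(3, 1, 4), c(3, 1, 4)), "new")
  expect_equal(choose_best_tree(c(0, 0, 0), c(1, 0, 1)), "new")
  expect_equal(choose_best_tree(c(1, 0, 1), c(0, 0, 0)), "old")
  expect_equal(choose_best_tree(c(0, 0, 0), c(0, 0, 0)), "new")
  expect_equal(choose_best_tree(c(2, 2, 4), c(2, 3, 5)), "new")
  expect_equal(choose_best_tree(c(2, 3, 5), c(2, 2, 4)), "old")
})

test_that("grafting restores propagation-deleted branches within geometric bounds", {
  fx <- cached_fixture(14)
  tr <- fixture_tree(fx)
  # crop: second NAG is bad; BMA and the two MANs fall by propagation
  st <- fake_statuses(fx$tree_keys, c("yes", "no", "yes", "yes", "yes"))
  cr <- crop_poor_residues(fx$truth, list(tr), st)
  model <- cr$model
  # a map truncated after the second NAG: only that residue can rebuild,
  # leaving the old BMA/MAN branch to the grafting step
  m_cut <- recarb:::remove_residues(fx$truth, fx$tree_keys[3:5])
  map_cut <- map_normalize(calc_model_map(m_cut, d_min = 2.0, spacing = 0.5))
  td <- load_tree_types()[["high-mannose"]]
  gr <- extend_tree(model, fx$asn, extract_trees(model)$trees[[1]], td, map_cut)
  expect_equal(length(gr$new_keys), 1L)
  rebuilt <- gr$new_keys[1]
  expect_equal(recarb:::residue_comp(gr$model, rebuilt), "NAG")
  status_map <- stats::setNames(st$status, st$key)
  cur_edges <- rbind(tr$edges[tr$edges$child == fx$tree_keys[1], , drop = FALSE],
                     gr$edges[gr$edges$child == rebuilt, , drop = FALSE])
  g <- graft_tree(gr$model, tr$edges, cur_edges, cr$store, status_map,
                  cr$delete_reason, gr$new_keys)
  expect_true(fx$tree_keys[3] %in% g$grafted)      # BMA comes back
  expect_true(all(fx$tree_keys[4:5] %in% g$grafted))
  expect_gte(nrow(g$links_added), 1L)

  # displaced rebuild: no graft
  m2 <- gr$model
  sel <- rkeys_of(m2$atoms) == rebuilt
  m2$atoms$x[sel] <- m2$atoms$x[sel] + 3.0
  g2 <- graft_tree(m2, tr$edges, cur_edges, cr$store, status_map,
                   cr$delete_reason, gr$new_keys)
  expect_length(g2$grafted, 0L)

  # overlapping old branch: no graft (clash < 2.0 with a new residue)
  m3 <- gr$model
  store3 <- cr$store
  bma <- fx$tree_keys[3]
  sel3 <- rkeys_of(store3$atoms) == bma
  newat <- recarb:::residue_atoms(m3, rebuilt)
  store3$atoms$x[sel3] <- newat$x[seq_len(sum(sel3)) %% nrow(newat) + 1] + 0.5
  store3$atoms$y[sel3] <- newat$y[seq_len(sum(sel3)) %% nrow(newat) + 1]
  store3$atoms$z[sel3] <- newat$z[seq_len(sum(sel3)) %% nrow(newat) + 1]
  g3 <- graft_tree(m3, tr$edges, cur_edges, store3, status_map,
                   cr$delete_reason, gr$new_keys)
  expect_false(bma %in% g3$grafted)
})

test_that("restoration honours the 2.5 A clash rule, per unit for chains", {
  fx <- cached_fixture(11)
  m <- fx$truth
  new_key <- fx$tree_keys[5]
  at5 <- recarb:::residue_atoms(m, new_key)
  pos <- c(at5$x[1], at5$y[1], at5$z[1])
  parked <- list(
    waters = c("W|1|", "W|2|"),
    single_carbs = character(),
    chains = list(c("D|1|", "D|2|")),
    store = list(
      atoms = rbind(water_atom("W", 1, pos[1] + 3.0, pos[2], pos[3]),
                    water_atom("W", 2, pos[1] + 2.0, pos[2], pos[3]),
                    # chain: one unit clashes, one far away
                    water_chain_unit("D", 1L, pos + c(1.5, 0, 0)),
                    water_chain_unit("D", 2L, pos + c(12, 0, 0))),
      links = link_row("D", 1, "O4", "D", 2, "C1")))
  rp <- restore_parked(m, parked, new_key)
  expect_true("W|1|" %in% rp$restored)
  expect_true("W|2|" %in% rp$dropped)
  expect_true(all(c("D|1|", "D|2|") %in% rp$dropped))  # whole chain stays out
})

test_that("restored identifiers force renumbering of colliding new residues", {
  fx <- cached_fixture(11)
  m <- fx$truth
  new_key <- fx$tree_keys[1]     # pretend the root NAG (A|401|) is newly built
  far <- c(recarb:::residue_atoms(m, new_key)$x[1] + 15, 5, 5)
  parked <- list(waters = "A|401|", single_carbs = character(), chains = list(),
                 store = list(atoms = {
                   w <- water_atom("A", 401, far[1], far[2], far[3])
                   w$seq <- 401L
                   w
                 }, links = recarb:::empty_links()))
  # the parked water shares the id A|401| with the "new" residue
  rp <- restore_parked(m, parked, new_key)
  expect_true("A|401|" %in% rp$restored)
  expect_length(rp$renumbered, 1L)
  newid <- unname(rp$renumbered["A|401|"])
  expect_false(newid == "A|401|")
  rs <- recarb:::model_residues(rp$model)
  expect_false(any(duplicated(rs$key)))
})

test_that("flat-B models get their carbohydrate B factors aligned on restore", {
  fx <- cached_fixture(11)
  m <- fx$truth
  m$flat_b <- 42.0
  parked <- list(waters = character(), single_carbs = character(),
                 chains = list(),
                 store = list(atoms = recarb:::empty_atoms(),
                              links = recarb:::empty_links()))
  rp <- restore_parked(m, parked, character())
  carb <- rp$model$atoms$comp %in% recarb:::PYRANOSE_COMPS
  expect_true(all(rp$model$atoms$b[carb] == 42.0))
  expect_false(all(rp$model$atoms$b[!carb] == 42.0))
})

test_that("the pipeline is a no-op on a model without sequons or carbohydrates", {
  pep <- recarb:::build_peptide(c("GLY", "ALA", "LYS", "ALA", "VAL", "ALA"))
  m <- recarb:::box_model(pep, recarb:::empty_links(), pad = 8, resolution = 2.0)
  map <- map_normalize(calc_model_map(m, d_min = 2.0, spacing = 0.6))
  res <- run_pipeline(m, map)
  expect_length(res$report$built, 0L)
  expect_length(res$report$deleted, 0L)
  expect_equal(recarb:::model_residues(res$model)$key,
               recarb:::model_residues(m)$key)
})

test_that("a chitobiose-linked sequon is skipped for whole-tree addition", {
  fx <- cached_fixture(15, crop = "all")
  m <- fx$working
  # park a CBS stand-in linked to the Asn (ring atoms suffice for the test)
  t1 <- sugar_template("NAG")
  nd2 <- recarb:::get_atom(m, fx$asn, "ND2")
  cbs <- data.frame(chain = "A", seq = 451L, ins = "", comp = "CBS",
                    name = t1$name, element = t1$element,
                    x = t1$x + nd2[1] + 2, y = t1$y + nd2[2],
                    z = t1$z + nd2[3], occ = 1, b = 30, altloc = "",
                    het = TRUE, stringsAsFactors = FALSE)
  m$atoms <- rbind(m$atoms, cbs)
  ak <- recarb:::split_key(fx$asn)[[1]]
  m$links <- rbind(m$links, link_row(ak$chain, ak$seq, "ND2", "A", 451, "C1"))
  res <- run_pipeline(m, fx$map)
  expect_length(res$report$built, 0L)
})

test_that("end-to-end: a cropped tree is rebuilt and the report balances", {
  fx <- cached_fixture(16, crop = "all")
  res <- run_pipeline(fx$working, fx$map)
  rep <- res$report
  expect_gte(length(rep$built), 4L)
  expect_true(all(vapply(rep$verdicts, `[[`, "", "chosen") %in%
                    c("new", "grafted")))
  # conservation: every input residue is kept, deleted or restored
  out_keys <- recarb:::model_residues(res$model)$key
  for (k in rep$input_keys) {
    expect_true(k %in% out_keys || k %in% rep$deleted || k %in% rep$restored,
                info = k)
  }
  # built residues all pass the published filters post hoc
  sc <- score_residues(res$model, rep$built, fx$map, d_min = 2.0)
  st <- recarb:::validate_rings(res$model, rep$built)
  for (i in seq_along(rep$built)) {
    expect_equal(st$status[i], "yes")
    expect_true(accept_density_rule(sc$rscc[i], sc$ediam[i],
                                    sc$density_ratio[i], 2.0))
  }
})

test_that("waters parked during building are restored when they do not clash", {
  fx <- cached_fixture(17, crop = "all")
  m <- fx$working
  # one far water and one sitting inside the future tree envelope
  tree_at <- fx$truth$atoms[rkeys_of(fx$truth$atoms) %in% fx$tree_keys, ]
  inside <- c(tree_at$x[10], tree_at$y[10], tree_at$z[10])
  m$atoms <- rbind(m$atoms, water_atom("W", 1, 3, 3, 3),
                   water_atom("W", 2, inside[1], inside[2], inside[3]))
  res <- run_pipeline(m, fx$map)
  expect_true("W|1|" %in% res$report$restored)
  if (length(res$report$built) >= 2)
    expect_true("W|2|" %in% res$report$deleted)
})
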