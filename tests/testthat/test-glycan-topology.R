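pep_model <- function(sequence, chain = "A", seq_start = 21L) {
  pep <- recarb:::build_peptide(sequence, chain = chain, seq_start = seq_start)
  recarb:::box_model(pep, recarb:::empty_links(), pad = 10)
}

test_that("sequon detection follows the Asn-X-Ser/Thr motif", {
  m <- pep_model(c("GLY", "ALA", "ASN", "GLY", "THR", "ALA"))
  sq <- find_sequons(m)
  expect_equal(nrow(sq), 1L)
  expect_equal(recarb:::residue_comp(m, sq$asn), "ASN")

  expect_equal(nrow(find_sequons(pep_model(c("GLY", "ALA", "ASN", "PRO", "SER", "ALA")))), 0L)
  expect_equal(nrow(find_sequons(pep_model(c("GLY", "ALA", "ASN", "THR", "LYS", "ALA")))), 0L)
})

test_that("an Asn adjacent to a chain break is not a sequon", {
  m <- pep_model(c("GLY", "ALA", "ASN", "GLY", "THR", "ALA"))
  rs <- recarb:::model_residues(m)
  xkey <- rs$key[rs$seq == 24]    # the X position
  m$atoms <- m$atoms[rkeys_of(m$atoms) != xkey, , drop = FALSE]
  expect_equal(nrow(find_sequons(m)), 0L)
})

test_that("find_sequons agrees with the regex oracle on randomized chains", {
  comps <- c("ALA", "GLY", "SER", "THR", "ASN", "PRO", "LYS", "VAL", "LEU")
  set.seed(77)
  for (trial in 1:300) {
    n <- sample(4:9, 1)
    sequence <- sample(comps, n, replace = TRUE)
    m <- pep_model(sequence)
    if (runif(1) < 0.3) {   # introduce a numbering gap -> chain break
      cut <- sample(2:(n - 1), 1)
      sel <- m$atoms$seq >= 20L + cut
      m$atoms$seq[sel] <- m$atoms$seq[sel] + 5L
    }
    expect_setequal(find_sequons(m)$asn, oracle_sequons(m))
  }
})

test_that("tree extraction follows links transitively and reports unattached chains", {
  fx <- cached_fixture(11)
  ext <- extract_trees(fx$truth)
  expect_length(ext$trees, 1L)
  tr <- ext$trees[[1]]
  expect_equal(length(tr$nodes), 5L)
  expect_equal(nrow(tr$edges), 5L)          # root edge + 4 glycosidic
  expect_length(ext$unattached, 0L)

  # NAG-NAG pair with no Asn link: zero trees, one unattached chain of 2
  t1 <- sugar_template("NAG")
  at <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(chain = "A", seq = 400L + i, ins = "", comp = "NAG",
               name = t1$name, element = t1$element,
               x = t1$x + 8 * i, y = t1$y + 10, z = t1$z + 10,
               occ = 1, b = 30, altloc = "", het = TRUE,
               stringsAsFactors = FALSE)
  }))
  m <- glyco_model(at, link_row("A", 401, "O4", "A", 402, "C1"),
                   cell = c(30, 30, 30, 90, 90, 90))
  ext2 <- extract_trees(m)
  expect_length(ext2$trees, 0L)
  expect_length(ext2$unattached, 1L)
  expect_length(ext2$unattached[[1]], 2L)
})

test_that("tree node count equals edge count and trees partition reachable sugars", {
  for (seed in c(11, 12)) {
    fx <- cached_fixture(seed)
    ext <- extract_trees(fx$truth)
    for (tr in ext$trees) {
      expect_equal(length(tr$nodes), nrow(tr$edges))  # incl. the root edge
      expect_false(any(duplicated(tr$nodes)))
    }
    all_nodes <- unlist(lapply(ext$trees, `[[`, "nodes"))
    expect_false(any(duplicated(all_nodes)))
  }
})

test_that("a cycle-forming link is dropped with a warning", {
  fx <- cached_fixture(11)
  m <- fx$truth
  # add a bogus back-link from the BMA O3 to the root NAG C1
  k3 <- fx$tree_keys[3]; k1 <- fx$tree_keys[1]
  p3 <- recarb:::split_key(k3)[[1]]; p1 <- recarb:::split_key(k1)[[1]]
  m$links <- rbind(m$links, link_row(p3$chain, p3$seq, "O3", p1$chain, p1$seq, "C1"))
  expect_warning(ext <- extract_trees(m), "cycle")
  expect_equal(length(ext$trees[[1]]$nodes), 5L)
})

test_that("tree-type selection defaults to high-mannose and follows beyond-core residues", {
  td <- load_tree_types()
  expect_named(td, c("high-mannose", "hybrid-mammal", "complex-mammal",
                     "hybrid-plant", "complex-plant"), ignore.order = TRUE)
  # no trees at all
  fx <- cached_fixture(11)
  expect_equal(select_tree_type(list(), fx$truth, td)$name, "high-mannose")
  # core-only tree
  ext <- extract_trees(fx$truth)
  expect_equal(select_tree_type(ext$trees, fx$truth, td)$name, "high-mannose")
  # a tree with a beta1-2 NAG antenna on an arm mannose matches the
  # hybrid/complex grammars, not high-mannose; ties break mammal-first
  m <- fx$truth
  man3 <- fx$tree_keys[4]
  gr <- recarb:::try_ideal_place(m, man3,
                                 data.frame(position = 2L, child = "NAG",
                                            anomer = "beta", class = "beyond",
                                            stringsAsFactors = FALSE),
                                 sugar_templates())
  ext2 <- extract_trees(gr$model)
  sel <- select_tree_type(ext2$trees, gr$model, td)
  expect_equal(sel$name, "hybrid-mammal")
})

test_that("residue classification flags nonstandard sugars and their descendants", {
  fx <- cached_fixture(11)
  ext <- extract_trees(fx$truth)
  tr <- ext$trees[[1]]
  cls <- classify_residues(tr, fx$truth)
  expect_true(all(cls == "conforming"))

  # corrupt the second NAG into an LXZ-like inverted-chirality analog
  m <- fx$truth
  k2 <- fx$tree_keys[2]
  m$atoms$comp[rkeys_of(m$atoms) == k2] <- "LXZ"
  ext2 <- extract_trees(m)
  cls2 <- classify_residues(ext2$trees[[1]], m)
  expect_equal(unname(cls2[k2]), "nonstandard")
  descendants <- setdiff(fx$tree_keys[-1], k2)
  expect_true(all(cls2[descendants] == "nonstandard"))
  expect_equal(unname(cls2[fx$tree_keys[1]]), "conforming")

  # conforming set is closed under the ancestor relation
  conf <- names(cls2)[cls2 == "conforming"]
  for (k in conf) {
    e <- ext2$trees[[1]]$edges
    up <- e$parent[e$child == k]
    if (length(up) && up %in% names(cls2))
      expect_equal(unname(cls2[up]), "conforming")
  }
})

test_that("an alpha1-6 fucose on the first NAG conforms to the grammars", {
  fx <- cached_fixture(11)
  gr <- recarb:::try_ideal_place(fx$truth, fx$tree_keys[1],
                                 data.frame(position = 6L, child = "FUC",
                                            anomer = "alpha", class = "fucose",
                                            stringsAsFactors = FALSE),
                                 sugar_templates())
  expect_false(is.null(gr))
  ext <- extract_trees(gr$model)
  tr <- ext$trees[[1]]
  comps <- vapply(tr$nodes, function(k) recarb:::residue_comp(gr$model, k), "")
  expect_true("FUC" %in% comps)
  cls <- classify_residues(tr, gr$model)
  expect_true(all(cls == "conforming"))
})
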