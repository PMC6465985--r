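# Shared helpers: small model builders and independent brute-force oracles.
# The oracles deliberately re-derive results from first principles and stay
# independent of the implementation paths they check.

rkey <- recarb:::res_key
rkeys_of <- recarb:::res_key_of

water_atom <- function(chain, seq, x, y, z) {
  data.frame(chain = chain, seq = as.integer(seq), ins = "", comp = "HOH",
             name = "O", element = "O", x = x, y = y, z = z, occ = 1, b = 20,
             altloc = "", het = TRUE, stringsAsFactors = FALSE)
}

point_atoms <- function(xyz, chain = "A", comp = "HOH", name = "O",
                        element = "O", b = 20, seq_start = 1L) {
  n <- nrow(xyz)
  data.frame(chain = chain, seq = seq_start + seq_len(n) - 1L, ins = "",
             comp = comp, name = name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = b,
             altloc = "", het = TRUE, stringsAsFactors = FALSE)
}

water_chain_unit <- function(chain, seq, pos) {
  data.frame(chain = chain, seq = as.integer(seq), ins = "", comp = "NAG",
             name = "C1", element = "C", x = pos[1], y = pos[2], z = pos[3],
             occ = 1, b = 30, altloc = "", het = TRUE, stringsAsFactors = FALSE)
}

link_row <- function(chain1, seq1, atom1, chain2, seq2, atom2, dist = NA) {
  data.frame(chain1 = chain1, seq1 = as.integer(seq1), ins1 = "",
             atom1 = atom1, chain2 = chain2, seq2 = as.integer(seq2),
             ins2 = "", atom2 = atom2, dist = dist, stringsAsFactors = FALSE)
}

# brute-force minimum symmetry distance: literal enumeration over every
# operator, every translation in {-1,0,1}^3 and every atom pair
brute_sym_dist <- function(model, probe, target) {
  Om <- recarb:::orth_matrix(model$cell)
  Fm <- recarb:::frac_matrix(model$cell)
  best <- Inf
  pid <- paste(rkeys_of(probe), probe$name)
  tid <- paste(rkeys_of(target), target$name)
  for (k in seq_along(model$sym_ops)) {
    op <- model$sym_ops[[k]]
    ident <- max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t)) < 1e-9
    for (u in -1:1) for (v in -1:1) for (w in -1:1) {
      for (i in seq_len(nrow(probe))) for (j in seq_len(nrow(target))) {
        if (ident && u == 0 && v == 0 && w == 0 && pid[i] == tid[j]) next
        tf <- as.numeric(Fm %*% c(target$x[j], target$y[j], target$z[j]))
        tf <- as.numeric(op$R %*% tf) + op$t + c(u, v, w)
        tx <- as.numeric(Om %*% tf)
        d <- sqrt(sum((c(probe$x[i], probe$y[i], probe$z[i]) - tx)^2))
        if (d < best) best <- d
      }
    }
  }
  best
}

# regular-expression sequon oracle over the one-letter sequence of fully
# modeled contiguous stretches
ONE_LETTER <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
                MSE = "M")

oracle_sequons <- function(model) {
  rs <- recarb:::model_residues(model)
  rs <- rs[rs$comp %in% names(ONE_LETTER), , drop = FALSE]
  hits <- character()
  for (ch in unique(rs$chain)) {
    sub <- rs[rs$chain == ch, , drop = FALSE]
    sub <- sub[order(sub$seq), , drop = FALSE]
    if (nrow(sub) == 0) next
    # contiguous stretches: consecutive numbering and intact C-N bond
    brk <- c(TRUE, diff(sub$seq) != 1L)
    for (i in 2:max(2, nrow(sub))) {
      if (i > nrow(sub)) break
      if (!brk[i] && recarb:::peptide_break(model, sub$key[i - 1], sub$key[i]))
        brk[i] <- TRUE
    }
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      piece <- sub[grp == g, , drop = FALSE]
      s <- paste(ONE_LETTER[piece$comp], collapse = "")
      m <- gregexpr("(?=N[^P][ST])", s, perl = TRUE)[[1]]
      if (m[1] == -1) next
      hits <- c(hits, piece$key[as.integer(m)])
    }
  }
  hits
}

# literal brute-force evaluation of the three link filters for one
# unlinked NAG/NDG; independent of detect_asn_links
oracle_link_outcome <- function(model, carb_key, cfg = link_config()) {
  rs <- recarb:::model_residues(model)
  linked <- recarb:::linked_atoms_index(model)
  if (paste(carb_key, "C1") %in% linked) return(NULL)
  catoms <- recarb:::heavy_atoms(recarb:::residue_atoms(model, carb_key))
  c1 <- catoms[catoms$name == "C1", , drop = FALSE]
  if (nrow(c1) == 0) return(list(outcome = "no_candidate"))
  c1 <- c(c1$x[1], c1$y[1], c1$z[1])
  seq_asns <- find_sequons(model)$asn
  surv <- character(); near <- 0L; fail <- character(); faild <- numeric()
  flips <- logical()
  for (ak in rs$key[rs$comp == "ASN"]) {
    if (paste(ak, "ND2") %in% linked) next
    nd2 <- recarb:::get_atom(model, ak, "ND2")
    od1 <- recarb:::get_atom(model, ak, "OD1")
    if (is.null(nd2) || is.null(od1)) next
    if (sqrt(sum((c1 - nd2)^2)) > cfg$search_radius) next
    near <- near + 1L
    flip <- sqrt(sum((c1 - od1)^2)) < sqrt(sum((c1 - nd2)^2))
    if (flip) nd2 <- od1
    d <- sqrt(sum((c1 - nd2)^2))
    if (!(ak %in% seq_asns)) {
      fail <- c(fail, "rejected_no_sequon"); faild <- c(faild, d); next
    }
    pass <- d <= cfg$direct_bond_max
    if (!pass) {
      others <- catoms[catoms$name != "C1", , drop = FALSE]
      if (nrow(others) > 0) {
        dmin <- min(sqrt((others$x - nd2[1])^2 + (others$y - nd2[2])^2 +
                           (others$z - nd2[3])^2))
        pass <- dmin <= cfg$secondary_atom_max
      }
    }
    if (pass) { surv <- c(surv, ak); flips <- c(flips, flip) }
    else { fail <- c(fail, "rejected_distance"); faild <- c(faild, d) }
  }
  if (near == 0L) return(list(outcome = "no_candidate"))
  if (length(surv) > 1L) return(list(outcome = "rejected_ambiguous"))
  if (length(surv) == 1L)
    return(list(outcome = "linked", asn = surv, flipped = flips[1]))
  list(outcome = fail[which.min(faild)])
}

# random single-site link geometry for the oracle-equivalence battery
random_link_geometry <- function(seed) {
  set.seed(seed)
  variant <- sample(c("sequon", "nonsequon", "proline", "twoasn"), 1,
                    prob = c(0.55, 0.15, 0.1, 0.2))
  d <- runif(1, 2.6, 7.0)
  orient <- sample(c("away", "toward"), 1)
  flip_amide <- runif(1) < 0.3
  seqs <- switch(variant,
    sequon = c("GLY", "ALA", "ASN", "ALA", "THR", "ALA"),
    nonsequon = c("GLY", "ALA", "ASN", "ALA", "LYS", "ALA"),
    proline = c("GLY", "ALA", "ASN", "PRO", "SER", "ALA"),
    twoasn = c("GLY", "ALA", "ASN", "ALA", "THR", "ALA"))
  if (variant == "twoasn") {
    m <- recarb:::two_asn_case(d, runif(1, 2.6, 5))
  } else {
    pep <- recarb:::build_peptide(seqs)
    m <- recarb:::box_model(pep, recarb:::empty_links(), pad = 12)
    asn <- recarb:::model_residues(m)$key[recarb:::model_residues(m)$comp == "ASN"][1]
    m <- recarb:::place_sugar_near(m, asn, d, orient,
                                   comp = sample(c("NAG", "NDG"), 1),
                                   keep_leaving = runif(1) < 0.5)
  }
  if (flip_amide) {
    asn <- recarb:::model_residues(m)$key[recarb:::model_residues(m)$comp == "ASN"][1]
    m$atoms <- recarb:::swap_amide(m$atoms, asn)
  }
  m
}

carb_keys_of <- function(model) {
  rs <- recarb:::model_residues(model)
  rs$key[rs$comp %in% c("NAG", "NDG")]
}

# quick core-5 fixture cache shared across test files (built once)
.fx_cache <- new.env()
cached_fixture <- function(seed = 11, ...) {
  id <- paste0("fx", seed, paste(c(...), collapse = "_"))
  if (is.null(.fx_cache[[id]]))
    .fx_cache[[id]] <- make_glycosite(seed = seed, ...)
  .fx_cache[[id]]
}
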