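#' @title End-to-end N-glycan curation pipeline
#'
#' @description Orchestrates the full curation pass over a model and an
#' observed density map: link generation, NDG renaming, tree extraction and
#' type selection, cropping of poor-quality carbohydrate residues,
#' temporary removal of blocking molecules and waters, density-driven tree
#' extension and whole-tree addition, density filtering of new residues,
#' old-versus-new tree comparison, grafting of surviving old branches,
#' restoration of parked molecules and renumbering.
#' @name curation-pipeline
NULL

remove_residues <- function(model, keys) {
  if (length(keys) == 0L) return(model)
  model$atoms <- model$atoms[!(res_key_of(model$atoms) %in% keys), , drop = FALSE]
  lk <- model$links
  if (nrow(lk)) {
    k1 <- res_key(lk$chain1, lk$seq1, lk$ins1)
    k2 <- res_key(lk$chain2, lk$seq2, lk$ins2)
    model$links <- lk[!(k1 %in% keys) & !(k2 %in% keys), , drop = FALSE]
  }
  model
}

links_touching <- function(links, keys) {
  k1 <- res_key(links$chain1, links$seq1, links$ins1)
  k2 <- res_key(links$chain2, links$seq2, links$ins2)
  links[k1 %in% keys | k2 %in% keys, , drop = FALSE]
}

#' Crop poor-quality and nonstandard residues from glycan trees
#'
#' Tree nodes whose ring status is "check" or "no", or that do not fit any
#' standard tree grammar, are deleted together with every residue further
#' along the tree. A tree whose root carbohydrate is deleted is marked for
#' whole-tree addition.
#'
#' @param model a [glyco_model]
#' @param trees trees from [extract_trees()]
#' @param statuses data.frame from [validate_rings()] covering all tree nodes
#' @param typedefs tree grammars
#' @return `list(model =, deleted =, store =, full_delete_sites =,
#'   delete_reason =)`; `store` keeps atoms and links of everything removed
#' @export
crop_poor_residues <- function(model, trees, statuses,
                               typedefs = load_tree_types()) {
  status_map <- stats::setNames(statuses$status, statuses$key)
  deleted <- character()
  reason <- character()
  full_delete_sites <- character()
  for (tree in trees) {
    cls <- classify_residues(tree, model, typedefs)
    bad_own <- tree$nodes[status_map[tree$nodes] %in% c("check", "no") |
                            cls[tree$nodes] == "nonstandard"]
    bad <- bad_own
    repeat {
      more <- tree$edges$child[tree$edges$parent %in% bad &
                                 !(tree$edges$child %in% bad)]
      if (length(more) == 0) break
      bad <- c(bad, more)
    }
    root_child <- tree$edges$child[tree$edges$parent_atom == "ND2"]
    if (any(root_child %in% bad)) full_delete_sites <- c(full_delete_sites, tree$root_asn)
    deleted <- c(deleted, bad)
    reason <- c(reason, ifelse(bad %in% bad_own, "poor_or_nonstandard",
                               "descendant_of_deleted"))
  }
  store <- list(atoms = model$atoms[res_key_of(model$atoms) %in% deleted, , drop = FALSE],
                links = links_touching(model$links, deleted))
  model <- remove_residues(model, deleted)
  list(model = model, deleted = deleted, store = store,
       full_delete_sites = unique(full_delete_sites),
       delete_reason = stats::setNames(reason, deleted))
}

#' Temporarily remove molecules that could block carbohydrate building
#'
#' Parks (i) detached carbohydrate chains with any atom within 2.5 Angstrom
#' of an asparagine of interest, (ii) unlinked single carbohydrate residues
#' of the six allowed types (NAG, NDG, MAN, BMA, FUC, FUL), and (iii) all
#' water molecules. Parked residues keep their identifiers for restoration.
#'
#' @param model a [glyco_model]
#' @param asns_of_interest residue keys of the asparagines at which building
#'   will be attempted
#' @return `list(model =, parked =)`; `parked` has `waters`, `single_carbs`,
#'   `chains` (list of key vectors) plus an atom/link `store`
#' @export
clear_blocking_molecules <- function(model, asns_of_interest) {
  rs <- model_residues(model)
  ext <- extract_trees(model)
  linked_keys <- unique(c(unlist(lapply(ext$trees, `[[`, "nodes")),
                          unlist(ext$unattached)))
  park_chain <- list()
  for (chain in ext$unattached) {
    ch_atoms <- model$atoms[res_key_of(model$atoms) %in% chain, , drop = FALSE]
    close <- FALSE
    for (ak in asns_of_interest) {
      aat <- residue_atoms(model, ak)
      if (min_cross_dist(atom_xyz(ch_atoms), atom_xyz(aat)) < 2.5) {
        close <- TRUE; break
      }
    }
    if (close) park_chain[[length(park_chain) + 1L]] <- chain
  }
  allowed <- c("NAG", "NDG", "MAN", "BMA", "FUC", "FUL")
  lk_keys <- unique(c(res_key(model$links$chain1, model$links$seq1, model$links$ins1),
                      res_key(model$links$chain2, model$links$seq2, model$links$ins2)))
  singles <- rs$key[rs$comp %in% allowed & !(rs$key %in% lk_keys) &
                      !(rs$key %in% linked_keys)]
  waters <- rs$key[rs$comp == "HOH"]
  park_keys <- c(unlist(park_chain), singles, waters)
  store <- list(atoms = model$atoms[res_key_of(model$atoms) %in% park_keys, , drop = FALSE],
                links = links_touching(model$links, park_keys))
  model <- remove_residues(model, park_keys)
  list(model = model,
       parked = list(waters = waters, single_carbs = singles,
                     chains = park_chain, store = store))
}

#' Density-acceptance rule for newly built carbohydrate residues
#'
#' A residue passes when RSCC >= 0.70, or RSCC + EDIAm > 1.20, or - at a
#' resolution better than 3.0 Angstrom - RSCC lies in [0.60, 0.70) and the
#' density ratio is at least 0.25.
#'
#' @param rscc_val,ediam_val,ratio_val residue scores
#' @param resolution data resolution (Angstrom)
#' @param cfg a [score_config()]
#' @return logical
#' @export
accept_density_rule <- function(rscc_val, ediam_val, ratio_val, resolution,
                                cfg = score_config()) {
  if (is.na(rscc_val)) return(FALSE)
  if (rscc_val >= cfg$rscc_accept) return(TRUE)
  if (!is.na(ediam_val) && rscc_val + ediam_val > cfg$sum_accept) return(TRUE)
  if (!is.na(resolution) && resolution < cfg$ratio_resolution_cutoff &&
      !is.na(ratio_val) &&
      rscc_val >= cfg$rscc_borderline_low && rscc_val < cfg$rscc_accept &&
      ratio_val >= cfg$ratio_accept) return(TRUE)
  FALSE
}

#' Filter newly built residues on geometry, symmetry clashes and density
#'
#' Keeps a new residue when its ring status is "yes", it does not clash
#' (< `cfg$sym_clash`) with symmetry images of pre-existing atoms, and it
#' passes [accept_density_rule()]. Discarding a residue discards its
#' descendants.
#'
#' @param model a [glyco_model] containing the new residues
#' @param new_keys keys of the newly built residues
#' @param edges build edges (parent/child keys)
#' @param scores data.frame from [score_residues()]
#' @param statuses data.frame from [validate_rings()] for the new residues
#' @param pre_atoms atom table of the model before building
#' @param cfg a [score_config()]
#' @param resolution data resolution
#' @return `list(keep =, drop =, why =)` key vectors
#' @export
filter_new_residues <- function(model, new_keys, edges, scores, statuses,
                                pre_atoms, cfg = score_config(),
                                resolution = model$resolution) {
  status_map <- stats::setNames(statuses$status, statuses$key)
  smap <- scores[match(new_keys, scores$key), , drop = FALSE]
  drop <- character(); why <- character()
  for (i in seq_along(new_keys)) {
    k <- new_keys[i]
    if (is.na(status_map[k]) || status_map[k] != "yes") {
      drop <- c(drop, k); why <- c(why, "ring_status"); next
    }
    at <- residue_atoms(model, k)
    sym <- min_symmetry_distance(model, heavy_atoms(at),
                                 pre_atoms[!(toupper(pre_atoms$element) %in%
                                               c("H", "D")), , drop = FALSE],
                                 exclude_identity = TRUE)
    if (sym$defined && sym$dist < cfg$sym_clash) {
      drop <- c(drop, k); why <- c(why, "symmetry_clash"); next
    }
    if (!accept_density_rule(smap$rscc[i], smap$ediam[i],
                             smap$density_ratio[i], resolution, cfg)) {
      drop <- c(drop, k); why <- c(why, "density")
    }
  }
  # propagate to descendants
  repeat {
    more <- edges$child[edges$parent %in% drop & !(edges$child %in% drop)]
    if (length(more) == 0) break
    drop <- c(drop, more); why <- c(why, rep("parent_discarded", length(more)))
  }
  list(keep = setdiff(new_keys, drop), drop = drop,
       why = stats::setNames(why, drop))
}

#' Decide between the old and the newly built tree at one site
#'
#' The tree with more "yes" residues wins; ties fall to more "check"
#' statuses, then to more residues in total; a full tie keeps the new tree.
#'
#' @param counts_old,counts_new numeric triples `(n_yes, n_check, n_total)`
#' @return `"old"` or `"new"`
#' @export
choose_best_tree <- function(counts_old, counts_new) {
  if (counts_new[1] != counts_old[1])
    return(if (counts_new[1] > counts_old[1]) "new" else "old")
  if (counts_new[2] != counts_old[2])
    return(if (counts_new[2] > counts_old[2]) "new" else "old")
  if (counts_new[3] != counts_old[3])
    return(if (counts_new[3] > counts_old[3]) "new" else "old")
  "new"
}

status_counts <- function(keys, status_map) {
  st <- status_map[keys]
  c(n_yes = sum(st == "yes", na.rm = TRUE),
    n_check = sum(st == "check", na.rm = TRUE),
    n_total = length(keys))
}

# path of every node from the root as "pos/pos/..."; used to match old tree
# slots with rebuilt residues
tree_paths <- function(edges) {
  paths <- character()
  root_edges <- which(edges$parent_atom == "ND2")
  walk <- function(node, path) {
    paths[node] <<- path
    kids <- which(edges$parent == node)
    for (j in kids) walk(edges$child[j], paste0(path, "/", edges$position[j]))
  }
  for (j in root_edges) walk(edges$child[j], as.character(edges$position[j]))
  paths
}

#' Graft surviving old branches onto a rebuilt tree
#'
#' An old branch whose residues were deleted only because an upstream
#' residue was cropped can be re-attached when the rebuilt parent occupies
#' the same slot: its C1 must lie within 2.5 Angstrom of the rebuilt
#' parent's attachment oxygen and the restored branch must not clash
#' (< 2.0 Angstrom) with the newly built residues. Link records are
#' generated for every re-attachment.
#'
#' @param model current [glyco_model] (new tree in place)
#' @param old_edges edges of the pre-crop tree at this site
#' @param cur_edges edges of the current tree at this site (survivors + new)
#' @param store atom/link store of the cropped residues
#' @param status_map old ring statuses (only "yes" residues whose deletion
#'   was propagation are graft candidates)
#' @param delete_reason reasons from [crop_poor_residues()]
#' @param new_keys keys of the newly built residues at this site
#' @param link_max C1-to-oxygen distance bound (2.5 Angstrom)
#' @param clash_min clash bound against new residues (2.0 Angstrom)
#' @return `list(model =, grafted =, links_added =)`
#' @export
graft_tree <- function(model, old_edges, cur_edges, store, status_map,
                       delete_reason, new_keys, link_max = 2.5,
                       clash_min = 2.0) {
  grafted <- character()
  links_added <- empty_links()
  if (nrow(old_edges) == 0 || nrow(cur_edges) == 0)
    return(list(model = model, grafted = grafted, links_added = links_added))
  old_paths <- tree_paths(old_edges)             # node key -> path
  cp <- tree_paths(cur_edges)
  cur_by_path <- stats::setNames(names(cp), unname(cp))   # path -> node key
  store_keys <- unique(res_key_of(store$atoms))
  new_atoms <- model$atoms[res_key_of(model$atoms) %in% new_keys, , drop = FALSE]
  for (i in seq_len(nrow(old_edges))) {
    child <- old_edges$child[i]
    if (!(child %in% store_keys)) next                     # was not cropped
    if (child %in% grafted) next
    if (is.na(delete_reason[child]) ||
        delete_reason[child] != "descendant_of_deleted") next
    if (is.na(status_map[child]) || status_map[child] != "yes") next
    parent_path <- dirname_path(old_paths[child])
    parent_key <- if (parent_path == "") NA_character_ else cur_by_path[parent_path]
    if (is.na(parent_key)) next
    oxy <- get_atom(model, parent_key, old_edges$parent_atom[i])
    if (is.null(oxy)) next
    c1_old <- store$atoms[res_key_of(store$atoms) == child &
                            store$atoms$name == "C1", , drop = FALSE]
    if (nrow(c1_old) == 0) next
    if (vnorm(c(c1_old$x[1], c1_old$y[1], c1_old$z[1]) - oxy) >= link_max) next
    # subtree of `child` among cropped propagation-deleted "yes" residues
    sub <- child
    repeat {
      more <- old_edges$child[old_edges$parent %in% sub &
                                !(old_edges$child %in% sub) &
                                old_edges$child %in% store_keys]
      more <- more[delete_reason[more] == "descendant_of_deleted" &
                     status_map[more] == "yes"]
      if (length(more) == 0) break
      sub <- c(sub, more)
    }
    sub_atoms <- store$atoms[res_key_of(store$atoms) %in% sub, , drop = FALSE]
    # the bonded pair (old child's C1, rebuilt parent's attachment oxygen)
    # is the link being re-formed; it is not a clash
    chk_new <- new_atoms[!(res_key_of(new_atoms) == parent_key &
                             new_atoms$name == old_edges$parent_atom[i]), , drop = FALSE]
    if (nrow(chk_new) > 0 &&
        min_cross_dist(atom_xyz(sub_atoms), atom_xyz(chk_new)) < clash_min) next
    # restore atoms, internal links, and the re-attachment link
    model$atoms <- rbind(model$atoms, sub_atoms)
    lk <- store$links
    if (nrow(lk)) {
      k1 <- res_key(lk$chain1, lk$seq1, lk$ins1)
      k2 <- res_key(lk$chain2, lk$seq2, lk$ins2)
      internal <- lk[k1 %in% sub & k2 %in% sub, , drop = FALSE]
      model$links <- rbind(model$links, internal)
    }
    pp <- split_key(parent_key)[[1]]
    cc <- split_key(child)[[1]]
    newlk <- data.frame(chain1 = pp$chain, seq1 = pp$seq, ins1 = pp$ins,
                        atom1 = old_edges$parent_atom[i],
                        chain2 = cc$chain, seq2 = cc$seq, ins2 = cc$ins,
                        atom2 = "C1",
                        dist = vnorm(c(c1_old$x[1], c1_old$y[1], c1_old$z[1]) - oxy),
                        stringsAsFactors = FALSE)
    model$links <- rbind(model$links, newlk)
    links_added <- rbind(links_added, newlk)
    grafted <- c(grafted, sub)
  }
  list(model = model, grafted = grafted, links_added = links_added)
}

dirname_path <- function(p) {
  parts <- strsplit(p, "/", fixed = TRUE)[[1]]
  if (length(parts) <= 1) "" else paste(parts[-length(parts)], collapse = "/")
}

#' Restore parked waters and carbohydrates
#'
#' Waters and single carbohydrates come back unless any atom lies within
#' 2.5 Angstrom (symmetry-aware) of a newly built residue; detached chains
#' come back only when none of their units clash. Newly built residues are
#' then renumbered if identifiers collide, and on flat-B models the
#' carbohydrate B factors are set to the flat value.
#'
#' @param model a [glyco_model]
#' @param parked parked set from [clear_blocking_molecules()]
#' @param new_keys keys of newly built residues
#' @param clash restoration clash distance (2.5 Angstrom)
#' @return `list(model =, restored =, dropped =, renumbered =)`;
#'   `renumbered` maps old new-residue keys to final keys
#' @export
restore_parked <- function(model, parked, new_keys, clash = 2.5) {
  new_atoms <- model$atoms[res_key_of(model$atoms) %in% new_keys, , drop = FALSE]
  restored <- character(); dropped <- character()
  clashes <- function(keys) {
    at <- parked$store$atoms[res_key_of(parked$store$atoms) %in% keys, , drop = FALSE]
    if (nrow(new_atoms) == 0L || nrow(at) == 0L) return(FALSE)
    d <- min_symmetry_distance(model, at, new_atoms)
    d$defined && d$dist < clash
  }
  for (w in parked$waters) {
    if (clashes(w)) dropped <- c(dropped, w) else restored <- c(restored, w)
  }
  for (s in parked$single_carbs) {
    if (clashes(s)) dropped <- c(dropped, s) else restored <- c(restored, s)
  }
  for (chain in parked$chains) {
    if (any(vapply(chain, clashes, logical(1)))) dropped <- c(dropped, chain)
    else restored <- c(restored, chain)
  }
  # renumber new residues colliding with restored identifiers
  renumbered <- stats::setNames(character(0), character(0))
  if (length(restored)) {
    back <- parked$store$atoms[res_key_of(parked$store$atoms) %in% restored, , drop = FALSE]
    blk <- parked$store$links
    if (nrow(blk)) {
      k1 <- res_key(blk$chain1, blk$seq1, blk$ins1)
      k2 <- res_key(blk$chain2, blk$seq2, blk$ins2)
      blk <- blk[k1 %in% restored & k2 %in% restored, , drop = FALSE]
    }
    for (nk in new_keys) {
      if (nk %in% restored) {
        p <- split_key(nk)[[1]]
        ns <- next_free_seq(glyco_model(rbind(model$atoms, back), cell = model$cell),
                            p$chain)
        sel <- res_key_of(model$atoms) == nk
        model$atoms$seq[sel] <- ns
        lsel1 <- res_key(model$links$chain1, model$links$seq1, model$links$ins1) == nk
        lsel2 <- res_key(model$links$chain2, model$links$seq2, model$links$ins2) == nk
        model$links$seq1[lsel1] <- ns
        model$links$seq2[lsel2] <- ns
        renumbered[nk] <- res_key(p$chain, ns, p$ins)
      }
    }
    model$atoms <- rbind(model$atoms, back)
    model$links <- rbind(model$links, blk)
  }
  if (!is.null(model$flat_b)) {
    sel <- model$atoms$comp %in% PYRANOSE_COMPS
    model$atoms$b[sel] <- model$flat_b
  }
  list(model = model, restored = restored, dropped = dropped,
       renumbered = renumbered)
}

#' Run the full curation pipeline
#'
#' Stage order: link detection, NDG renaming, tree extraction, tree-type
#' selection, cropping, temporary deletion of blocking molecules and waters,
#' extension of existing trees, whole-tree addition at remaining sequon
#' sites (skipping chitobiose-blocked asparagines), density scoring and
#' filtering of new residues, old-versus-new comparison per site with
#' grafting, restoration and renumbering.
#'
#' @param model a [glyco_model]
#' @param map_obs observed [density_map]
#' @param cfg a [score_config()]
#' @param link_cfg a [link_config()]
#' @param d_min resolution; defaults to `model$resolution`
#' @param typedefs tree grammars
#' @param local_threshold local builder acceptance (sigma)
#' @return `list(model =, report =)`; the report lists built, deleted and
#'   restored residues, added links, scores, per-site verdicts and the
#'   link-detection decisions
#' @export
run_pipeline <- function(model, map_obs, cfg = score_config(),
                         link_cfg = link_config(), d_min = model$resolution,
                         typedefs = load_tree_types(), local_threshold = 0.6) {
  input_keys <- model_residues(model)$key
  obs <- map_normalize(map_obs)

  ld <- detect_asn_links(model, link_cfg)
  model <- rename_linked_ndg(ld$model)

  ext <- extract_trees(model)
  typedef <- select_tree_type(ext$trees, model, typedefs)
  tree_nodes <- unlist(lapply(ext$trees, `[[`, "nodes"))
  statuses <- validate_rings(model, tree_nodes)
  old_status_map <- stats::setNames(statuses$status, statuses$key)
  old_trees <- stats::setNames(ext$trees,
                               vapply(ext$trees, `[[`, character(1), "root_asn"))

  cr <- crop_poor_residues(model, ext$trees, statuses, typedefs)
  model <- cr$model

  sequons <- find_sequons(model)
  rooted <- vapply(ext$trees, `[[`, character(1), "root_asn")
  cbs_asns <- cbs_linked_asns(model)
  addition_sites <- setdiff(union(sequons$asn, cr$full_delete_sites),
                            c(setdiff(rooted, cr$full_delete_sites), cbs_asns))
  interest <- union(addition_sites, rooted)

  cb <- clear_blocking_molecules(model, interest)
  model <- cb$model
  pre_atoms <- model$atoms

  # extension of surviving trees, then whole-tree addition
  surviving <- extract_trees(model)$trees
  new_keys <- character()
  new_edges <- data.frame()
  site_of_new <- character()
  for (tr in surviving) {
    gr <- extend_tree(model, tr$root_asn, tr, typedef, obs,
                      local_threshold = local_threshold)
    model <- gr$model
    new_keys <- c(new_keys, gr$new_keys)
    new_edges <- rbind(new_edges, gr$edges)
    site_of_new <- c(site_of_new, rep(tr$root_asn, length(gr$new_keys)))
  }
  for (ak in addition_sites) {
    if (ak %in% vapply(surviving, `[[`, character(1), "root_asn")) next
    gr <- extend_tree(model, ak, NULL, typedef, obs,
                      local_threshold = local_threshold)
    model <- gr$model
    new_keys <- c(new_keys, gr$new_keys)
    new_edges <- rbind(new_edges, gr$edges)
    site_of_new <- c(site_of_new, rep(ak, length(gr$new_keys)))
  }
  names(site_of_new) <- new_keys

  scores <- if (length(new_keys))
    score_residues(model, new_keys, obs, cfg, d_min = d_min)
  else data.frame(key = character(), rscc = numeric(), ediam = numeric(),
                  density_ratio = numeric())
  new_statuses <- validate_rings(model, new_keys)
  flt <- filter_new_residues(model, new_keys, new_edges, scores, new_statuses,
                             pre_atoms, cfg, resolution = d_min)
  model <- remove_residues(model, flt$drop)
  kept_new <- flt$keep
  new_edges <- new_edges[new_edges$child %in% kept_new, , drop = FALSE]
  new_status_map <- stats::setNames(new_statuses$status, new_statuses$key)

  # per-site comparison of old and new trees, then grafting
  verdicts <- list()
  grafted_all <- character()
  links_added <- rbind(ld$links, links_touching(model$links, kept_new))
  sites <- unique(c(names(old_trees), unname(site_of_new[kept_new])))
  for (site in sites) {
    old_tr <- old_trees[[site]]
    rebuilt_here <- !is.null(old_tr) &&
      any(old_tr$nodes %in% cr$deleted)
    site_new <- kept_new[site_of_new[kept_new] == site]
    if (!is.null(old_tr)) {
      survivors_here <- setdiff(old_tr$nodes, cr$deleted)
      counts_old <- status_counts(old_tr$nodes, old_status_map)
      st_new_map <- c(old_status_map[survivors_here], new_status_map[site_new])
      counts_new <- status_counts(c(survivors_here, site_new), st_new_map)
      chosen <- choose_best_tree(counts_old, counts_new)
      if (chosen == "old" && rebuilt_here) {
        # revert: drop this site's new residues, restore the old tree
        model <- remove_residues(model, site_new)
        del_here <- intersect(old_tr$nodes, cr$deleted)
        model$atoms <- rbind(model$atoms,
                             cr$store$atoms[res_key_of(cr$store$atoms) %in% del_here, , drop = FALSE])
        lk <- cr$store$links
        if (nrow(lk)) {
          k1 <- res_key(lk$chain1, lk$seq1, lk$ins1)
          k2 <- res_key(lk$chain2, lk$seq2, lk$ins2)
          keep_lk <- lk[(k1 %in% del_here | k2 %in% del_here), , drop = FALSE]
          model$links <- unique(rbind(model$links, keep_lk))
        }
        kept_new <- setdiff(kept_new, site_new)
        cr$deleted <- setdiff(cr$deleted, del_here)
        verdicts[[site]] <- list(chosen = "old", counts_old = counts_old,
                                 counts_new = counts_new)
        next
      }
      verdict <- list(chosen = chosen, counts_old = counts_old,
                      counts_new = counts_new)
      if (chosen == "new" && rebuilt_here && length(site_new) > 0) {
        cur_edges <- rbind(
          old_tr$edges[!(old_tr$edges$child %in% cr$deleted) &
                         !(old_tr$edges$parent %in% cr$deleted), , drop = FALSE],
          new_edges[new_edges$child %in% site_new, , drop = FALSE])
        g <- graft_tree(model, old_tr$edges, cur_edges, cr$store,
                        old_status_map, cr$delete_reason, site_new)
        model <- g$model
        if (length(g$grafted)) {
          grafted_all <- c(grafted_all, g$grafted)
          cr$deleted <- setdiff(cr$deleted, g$grafted)
          links_added <- rbind(links_added, g$links_added)
          verdict$chosen <- "grafted"
        }
      }
      verdicts[[site]] <- verdict
    } else if (length(site_new) > 0) {
      verdicts[[site]] <- list(chosen = "new",
                               counts_old = c(0, 0, 0),
                               counts_new = status_counts(site_new, new_status_map))
    }
  }

  rp <- restore_parked(model, cb$parked, kept_new)
  model <- rp$model
  kept_new <- vapply(kept_new, function(k)
    if (k %in% names(rp$renumbered)) rp$renumbered[[k]] else k, character(1),
    USE.NAMES = FALSE)

  perm_deleted <- unique(c(cr$deleted, rp$dropped, flt$drop))
  report <- list(
    built = kept_new,
    deleted = perm_deleted,
    restored = rp$restored,
    grafted = grafted_all,
    links_added = links_added,
    scores = scores,
    filter_drop = flt$why,
    verdicts = verdicts,
    link_decisions = ld$decisions,
    tree_type = typedef$name,
    input_keys = input_keys)
  list(model = model, report = report)
}

cbs_linked_asns <- function(model) {
  rs <- model_residues(model)
  comp_map <- stats::setNames(rs$comp, rs$key)
  lk <- model$links
  out <- character()
  for (i in seq_len(nrow(lk))) {
    k1 <- res_key(lk$chain1[i], lk$seq1[i], lk$ins1[i])
    k2 <- res_key(lk$chain2[i], lk$seq2[i], lk$ins2[i])
    if (!is.na(comp_map[k1]) && comp_map[k1] == "ASN" &&
        !is.na(comp_map[k2]) && comp_map[k2] == "CBS") out <- c(out, k1)
    if (!is.na(comp_map[k2]) && comp_map[k2] == "ASN" &&
        !is.na(comp_map[k1]) && comp_map[k1] == "CBS") out <- c(out, k2)
  }
  unique(out)
}
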