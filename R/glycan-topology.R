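#' @title Sequon detection and N-glycan tree topology
#'
#' @description N-glycosylation occurs at the sequon Asn-X-Ser/Thr (X any
#' residue but proline). Trees of carbohydrate residues are rooted at the
#' Asn ND2 atom and traced through covalent-link records; five standard
#' tree grammars (high-mannose, hybrid/complex mammal, hybrid/complex
#' plant) share the common five-residue core
#' NAG(beta1-N)Asn, NAG(beta1-4), BMA(beta1-4), MAN(alpha1-3), MAN(alpha1-6).
#' @name glycan-topology
NULL

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE")

#' Find N-glycosylation sequons among modeled residues
#'
#' Returns every modeled Asn whose two following residues are present in the
#' chain with consecutive author numbering and without a chain break
#' (peptide C-N distance <= 2.5 Angstrom), where the X position is not
#' proline and the third residue is Ser or Thr.
#'
#' @param model a [glyco_model]
#' @return data.frame with columns `asn`, `x_res`, `st_res` (residue keys)
#'   and `asn_chain`, `asn_seq`
#' @export
find_sequons <- function(model) {
  rs <- model_residues(model)
  rs <- rs[rs$comp %in% AMINO_ACIDS & rs$ins == "", , drop = FALSE]
  out <- data.frame(asn = character(), x_res = character(),
                    st_res = character(), asn_chain = character(),
                    asn_seq = integer(), stringsAsFactors = FALSE)
  for (i in which(rs$comp == "ASN")) {
    ch <- rs$chain[i]; sq <- rs$seq[i]
    j <- which(rs$chain == ch & rs$seq == sq + 1L)
    k <- which(rs$chain == ch & rs$seq == sq + 2L)
    if (length(j) != 1L || length(k) != 1L) next
    if (rs$comp[j] == "PRO") next
    if (!(rs$comp[k] %in% c("SER", "THR"))) next
    if (peptide_break(model, rs$key[i], rs$key[j]) ||
        peptide_break(model, rs$key[j], rs$key[k])) next
    out <- rbind(out, data.frame(asn = rs$key[i], x_res = rs$key[j],
                                 st_res = rs$key[k], asn_chain = ch,
                                 asn_seq = sq, stringsAsFactors = FALSE))
  }
  out
}

peptide_break <- function(model, key1, key2, max_cn = 2.5) {
  c1 <- get_atom(model, key1, "C")
  n2 <- get_atom(model, key2, "N")
  if (is.null(c1) || is.null(n2)) return(TRUE)
  vnorm(c1 - n2) > max_cn
}

link_position <- function(parent_atom) {
  if (parent_atom == "ND2") return(0L)
  p <- suppressWarnings(as.integer(gsub("[^0-9]", "", parent_atom)))
  if (is.na(p)) -1L else p
}

# Directed carbohydrate edges from link records: child C1 -> parent oxygen
# (or Asn ND2). Returns data.frame(parent, child, parent_atom, child_atom,
# position, anomer).
carb_edges <- function(model) {
  lk <- model$links
  rs <- model_residues(model)
  comp_map <- stats::setNames(rs$comp, rs$key)
  out <- data.frame(parent = character(), child = character(),
                    parent_atom = character(), child_atom = character(),
                    position = integer(), anomer = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lk))) {
    k1 <- res_key(lk$chain1[i], lk$seq1[i], lk$ins1[i])
    k2 <- res_key(lk$chain2[i], lk$seq2[i], lk$ins2[i])
    a1 <- lk$atom1[i]; a2 <- lk$atom2[i]
    # orient: the C1 side is the child
    if (a1 == "C1" && comp_map[k1] %in% PYRANOSE_COMPS) {
      child <- k1; catom <- a1; parent <- k2; patom <- a2
    } else if (a2 == "C1" && comp_map[k2] %in% PYRANOSE_COMPS) {
      child <- k2; catom <- a2; parent <- k1; patom <- a1
    } else next
    if (is.na(comp_map[parent])) next
    anomer <- unname(COMP_ANOMER[comp_map[child]])
    out <- rbind(out, data.frame(
      parent = parent, child = child, parent_atom = patom, child_atom = catom,
      position = link_position(patom),
      anomer = if (is.null(anomer) || is.na(anomer)) "beta" else anomer,
      stringsAsFactors = FALSE))
  }
  out
}

#' Extract N-glycan trees from a model's link records
#'
#' One tree per Asn carrying an ND2 to C1 link; membership follows
#' carbohydrate C1 to oxygen links transitively. A link that would close a
#' cycle is dropped with a warning. Carbohydrate chains (two or more linked
#' sugars) not reachable from any Asn are reported as unattached chains.
#'
#' @param model a [glyco_model]
#' @return `list(trees = list(...), unattached = list(character vectors))`;
#'   each tree is `list(root_asn =, edges =, nodes =)`
#' @export
extract_trees <- function(model) {
  edges <- carb_edges(model)
  rs <- model_residues(model)
  comp_map <- stats::setNames(rs$comp, rs$key)
  roots <- edges[edges$parent_atom == "ND2" &
                   comp_map[edges$parent] == "ASN" &
                   comp_map[edges$child] %in% c("NAG", "NDG"), , drop = FALSE]
  trees <- list()
  claimed <- character()
  for (i in seq_len(nrow(roots))) {
    root_edge <- roots[i, , drop = FALSE]
    nodes <- root_edge$child
    tree_edges <- root_edge
    frontier <- root_edge$child
    while (length(frontier) > 0) {
      nxt <- character()
      for (p in frontier) {
        kids <- edges[edges$parent == p & edges$parent_atom != "ND2", , drop = FALSE]
        for (j in seq_len(nrow(kids))) {
          ch <- kids$child[j]
          if (ch %in% nodes || ch %in% claimed || ch == root_edge$parent) {
            warning("link would close a cycle or reuse a residue; dropped: ",
                    p, " -> ", ch, call. = FALSE)
            next
          }
          nodes <- c(nodes, ch)
          tree_edges <- rbind(tree_edges, kids[j, , drop = FALSE])
          nxt <- c(nxt, ch)
        }
      }
      frontier <- nxt
    }
    claimed <- c(claimed, nodes)
    trees[[length(trees) + 1L]] <- list(root_asn = root_edge$parent,
                                        edges = tree_edges, nodes = nodes)
  }
  # unattached chains: linked-sugar components not reachable from an Asn
  carbs <- rs$key[rs$comp %in% PYRANOSE_COMPS]
  rest <- setdiff(carbs, claimed)
  sub <- edges[edges$parent %in% rest & edges$child %in% rest, , drop = FALSE]
  unattached <- connected_components(rest, sub)
  unattached <- unattached[vapply(unattached, length, integer(1)) >= 2L]
  list(trees = trees, unattached = unattached)
}

connected_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    a <- find(edges$parent[i]); b <- find(edges$child[i])
    if (a != b) parent[[a]] <- b
  }
  comp <- vapply(nodes, find, character(1))
  unname(split(nodes, comp))
}

#' Load the standard N-glycan tree-type grammars
#'
#' @param path optional path to an alternative production-table JSON
#' @return named list of typedefs; each has `name` and a `productions`
#'   data.frame (`parent`, `position`, `child`, `anomer`, `depth`, `class`)
#' @export
load_tree_types <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tree_types.json", package = "recarb")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  core <- raw$core
  core$class <- "core"
  out <- list()
  for (nm in names(raw$types)) {
    fu <- raw$types[[nm]]$fucoses
    bc <- raw$types[[nm]]$beyond_core
    fu$class <- if (nrow(fu)) "fucose" else character(0)
    bc$class <- if (nrow(bc)) "beyond" else character(0)
    prod <- rbind(core, fu, bc)
    out[[nm]] <- list(name = nm, productions = prod)
  }
  out
}

TREE_TYPE_ORDER <- c("high-mannose", "hybrid-mammal", "complex-mammal",
                     "hybrid-plant", "complex-plant")

production_matches <- function(prods, parent_comp, position, child_comp, anomer) {
  any(prods$parent == parent_comp & prods$position == position &
        prods$child == child_comp & prods$anomer == anomer)
}

# Edges of a tree annotated with parent/child comps and whether they belong
# to the common core (by pattern, position in tree).
annotate_tree_edges <- function(tree, model) {
  rs <- model_residues(model)
  comp_map <- stats::setNames(rs$comp, rs$key)
  e <- tree$edges
  e$parent_comp <- unname(comp_map[e$parent])
  e$child_comp <- unname(comp_map[e$child])
  e$depth <- tree_node_depths(tree)[e$child]
  core_pat <- list(c("ASN", 0, "NAG"), c("NAG", 4, "NAG"), c("NAG", 4, "BMA"),
                   c("BMA", 3, "MAN"), c("BMA", 6, "MAN"))
  e$is_core <- vapply(seq_len(nrow(e)), function(i) {
    any(vapply(core_pat, function(p)
      e$parent_comp[i] == p[1] && e$position[i] == as.integer(p[2]) &&
        e$child_comp[i] == p[3], logical(1))) && e$depth[i] <= 4
  }, logical(1))
  e
}

tree_node_depths <- function(tree) {
  d <- stats::setNames(integer(length(tree$nodes)), tree$nodes)
  e <- tree$edges
  root_children <- e$child[e$parent_atom == "ND2"]
  d[root_children] <- 1L
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(nrow(e))) {
      if (e$parent_atom[i] == "ND2") next
      pd <- d[e$parent[i]]
      if (!is.na(pd) && pd > 0 && (is.na(d[e$child[i]]) || d[e$child[i]] == 0L)) {
        d[e$child[i]] <- pd + 1L
        changed <- TRUE
      }
    }
  }
  d
}

#' Select the tree type to build
#'
#' If no existing tree extends beyond the five-residue core, the default
#' type is returned: high-mannose with its fucose productions enabled.
#' Otherwise the type whose productions cover the largest number of existing
#' beyond-core residues wins; ties are broken in the order high-mannose,
#' hybrid-mammal, complex-mammal, hybrid-plant, complex-plant.
#'
#' @param trees list of trees from [extract_trees()]
#' @param model the model the trees live in
#' @param typedefs from [load_tree_types()]
#' @return a single typedef
#' @export
select_tree_type <- function(trees, model, typedefs = load_tree_types()) {
  beyond <- list()
  for (tr in trees) {
    e <- annotate_tree_edges(tr, model)
    bc <- e[!e$is_core, , drop = FALSE]
    if (nrow(bc)) beyond[[length(beyond) + 1L]] <- bc
  }
  if (length(beyond) == 0L) return(typedefs[["high-mannose"]])
  bc <- do.call(rbind, beyond)
  scores <- vapply(TREE_TYPE_ORDER, function(nm) {
    prods <- typedefs[[nm]]$productions
    sum(vapply(seq_len(nrow(bc)), function(i)
      production_matches(prods, bc$parent_comp[i], bc$position[i],
                         bc$child_comp[i], bc$anomer[i]), logical(1)))
  }, numeric(1))
  if (max(scores) == 0) return(typedefs[["high-mannose"]])
  typedefs[[TREE_TYPE_ORDER[which.max(scores)]]]
}

#' Classify tree residues as conforming or nonstandard
#'
#' A residue conforms when its incoming edge's production (parent component,
#' attachment position, child component, anomer) appears in at least one of
#' the five standard tree grammars; a nonstandard mark propagates to every
#' descendant.
#'
#' @param tree a tree from [extract_trees()]
#' @param model the model
#' @param typedefs from [load_tree_types()]
#' @return named character vector, `"conforming"` or `"nonstandard"` per node
#' @export
classify_residues <- function(tree, model, typedefs = load_tree_types()) {
  e <- annotate_tree_edges(tree, model)
  all_prods <- unique(do.call(rbind, lapply(typedefs, `[[`, "productions")))
  cls <- stats::setNames(rep("conforming", length(tree$nodes)), tree$nodes)
  ord <- order(e$depth)
  for (i in ord) {
    ok <- production_matches(all_prods, e$parent_comp[i], e$position[i],
                             e$child_comp[i], e$anomer[i])
    parent_bad <- e$parent_atom[i] != "ND2" &&
      cls[e$parent[i]] == "nonstandard"
    if (!ok || parent_bad) cls[e$child[i]] <- "nonstandard"
  }
  cls
}
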