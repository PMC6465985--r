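#' @title Detection of missing Asn-carbohydrate covalent links
#'
#' @description For every NAG or NDG whose anomeric C1 participates in no
#' covalent link, candidate asparagines are sought with ND2 within the
#' search radius of C1. If the carbonyl OD1 of a candidate is closer to C1
#' than ND2, the side-chain amide is flipped (OD1/ND2 swapped) before
#' evaluation. Three filters follow: the asparagine must head a valid
#' Asn-X-Ser/Thr sequon; if the ND2-C1 distance exceeds the direct-bond
#' maximum, some other carbohydrate atom must lie within the secondary-atom
#' maximum of ND2; and if more than one asparagine survives, no link is
#' generated. On success the link record is appended, an applied flip is
#' persisted, and the leaving atom (O1 for NAG, O1L for NDG) is deleted.
#' @name link-detection
NULL

#' Link-detection configuration
#'
#' @param search_radius candidate search radius around C1 (Angstrom)
#' @param direct_bond_max maximum ND2-C1 distance for a direct link
#' @param secondary_atom_max maximum ND2-to-other-carbohydrate-atom distance
#'   rescuing candidates beyond `direct_bond_max`
#' @return list of class `link_config`
#' @export
link_config <- function(search_radius = 6.0, direct_bond_max = 4.0,
                        secondary_atom_max = 3.5) {
  stopifnot(direct_bond_max > 0, direct_bond_max <= search_radius,
            secondary_atom_max < search_radius)
  structure(list(search_radius = search_radius,
                 direct_bond_max = direct_bond_max,
                 secondary_atom_max = secondary_atom_max),
            class = "link_config")
}

linked_atoms_index <- function(model) {
  lk <- model$links
  c(paste(res_key(lk$chain1, lk$seq1, lk$ins1), lk$atom1),
    paste(res_key(lk$chain2, lk$seq2, lk$ins2), lk$atom2))
}

#' Generate missing Asn-NAG/NDG link records
#'
#' @param model a [glyco_model]
#' @param cfg a [link_config()]
#' @return `list(model =, links =, decisions =)`: the modified model (new
#'   link records, persisted amide flips, leaving atoms removed), the new
#'   links, and one decision row per unlinked NAG/NDG with columns `carb`,
#'   `asn`, `outcome` (linked / rejected_no_sequon / rejected_distance /
#'   rejected_ambiguous / no_candidate), `flipped`, `removed_atoms`
#' @export
detect_asn_links <- function(model, cfg = link_config()) {
  rs <- model_residues(model)
  linked <- linked_atoms_index(model)
  sequon_asns <- find_sequons(model)$asn
  decisions <- data.frame(carb = character(), asn = character(),
                          outcome = character(), flipped = logical(),
                          removed_atoms = character(), stringsAsFactors = FALSE)
  new_links <- empty_links()
  decide <- function(carb, asn, outcome, flipped = FALSE, removed = character())
    decisions <<- rbind(decisions, data.frame(
      carb = carb, asn = ifelse(is.na(asn), NA_character_, asn),
      outcome = outcome, flipped = flipped,
      removed_atoms = paste(removed, collapse = ","),
      stringsAsFactors = FALSE))

  carbs <- rs$key[rs$comp %in% c("NAG", "NDG")]
  asns <- rs$key[rs$comp == "ASN"]
  for (ck in carbs) {
    if (paste(ck, "C1") %in% linked) next
    c1 <- get_atom(model, ck, "C1")
    if (is.null(c1)) {
      warning("carbohydrate ", ck, " lacks a C1 atom", call. = FALSE)
      decide(ck, NA, "no_candidate")
      next
    }
    cand <- list()
    any_within <- FALSE
    for (ak in asns) {
      if (paste(ak, "ND2") %in% linked) next
      nd2 <- get_atom(model, ak, "ND2")
      od1 <- get_atom(model, ak, "OD1")
      if (is.null(nd2) || is.null(od1)) next
      if (vnorm(c1 - nd2) > cfg$search_radius) next
      any_within <- TRUE
      flip <- vnorm(c1 - od1) < vnorm(c1 - nd2)
      nd2_eff <- if (flip) od1 else nd2
      # filter 1: sequon
      if (!(ak %in% sequon_asns)) {
        cand[[length(cand) + 1L]] <- list(asn = ak, ok = FALSE,
                                          why = "rejected_no_sequon",
                                          flip = flip, d = vnorm(c1 - nd2_eff))
        next
      }
      # filter 2: direct bond or secondary atom
      d <- vnorm(c1 - nd2_eff)
      ok <- d <= cfg$direct_bond_max
      if (!ok) {
        other <- heavy_atoms(residue_atoms(model, ck))
        other <- other[other$name != "C1", , drop = FALSE]
        if (nrow(other) > 0) {
          dmin <- min(sqrt(rowSums(sweep(atom_xyz(other), 2, nd2_eff)^2)))
          ok <- dmin <= cfg$secondary_atom_max
        }
      }
      cand[[length(cand) + 1L]] <- list(asn = ak, ok = ok,
                                        why = if (ok) "ok" else "rejected_distance",
                                        flip = flip, d = d)
    }
    survivors <- Filter(function(x) x$ok, cand)
    if (length(survivors) == 0L) {
      if (!any_within || length(cand) == 0L) { decide(ck, NA, "no_candidate"); next }
      # report the closest candidate's failure mode
      dmins <- vapply(cand, `[[`, numeric(1), "d")
      decide(ck, NA, cand[[which.min(dmins)]]$why)
      next
    }
    if (length(survivors) > 1L) { decide(ck, NA, "rejected_ambiguous"); next }
    s <- survivors[[1]]
    removed <- character()
    if (s$flip) model$atoms <- swap_amide(model$atoms, s$asn)
    comp <- rs$comp[rs$key == ck]
    leaving <- if (comp == "NDG") "O1L" else "O1"
    has_leaving <- any(res_key_of(model$atoms) == ck & model$atoms$name == leaving)
    if (has_leaving) {
      model$atoms <- model$atoms[!(res_key_of(model$atoms) == ck &
                                     model$atoms$name == leaving), , drop = FALSE]
      removed <- leaving
    }
    ap <- split_key(s$asn)[[1]]
    cp <- split_key(ck)[[1]]
    lrow <- data.frame(chain1 = ap$chain, seq1 = ap$seq, ins1 = ap$ins,
                       atom1 = "ND2", chain2 = cp$chain, seq2 = cp$seq,
                       ins2 = cp$ins, atom2 = "C1", dist = s$d,
                       stringsAsFactors = FALSE)
    model$links <- rbind(model$links, lrow)
    new_links <- rbind(new_links, lrow)
    linked <- c(linked, paste(ck, "C1"), paste(s$asn, "ND2"))
    decide(ck, s$asn, "linked", flipped = s$flip, removed = removed)
  }
  list(model = model, links = new_links, decisions = decisions)
}

#' Rename asparagine-linked NDG residues to NAG
#'
#' An alpha-anomer assignment on the residue that is covalently bonded to
#' Asn ND2 is a nomenclature error; the root of an N-glycan is the beta
#' anomer NAG.
#'
#' @param model a [glyco_model]
#' @return the model with every Asn-linked NDG renamed to NAG (a remaining
#'   O1L leaving atom, if any, is renamed to O1)
#' @export
rename_linked_ndg <- function(model) {
  rs <- model_residues(model)
  comp_map <- stats::setNames(rs$comp, rs$key)
  lk <- model$links
  for (i in seq_len(nrow(lk))) {
    k1 <- res_key(lk$chain1[i], lk$seq1[i], lk$ins1[i])
    k2 <- res_key(lk$chain2[i], lk$seq2[i], lk$ins2[i])
    ndg <- NULL
    if (lk$atom1[i] == "ND2" && lk$atom2[i] == "C1" &&
        !is.na(comp_map[k1]) && comp_map[k1] == "ASN" &&
        !is.na(comp_map[k2]) && comp_map[k2] == "NDG") ndg <- k2
    if (lk$atom2[i] == "ND2" && lk$atom1[i] == "C1" &&
        !is.na(comp_map[k2]) && comp_map[k2] == "ASN" &&
        !is.na(comp_map[k1]) && comp_map[k1] == "NDG") ndg <- k1
    if (!is.null(ndg)) {
      sel <- res_key_of(model$atoms) == ndg
      model$atoms$comp[sel] <- "NAG"
      model$atoms$name[sel & model$atoms$name == "O1L"] <- "O1"
    }
  }
  model
}
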