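# Bilin chromophore extraction, ring partition, and distance metrics.

.ring_core_pattern <- "^(N|C[1-4])[ABCD]$"
.bridge_pattern <- "^CH[BCD]$"

#' Partition bilin atoms into pyrrole rings and methine bridges
#'
#' Open-chain tetrapyrroles follow a ring nomenclature in which pyrrole
#' nitrogens and ring carbons carry the suffix of their ring (A-D): `NA`,
#' `C1A`..`C4A` and so on, while the methine bridge carbons joining
#' consecutive rings are `CHB`, `CHC`, `CHD`. Atoms matching the ring-core
#' pattern are assigned to their ring; bridge atoms are stored under bridge
#' labels; everything else (propionates, methyls, vinyl/ethylidene side
#' chains) is excluded from the rings and from the conjugated set.
#'
#' @param atom_names character vector of atom names.
#' @return list with elements `A`,`B`,`C`,`D` (integer indices of ring-core
#'   atoms), `HB`,`HC`,`HD` (bridge indices), and `conjugated` (all ring
#'   cores plus bridges).
#' @export
partition_rings <- function(atom_names) {
  ring_hit <- grepl(.ring_core_pattern, atom_names)
  bridge_hit <- grepl(.bridge_pattern, atom_names)
  if (!any(ring_hit) && !any(bridge_hit)) {
    stop("nomenclature error: no atoms match the bilin ring naming (N?/C1?-C4?/CH?)",
         call. = FALSE)
  }
  rings <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(rl) {
    which(ring_hit & endsWith(atom_names, rl))
  })
  small <- names(rings)[vapply(rings, length, integer(1)) > 0 &
                        vapply(rings, length, integer(1)) < 4]
  if (length(small)) {
    warning(sprintf("partial ring(s) %s: fewer than 4 matched atoms (kept)",
                    paste(small, collapse = ",")), call. = FALSE)
  }
  bridges <- lapply(c(HB = "CHB", HC = "CHC", HD = "CHD"), function(bn) {
    which(atom_names == bn)
  })
  c(rings, bridges, list(conjugated = sort(c(unlist(rings), unlist(bridges)))))
}

.new_chromophore <- function(atoms, chain, resno, resid, parent_chain = NA_character_,
                             parent_role = NA_character_, region = NULL) {
  ring_map <- partition_rings(atoms$elety)
  conj <- ring_map$conjugated
  if (length(conj) == 0) stop("nomenclature error: empty conjugated set", call. = FALSE)
  centroid <- colMeans(.axyz(atoms[conj, , drop = FALSE]))
  structure(list(
    id = .chrom_id(chain, resno, resid),
    chain = chain, resno = resno, comp = resid,
    atoms = atoms, ring_map = ring_map[c("A", "B", "C", "D", "HB", "HC", "HD")],
    conjugated = conj, centroid = centroid,
    parent_chain = parent_chain, parent_role = parent_role,
    region = region %||% .blank_region()), class = "chromophore")
}

.chrom_id <- function(chain, resno, resid) sprintf("%s/%d/%s", chain, resno, resid)

#' @export
print.chromophore <- function(x, ...) {
  cat(sprintf("chromophore %s: %d atoms (%d conjugated), parent %s (%s), centroid (%.2f, %.2f, %.2f)\n",
              x$id, nrow(x$atoms), length(x$conjugated),
              x$parent_chain, x$parent_role %||% NA, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Extract bilin chromophores from an assembly
#'
#' One chromophore per ligand group whose component code is in
#' `component_codes` (default: the phycobilisome bilins phycocyanobilin,
#' phycoerythrobilin, phycourobilin, phycoviolobilin, plus the packaged toy
#' code `TBL`). Each chromophore gets its ring partition, conjugated-atom
#' centroid, and a parent subunit assigned by minimum heavy-atom distance to
#' the polymer chains (a proximity proxy for the covalent cysteine
#' attachment); role and region labels are inherited from the model
#' annotation when present.
#'
#' @param model a `pbs_assembly`.
#' @param component_codes character vector of ligand component codes.
#' @return list of `chromophore` objects, ordered by (chain, residue number).
#' @export
extract_chromophores <- function(model, component_codes = .bilin_codes) {
  stopifnot(inherits(model, "pbs_assembly"))
  lg <- model$ligand_groups
  lg <- lg[lg$resid %in% component_codes, , drop = FALSE]
  if (nrow(lg) == 0) return(list())
  lg <- lg[order(lg$chain, lg$resno), , drop = FALSE]
  pol <- model$atoms[model$atoms$is_polymer, , drop = FALSE]
  ann <- model$annotations
  out <- vector("list", nrow(lg))
  keep <- logical(nrow(lg))
  for (k in seq_len(nrow(lg))) {
    sel <- model$atoms$chain == lg$chain[k] & model$atoms$resno == lg$resno[k] &
      model$atoms$resid == lg$resid[k]
    atoms <- model$atoms[sel, , drop = FALSE]
    if (nrow(atoms) == 0) {
      warning(sprintf("ligand %s/%d/%s has no atoms; skipped",
                      lg$chain[k], lg$resno[k], lg$resid[k]), call. = FALSE)
      next
    }
    parent <- .nearest_polymer_chain(atoms, pol)
    role <- NA_character_
    region <- NULL
    if (!is.null(ann) && !is.na(parent)) {
      row <- ann[ann$chain == parent, , drop = FALSE]
      if (nrow(row)) {
        role <- row$role[1]
        region <- list(compartment = row$compartment[1], cylinder = row$cylinder[1],
                       layer = row$layer[1], rod_name = row$rod_name[1],
                       hexamer_index = row$hexamer_index[1])
      }
    }
    out[[k]] <- .new_chromophore(atoms, lg$chain[k], lg$resno[k], lg$resid[k],
                                 parent_chain = parent, parent_role = role,
                                 region = region)
    keep[k] <- TRUE
  }
  out[keep]
}

# Nearest polymer chain to a ligand, by heavy-atom minimum distance.
# Candidate polymer atoms are pre-filtered by a bounding box for speed.
.nearest_polymer_chain <- function(lig_atoms, pol_atoms, pad = 6) {
  if (nrow(pol_atoms) == 0) return(NA_character_)
  lx <- .axyz(lig_atoms)
  repeat {
    box <- pol_atoms$x >= min(lx[, 1]) - pad & pol_atoms$x <= max(lx[, 1]) + pad &
           pol_atoms$y >= min(lx[, 2]) - pad & pol_atoms$y <= max(lx[, 2]) + pad &
           pol_atoms$z >= min(lx[, 3]) - pad & pol_atoms$z <= max(lx[, 3]) + pad
    if (any(box) || pad > 1e4) break
    pad <- pad * 4
  }
  cand <- pol_atoms[box, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  d2 <- .cross_dist2(lx, .axyz(cand))
  cand$chain[which.min(apply(d2, 2, min))]
}

# Atom selection of a chromophore under a metric.
.chrom_xyz <- function(chrom, metric) {
  switch(metric,
    min_conjugated_atom = {
      if (length(chrom$conjugated) == 0)
        stop(sprintf("metric undefined: %s has an empty conjugated set", chrom$id),
             call. = FALSE)
      .axyz(chrom$atoms[chrom$conjugated, , drop = FALSE])
    },
    min_any_atom = .axyz(chrom$atoms),
    centroid = matrix(chrom$centroid, 1, 3),
    stop(sprintf("unknown distance metric '%s'", metric), call. = FALSE))
}

#' Distance between two chromophores
#'
#' Three metrics are supported: `min_conjugated_atom` (minimum heavy-atom
#' distance between the two conjugated ring systems; the package default for
#' networks), `min_any_atom` (minimum over all heavy atoms, side chains
#' included), and `centroid` (conjugated-centroid to conjugated-centroid).
#' `min_any_atom <= min_conjugated_atom` always, since it minimises over a
#' superset of atom pairs. The centroid metric obeys the triangle
#' inequality; the min-atom metrics do not.
#'
#' @param c1,c2 `chromophore` objects.
#' @param metric one of `"min_conjugated_atom"`, `"min_any_atom"`,
#'   `"centroid"`.
#' @return distance in Angstrom.
#' @export
chromophore_distance <- function(c1, c2,
                                 metric = c("min_conjugated_atom", "min_any_atom", "centroid")) {
  metric <- match.arg(metric)
  a <- .chrom_xyz(c1, metric)
  b <- .chrom_xyz(c2, metric)
  .min_cross_dist(a, b)
}

#' All-pairs chromophore distances
#'
#' @param chromophores list of `chromophore` objects.
#' @param metric as in [chromophore_distance()].
#' @return long-format data.frame id1, id2, metric, distance (each unordered
#'   pair once, id1 < id2 lexicographically).
#' @export
chromophore_distance_matrix <- function(chromophores,
                                        metric = c("min_conjugated_atom", "min_any_atom", "centroid")) {
  metric <- match.arg(metric)
  n <- length(chromophores)
  ids <- vapply(chromophores, `[[`, character(1), "id")
  xyz <- lapply(chromophores, .chrom_xyz, metric = metric)
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(), 2, 0)
  d <- apply(pairs, 2, function(p) .min_cross_dist(xyz[[p[1]]], xyz[[p[2]]]))
  data.frame(id1 = ids[pairs[1, ]], id2 = ids[pairs[2, ]],
             metric = rep(metric, ncol(pairs)), distance = as.numeric(d),
             stringsAsFactors = FALSE)
}

#' Distance from a residue to a chromophore ring
#'
#' Minimum heavy-atom distance from a residue's selected atoms (side chain
#' only by default, matching how ring-stacking residues are discussed) to a
#' target atom set of the chromophore: one ring (`"A"`..`"D"`), the
#' conjugated system, or any atom.
#'
#' @param model a `pbs_assembly` (source of the residue's atoms).
#' @param chain,resno residue identity (author numbering).
#' @param chromophore a `chromophore`.
#' @param target `"conjugated"` (default), `"any"`, or a ring label.
#' @param selection `"sidechain"` (default) or `"all"` residue heavy atoms.
#' @return distance in Angstrom.
#' @export
residue_ring_distance <- function(model, chain, resno, chromophore,
                                  target = "conjugated",
                                  selection = c("sidechain", "all")) {
  stopifnot(inherits(model, "pbs_assembly"), inherits(chromophore, "chromophore"))
  selection <- match.arg(selection)
  res <- model$atoms[model$atoms$chain == chain & model$atoms$resno == resno &
                       model$atoms$is_polymer, , drop = FALSE]
  if (nrow(res) == 0) {
    stop(sprintf("residue %s/%d not found in model", chain, resno), call. = FALSE)
  }
  if (selection == "sidechain") res <- res[!(res$elety %in% .backbone_atoms), , drop = FALSE]
  if (nrow(res) == 0) {
    stop(sprintf("empty selection: residue %s/%d has no side-chain heavy atoms", chain, resno),
         call. = FALSE)
  }
  tgt <- .chrom_target_xyz(chromophore, target)
  .min_cross_dist(.axyz(res), tgt)
}

.chrom_target_xyz <- function(chrom, target) {
  if (target %in% c("A", "B", "C", "D")) {
    idx <- chrom$ring_map[[target]]
    if (length(idx) == 0) {
      stop(sprintf("metric undefined: chromophore %s has no ring %s atoms", chrom$id, target),
           call. = FALSE)
    }
    return(.axyz(chrom$atoms[idx, , drop = FALSE]))
  }
  if (target == "conjugated") return(.chrom_xyz(chrom, "min_conjugated_atom"))
  if (target == "any") return(.chrom_xyz(chrom, "min_any_atom"))
  stop(sprintf("unknown target '%s' (ring label, 'conjugated' or 'any')", target), call. = FALSE)
}

#' Tabulate a chromophore set
#'
#' @param chromophores list of `chromophore` objects.
#' @return data.frame id, comp, chain, resno, parent_chain, parent_role,
#'   compartment, cylinder, layer, rod_name, centroid_x/y/z, ring sizes.
#' @export
chromophore_table <- function(chromophores) {
  do.call(rbind, lapply(chromophores, function(ch) {
    data.frame(id = ch$id, comp = ch$comp, chain = ch$chain, resno = ch$resno,
               parent_chain = ch$parent_chain, parent_role = ch$parent_role,
               compartment = ch$region$compartment, cylinder = ch$region$cylinder,
               layer = ch$region$layer, rod_name = ch$region$rod_name,
               centroid_x = ch$centroid[1], centroid_y = ch$centroid[2],
               centroid_z = ch$centroid[3],
               ring_A = length(ch$ring_map$A), ring_B = length(ch$ring_map$B),
               ring_C = length(ch$ring_map$C), ring_D = length(ch$ring_map$D),
               stringsAsFactors = FALSE)
  }))
}
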