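# Residue microenvironment of bilins: contact shells, pi-pi and cation-pi
# geometry, and aromatic censuses.
#
# Geometric thresholds follow common structural-biology conventions
# (parallel stacking: ring-centroid distance <= 5.5 A and interplanar angle
# < 30 deg; T-shaped: <= 6.0 A and > 60 deg; cation-pi: cationic-group
# centroid <= 6.0 A from the ring centroid). All thresholds are arguments
# and are echoed in every annotation record.

.default_pi_thresholds <- list(parallel_dist = 5.5, parallel_angle = 30,
                               tshape_dist = 6.0, tshape_angle = 60)

#' Residues in the neighbourhood of a chromophore
#'
#' Enumerates polymer residues whose selected heavy atoms come within
#' `cutoff` of the chromophore, sorted by minimum distance. The common
#' shells are 5 A (primary, direct-contact) and 10 A (extended).
#'
#' @param model a `pbs_assembly`.
#' @param chromophore a `chromophore`.
#' @param cutoff shell radius in Angstrom (> 0).
#' @param target chromophore atom set: `"any"` (default), `"conjugated"`, or
#'   a ring label.
#' @param selection residue atoms: `"sidechain"` (default) or `"all"`.
#' @param exclude_attachment drop cysteines whose SG lies within covalent
#'   range (2.5 A) of the chromophore (the bilin's own thioether anchor).
#' @return data.frame chain, resno, resid, role, chromophore_id,
#'   min_distance, nearest_ring, res_atom, chrom_atom; ascending by
#'   min_distance.
#' @export
chromophore_neighborhood <- function(model, chromophore, cutoff = 5,
                                     target = "any",
                                     selection = c("sidechain", "all"),
                                     exclude_attachment = FALSE) {
  stopifnot(inherits(model, "pbs_assembly"), inherits(chromophore, "chromophore"))
  selection <- match.arg(selection)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  tgt <- .chrom_target_xyz(chromophore, target)
  tgt_names <- .chrom_target_names(chromophore, target)

  pol <- model$atoms[model$atoms$is_polymer, , drop = FALSE]
  if (selection == "sidechain") pol <- pol[!(pol$elety %in% .backbone_atoms), , drop = FALSE]
  if (nrow(pol) == 0) return(.empty_contacts())
  # bounding-box prefilter around the target set
  pad <- cutoff + 0.5
  box <- pol$x >= min(tgt[, 1]) - pad & pol$x <= max(tgt[, 1]) + pad &
         pol$y >= min(tgt[, 2]) - pad & pol$y <= max(tgt[, 2]) + pad &
         pol$z >= min(tgt[, 3]) - pad & pol$z <= max(tgt[, 3]) + pad
  pol <- pol[box, , drop = FALSE]
  if (nrow(pol) == 0) return(.empty_contacts())

  ann <- model$annotations
  key <- paste(pol$chain, pol$resno, pol$insert, pol$resid, sep = "\r")
  rows <- list()
  for (k in unique(key)) {
    res <- pol[key == k, , drop = FALSE]
    hit <- .argmin_cross(.axyz(res), tgt)
    if (hit$dist > cutoff) next
    role <- NA_character_
    if (!is.null(ann)) {
      m <- ann$role[ann$chain == res$chain[1]]
      if (length(m)) role <- m[1]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain = res$chain[1], resno = res$resno[1], resid = res$resid[1],
      role = role, chromophore_id = chromophore$id,
      min_distance = hit$dist,
      nearest_ring = .ring_of_atom(chromophore, tgt_names[hit$j]),
      res_atom = res$elety[hit$i], chrom_atom = tgt_names[hit$j],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_contacts()
  if (exclude_attachment && nrow(out)) {
    anchor <- out$resid == "CYS" & out$min_distance <= 2.5
    out <- out[!anchor, , drop = FALSE]
  }
  out <- out[order(out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_contacts <- function() {
  data.frame(chain = character(), resno = integer(), resid = character(),
             role = character(), chromophore_id = character(),
             min_distance = numeric(), nearest_ring = character(),
             res_atom = character(), chrom_atom = character(),
             stringsAsFactors = FALSE)
}

.chrom_target_names <- function(chrom, target) {
  if (target %in% c("A", "B", "C", "D")) {
    return(chrom$atoms$elety[chrom$ring_map[[target]]])
  }
  if (target == "conjugated") return(chrom$atoms$elety[chrom$conjugated])
  chrom$atoms$elety
}

# Ring (or bridge) label of a chromophore atom name; NA for side-chain atoms.
.ring_of_atom <- function(chrom, atom_name) {
  for (lab in c("A", "B", "C", "D", "HB", "HC", "HD")) {
    if (atom_name %in% chrom$atoms$elety[chrom$ring_map[[lab]]]) return(lab)
  }
  NA_character_
}

#' Classify pi-pi stacking geometry between two rings
#'
#' Computes ring centroids, best-fit plane normals (smallest-variance
#' principal axis of the ring-atom scatter), the interplanar angle folded to
#' `[0, 90]` degrees, and the lateral centroid offset in the bilin ring
#' plane. Classification: parallel stacking when centroid distance and angle
#' fall inside `parallel_dist`/`parallel_angle`; T-shaped when inside
#' `tshape_dist` with angle above `tshape_angle`; otherwise `none`.
#'
#' @param res_ring_xyz n x 3 matrix, aromatic side-chain ring atoms (>= 3).
#' @param bilin_ring_xyz m x 3 matrix, one bilin pyrrole ring (>= 4 atoms
#'   for a full ring; >= 3 accepted).
#' @param thresholds named list, see `.default_pi_thresholds`.
#' @return list (class `interaction_annotation`): kind, centroid_distance,
#'   interplanar_angle, offset, thresholds.
#' @export
classify_pi_interaction <- function(res_ring_xyz, bilin_ring_xyz,
                                    thresholds = .default_pi_thresholds) {
  thresholds <- utils::modifyList(.default_pi_thresholds, thresholds)
  p1 <- .ring_plane(res_ring_xyz)
  p2 <- .ring_plane(bilin_ring_xyz)
  dvec <- p1$centroid - p2$centroid
  d <- sqrt(sum(dvec^2))
  ang <- .axis_angle_deg(p1$normal, p2$normal)
  axial <- sum(dvec * p2$normal)
  offset <- sqrt(max(0, d^2 - axial^2))
  kind <- if (d <= thresholds$parallel_dist && ang < thresholds$parallel_angle) {
    "pi_pi_parallel"
  } else if (d <= thresholds$tshape_dist && ang > thresholds$tshape_angle) {
    "pi_pi_tshaped"
  } else "none"
  structure(list(kind = kind, centroid_distance = d, interplanar_angle = ang,
                 offset = offset, thresholds = thresholds),
            class = "interaction_annotation")
}

#' Classify cation-pi geometry between a cationic group and a ring
#'
#' @param cation_xyz n x 3 matrix of cationic-group heavy atoms (Arg
#'   guanidinium NE/CZ/NH1/NH2 or Lys NZ).
#' @param ring_xyz m x 3 matrix of ring atoms.
#' @param max_dist classification threshold on the centroid-centroid
#'   distance (default 6.0 A).
#' @return list (class `interaction_annotation`): kind (`cation_pi`/`none`),
#'   centroid_distance, axial_angle (between the centroid-centroid vector
#'   and the ring normal, folded to `[0, 90]`), thresholds.
#' @export
classify_cation_pi <- function(cation_xyz, ring_xyz, max_dist = 6.0) {
  cation_xyz <- matrix(as.numeric(cation_xyz), ncol = 3)
  if (nrow(cation_xyz) == 0) stop("empty selection: no cationic-group atoms", call. = FALSE)
  ring <- .ring_plane(ring_xyz)
  cc <- colMeans(cation_xyz)
  dvec <- cc - ring$centroid
  d <- sqrt(sum(dvec^2))
  ang <- if (d > 0) .axis_angle_deg(dvec, ring$normal) else 0
  structure(list(kind = if (d <= max_dist) "cation_pi" else "none",
                 centroid_distance = d, axial_angle = ang,
                 thresholds = list(max_dist = max_dist)),
            class = "interaction_annotation")
}

#' @export
print.interaction_annotation <- function(x, ...) {
  cat(sprintf("interaction: %s (centroid distance %.2f A%s)\n", x$kind,
              x$centroid_distance,
              if (!is.null(x$interplanar_angle))
                sprintf(", interplanar angle %.1f deg", x$interplanar_angle) else ""))
  invisible(x)
}

#' Classify the interaction of one residue with a chromophore
#'
#' Convenience wrapper: picks the residue's aromatic ring (Phe/Tyr/Trp/His)
#' or cationic group (Arg/Lys) from the model, the bilin ring nearest to it
#' (by ring-centroid distance, unless `ring` is given), and dispatches to
#' [classify_pi_interaction()] or [classify_cation_pi()].
#'
#' @param model a `pbs_assembly`.
#' @param chain,resno residue identity.
#' @param chromophore a `chromophore`.
#' @param ring optional ring label `"A"`..`"D"`.
#' @param thresholds passed through to the classifiers.
#' @return an `interaction_annotation` with `residue` and `ring` fields
#'   added; kind `none` for residues that are neither aromatic nor cationic.
#' @export
classify_residue_bilin <- function(model, chain, resno, chromophore, ring = NULL,
                                   thresholds = .default_pi_thresholds) {
  res <- model$atoms[model$atoms$chain == chain & model$atoms$resno == resno &
                       model$atoms$is_polymer, , drop = FALSE]
  if (nrow(res) == 0) stop(sprintf("residue %s/%d not found", chain, resno), call. = FALSE)
  resid <- res$resid[1]

  pick_ring <- function(group_xyz) {
    if (!is.null(ring)) return(ring)
    cands <- Filter(function(rl) length(chromophore$ring_map[[rl]]) >= 3,
                    c("A", "B", "C", "D"))
    if (length(cands) == 0) stop("chromophore has no complete rings", call. = FALSE)
    ctr <- colMeans(group_xyz)
    dd <- vapply(cands, function(rl) {
      rc <- colMeans(.axyz(chromophore$atoms[chromophore$ring_map[[rl]], , drop = FALSE]))
      sqrt(sum((ctr - rc)^2))
    }, numeric(1))
    cands[which.min(dd)]
  }

  if (resid %in% .aromatic_res) {
    ring_atoms <- res[res$elety %in% .aromatic_ring_atoms[[resid]], , drop = FALSE]
    if (nrow(ring_atoms) < 3) {
      stop(sprintf("empty selection: residue %s/%d (%s) is missing ring atoms",
                   chain, resno, resid), call. = FALSE)
    }
    rl <- pick_ring(.axyz(ring_atoms))
    out <- classify_pi_interaction(.axyz(ring_atoms),
                                   .axyz(chromophore$atoms[chromophore$ring_map[[rl]], , drop = FALSE]),
                                   thresholds = thresholds)
  } else if (resid %in% names(.cation_atoms)) {
    grp <- res[res$elety %in% .cation_atoms[[resid]], , drop = FALSE]
    if (nrow(grp) == 0) {
      stop(sprintf("empty selection: residue %s/%d (%s) is missing side-chain atoms",
                   chain, resno, resid), call. = FALSE)
    }
    rl <- pick_ring(.axyz(grp))
    out <- classify_cation_pi(.axyz(grp),
                              .axyz(chromophore$atoms[chromophore$ring_map[[rl]], , drop = FALSE]))
  } else {
    out <- structure(list(kind = "none", centroid_distance = NA_real_,
                          thresholds = thresholds), class = "interaction_annotation")
    rl <- NA_character_
  }
  out$residue <- list(chain = chain, resno = resno, resid = resid)
  out$ring <- rl
  out
}

#' Census of aromatic residues contacting bilins
#'
#' Counts Phe/Tyr/Trp/His residues whose side chains come within `cutoff` of
#' any chromophore, grouped by the residue chain's subunit role, region, or
#' chain id, with per-group composition fractions.
#'
#' @param model an annotated `pbs_assembly` (annotation required for
#'   role/region grouping).
#' @param chromophores list of `chromophore` objects.
#' @param cutoff contact shell in Angstrom (default 5).
#' @param grouping `"role"`, `"region"`, or `"chain"`.
#' @return data.frame group, PHE, TYR, TRP, HIS, total, plus fraction
#'   columns; one row per group with any contact.
#' @export
aromatic_census <- function(model, chromophores, cutoff = 5,
                            grouping = c("role", "region", "chain")) {
  grouping <- match.arg(grouping)
  if (grouping %in% c("role", "region")) .require_annotation(model)
  seen <- new.env(parent = emptyenv())
  for (ch in chromophores) {
    nb <- chromophore_neighborhood(model, ch, cutoff = cutoff, target = "any",
                                   selection = "sidechain")
    nb <- nb[nb$resid %in% .aromatic_res, , drop = FALSE]
    for (i in seq_len(nrow(nb))) {
      assign(paste(nb$chain[i], nb$resno[i], nb$resid[i], sep = "\r"), TRUE, envir = seen)
    }
  }
  keys <- ls(seen)
  if (length(keys) == 0) {
    return(data.frame(group = character(), PHE = integer(), TYR = integer(),
                      TRP = integer(), HIS = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                   resid = parts[, 3], stringsAsFactors = FALSE)
  ann <- model$annotations
  df$group <- switch(grouping,
    chain = df$chain,
    role = ann$role[match(df$chain, ann$chain)],
    region = {
      i <- match(df$chain, ann$chain)
      ifelse(ann$compartment[i] == "core",
             sprintf("core:%s%s", ann$cylinder[i], ifelse(is.na(ann$layer[i]), "", ann$layer[i])),
             ifelse(ann$compartment[i] == "rod", sprintf("rod:%s", ann$rod_name[i]), "none"))
    })
  out <- do.call(rbind, lapply(split(df, df$group), function(g) {
    counts <- vapply(.aromatic_res, function(tt) sum(g$resid == tt), integer(1))
    data.frame(group = g$group[1], PHE = counts[["PHE"]], TYR = counts[["TYR"]],
               TRP = counts[["TRP"]], HIS = counts[["HIS"]],
               total = sum(counts), stringsAsFactors = FALSE)
  }))
  for (tt in .aromatic_res) out[[paste0("frac_", tt)]] <- out[[tt]] / out$total
  out <- out[order(out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Polarization of a linker domain's aromatic residues toward one bilin set
#'
#' For a rod linker chain, the fraction of its bilin-contacting aromatic
#' residues that sit near a designated (core-proximal) subset of bilins:
#' 1.0 means fully concentrated around the proximal bilin(s).
#'
#' @param model a `pbs_assembly`.
#' @param chromophores list of `chromophore` objects (all bilins).
#' @param chain linker chain id.
#' @param proximal_ids chromophore ids of the core-proximal bilin(s).
#' @param cutoff contact shell (default 5 A).
#' @return list with counts `near_proximal`, `total` and the `polarization`
#'   index (NA when the chain contacts no bilin).
#' @export
linker_polarization <- function(model, chromophores, chain, proximal_ids, cutoff = 5) {
  res_near <- function(chroms) {
    keys <- character(0)
    for (ch in chroms) {
      nb <- chromophore_neighborhood(model, ch, cutoff = cutoff, target = "any",
                                     selection = "sidechain")
      nb <- nb[nb$chain == chain & nb$resid %in% .aromatic_res, , drop = FALSE]
      keys <- union(keys, paste(nb$chain, nb$resno, sep = "\r"))
    }
    keys
  }
  all_ids <- vapply(chromophores, `[[`, character(1), "id")
  total <- res_near(chromophores)
  prox <- res_near(chromophores[all_ids %in% proximal_ids])
  list(near_proximal = length(prox), total = length(total),
       polarization = if (length(total)) length(prox) / length(total) else NA_real_)
}
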