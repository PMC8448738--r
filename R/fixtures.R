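# Synthetic bilin-bearing assemblies with fully controlled geometry.
#
# Toy chromophores use bilin-style atom names (rings A-D, methine bridges)
# under the fictitious component code "TBL", so extraction-by-code and ring
# partitioning are exercised without colliding with real chemistry. Decoy
# residues are idealised side-chain templates with minimal backbones; each
# is placed so the realised minimum side-chain-to-target distance equals the
# intended distance exactly (to coordinate-file precision).

.toy_code <- "TBL"
.pentagon_radius <- 1.4 / (2 * sin(pi / 5))  # C-C bond 1.4 A

# Idealised side-chain templates: probe atom (the one that realises the
# intended minimum distance) at the origin, every other atom in the z >= 0
# half-space so the probe stays nearest to the target after placement.
.decoy_templates <- list(
  TYR = data.frame(
    elety = c("OH", "CZ", "CE1", "CE2", "CD1", "CD2", "CG", "CB", "CA", "N", "C", "O"),
    x = c(0, 0, 1.2, -1.2, 1.2, -1.2, 0, 0, 0, 1.3, -1.3, -1.9),
    y = c(0, 0, 0, 0, 0, 0, 0, 0, 0.9, 0.9, 0.9, 1.8),
    z = c(0, 1.4, 2.1, 2.1, 3.5, 3.5, 4.2, 5.7, 6.9, 7.6, 7.6, 8.1)),
  PHE = data.frame(
    elety = c("CZ", "CE1", "CE2", "CD1", "CD2", "CG", "CB", "CA", "N", "C", "O"),
    x = c(0, 1.2, -1.2, 1.2, -1.2, 0, 0, 0, 1.3, -1.3, -1.9),
    y = c(0, 0, 0, 0, 0, 0, 0, 0.9, 0.9, 0.9, 1.8),
    z = c(0, 0.7, 0.7, 2.1, 2.1, 2.8, 4.3, 5.5, 6.2, 6.2, 6.7)),
  TRP = data.frame(
    elety = c("CD1", "CG", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2", "CB", "CA", "N", "C", "O"),
    x = c(0, 0.7, -1.3, -1.2, 0.2, 1.0, -2.0, 0.4, -1.4, 2.0, 2.5, 3.8, 2.2, 2.8),
    y = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.9, 0.9, 1.8, 2.6),
    z = c(0, 1.2, 0.7, 2.1, 2.4, 3.5, 3.2, 4.6, 4.4, 1.0, 2.2, 2.0, 3.3, 3.8)),
  HIS = data.frame(
    elety = c("CE1", "ND1", "NE2", "CD2", "CG", "CB", "CA", "N", "C", "O"),
    x = c(0, -1.1, 1.1, 0.7, -0.7, -1.4, -1.0, 0.3, -2.0, -1.8),
    y = c(0, 0, 0, 0, 0, 0, 0.9, 0.9, 1.8, 2.7),
    z = c(0, 0.8, 0.8, 2.1, 2.1, 3.4, 4.6, 5.0, 5.2, 6.0)),
  ARG = data.frame(
    elety = c("NH1", "NH2", "CZ", "NE", "CD", "CG", "CB", "CA", "N", "C", "O"),
    x = c(0, 1.9, 0.6, -0.2, 0.8, 0.1, 0.9, 0.3, 1.4, -0.8, -0.9),
    y = c(0, 0, 0, 0, 0, 0, 0, 0.9, 0.9, 1.8, 2.7),
    z = c(0, 0.6, 1.0, 2.1, 3.1, 4.3, 5.5, 6.5, 7.3, 6.9, 7.6)),
  LYS = data.frame(
    elety = c("NZ", "CE", "CD", "CG", "CB", "CA", "N", "C", "O"),
    x = c(0, 0, 1.2, 1.2, 2.4, 2.4, 3.6, 1.3, 1.4),
    y = c(0, 0, 0, 0, 0, 0.9, 0.9, 1.8, 2.7),
    z = c(0, 1.5, 2.3, 3.8, 4.6, 5.9, 6.6, 6.5, 7.2)),
  ALA = data.frame(
    elety = c("CB", "CA", "N", "C", "O"),
    x = c(0, 0, 1.2, -1.2, -1.3),
    y = c(0, 0.9, 0.9, 1.4, 2.3),
    z = c(0, 1.2, 2.0, 1.8, 2.5)),
  CYS = data.frame(
    elety = c("SG", "CB", "CA", "N", "C", "O"),
    x = c(0, 0, 0, 1.3, -1.3, -1.5),
    y = c(0, 0, 0.9, 0.9, 1.4, 2.3),
    z = c(0, 1.8, 3.0, 3.7, 3.4, 4.1)))

#' Build a toy tetrapyrrole chromophore
#'
#' A planar four-ring bilin mimic: four regular pentagons (atom names `N?`,
#' `C1?`..`C4?` with ring suffixes A-D) joined by methine bridge atoms
#' `CHB`/`CHC`/`CHD`, ring centres 3.0 A apart, total span ~12 A. The
#' conjugated centroid equals `center` exactly.
#'
#' @param center length-3 numeric, target centroid in Angstrom.
#' @param orientation 3x3 proper rotation applied before translation.
#' @return data.frame elety, elesy, x, y, z (23 atoms).
#' @export
toy_chromophore <- function(center = c(0, 0, 0), orientation = diag(3)) {
  .check_rotation(orientation)
  ring_x <- c(A = -4.5, B = -1.5, C = 1.5, D = 4.5)
  rows <- list()
  for (rl in names(ring_x)) {
    ang <- pi / 2 + 2 * pi * (0:4) / 5
    px <- ring_x[[rl]] + .pentagon_radius * cos(ang)
    py <- .pentagon_radius * sin(ang)
    nm <- paste0(c("N", "C1", "C2", "C3", "C4"), rl)
    rows[[rl]] <- data.frame(elety = nm, elesy = c("N", "C", "C", "C", "C"),
                             x = px, y = py, z = 0, stringsAsFactors = FALSE)
  }
  bridges <- data.frame(elety = c("CHB", "CHC", "CHD"), elesy = "C",
                        x = c(-3, 0, 3), y = 0, z = 0, stringsAsFactors = FALSE)
  at <- rbind(do.call(rbind, rows), bridges)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(orientation)
  at$x <- xyz[, 1] + center[1]
  at$y <- xyz[, 2] + center[2]
  at$z <- xyz[, 3] + center[3]
  rownames(at) <- NULL
  at
}

#' Specify a synthetic assembly
#'
#' @param chromophores list; each element a list with `center` (length-3),
#'   optional `orientation` (3x3 rotation), `role` (subunit role for the
#'   parent chain, default `"ApcA"`), `region` (list of compartment /
#'   cylinder / layer / rod_name / hexamer_index fields).
#' @param decoys list; each element a list with `type` (Tyr/Phe/Trp/His/
#'   Arg/Lys/Ala as 3-letter codes), `target` (chromophore index), `ring`
#'   (ring label or `"conjugated"`), `distance` (intended minimum
#'   side-chain-to-target distance, > 2.5 A steric floor).
#' @param seed integer; all stochastic choices (jitter) derive from it.
#' @param jitter uniform coordinate noise: every atom is displaced by an
#'   independent uniform vector inside a ball of radius `jitter` Angstrom
#'   (default 0), so realised distances stay within intended +/- 2*jitter.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(chromophores, decoys = list(), seed = 1L, jitter = 0) {
  stopifnot(length(chromophores) >= 1)
  chromophores <- lapply(chromophores, function(ch) {
    ch$orientation <- ch$orientation %||% diag(3)
    .check_rotation(ch$orientation)
    stopifnot(length(ch$center) == 3)
    ch$role <- ch$role %||% "ApcA"
    if (!ch$role %in% .pbs_roles) stop(sprintf("unknown role '%s'", ch$role), call. = FALSE)
    ch$region <- .validate_region(ch$region %||% list(compartment = "core", cylinder = "A", layer = 1L),
                                  chain = "<fixture>")
    ch
  })
  decoys <- lapply(decoys, function(d) {
    d$type <- toupper(d$type)
    if (!d$type %in% names(.decoy_templates) || d$type == "CYS") {
      stop(sprintf("unknown decoy type '%s'", d$type), call. = FALSE)
    }
    if (is.null(d$target) || d$target < 1 || d$target > length(chromophores)) {
      stop("decoy target must index a chromophore", call. = FALSE)
    }
    d$ring <- d$ring %||% "conjugated"
    if (!d$ring %in% c("A", "B", "C", "D", "conjugated")) {
      stop(sprintf("unknown target ring '%s'", d$ring), call. = FALSE)
    }
    if (!is.numeric(d$distance) || d$distance <= 0) {
      stop("intended decoy distance must be > 0", call. = FALSE)
    }
    if (d$distance < 2.5) {
      stop(sprintf("fixture spec error: intended distance %.2f A below the 2.5 A steric floor",
                   d$distance), call. = FALSE)
    }
    d
  })
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  structure(list(chromophores = chromophores, decoys = decoys,
                 seed = as.integer(seed), jitter = jitter),
            class = "fixture_spec")
}

# Place a residue template so its probe atom sits at `pos` with the template
# +z axis along `u`; returns atom data.frame.
.place_template <- function(type, pos, u) {
  tpl <- .decoy_templates[[type]]
  R <- .rotation_z_to(u)
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(R)
  data.frame(elety = tpl$elety,
             elesy = substr(gsub("[0-9]", "", tpl$elety), 1, 1),
             x = xyz[, 1] + pos[1], y = xyz[, 2] + pos[2], z = xyz[, 3] + pos[3],
             stringsAsFactors = FALSE)
}

# Deterministic approach directions around a ring: alternating sides of the
# ring plane, then diagonals, so several decoys on one ring stay apart.
.approach_dirs <- function(normal, e1, e2) {
  s2 <- sqrt(2)
  list(normal, -normal,
       (normal + e1) / s2, (-normal + e1) / s2,
       (normal - e1) / s2, (-normal - e1) / s2,
       (normal + e2) / s2, (-normal + e2) / s2)
}

.fixture_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) stop("fixture supports at most 62 chains", call. = FALSE)
  pool[seq_len(n)]
}

#' Generate a synthetic assembly and write it to disk
#'
#' Builds the atoms for every chromophore (each with a parent chain holding
#' one cysteine whose SG is placed 1.9 A from ring A, the covalent-anchor
#' mimic, plus the bilin ligand on the same chain) and every decoy residue
#' (each on its own chain), applies jitter, writes mmCIF and PDB files, an
#' annotation config (YAML) and a ground-truth manifest (JSON), then
#' re-reads the mmCIF and re-verifies every planted distance from the file.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @param name basename for the generated files.
#' @return list: `cif`, `pdb`, `annotation`, `manifest_path` (paths),
#'   `manifest` (list), `model` (the re-read, annotated `pbs_assembly`).
#' @export
make_assembly <- function(spec, dir = tempdir(), name = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nch <- length(spec$chromophores)
  ids <- .fixture_chain_ids(nch + length(spec$decoys))
  parent_ids <- ids[seq_len(nch)]
  decoy_ids <- ids[nch + seq_along(spec$decoys)]

  atoms <- list()
  chrom_meta <- list()
  placed <- list()  # toy chromophore atom tables, for targeting
  for (k in seq_len(nch)) {
    ch <- spec$chromophores[[k]]
    toy <- toy_chromophore(ch$center, ch$orientation)
    placed[[k]] <- toy
    # parent chain: one cysteine anchored 1.9 A from ring A (covalent mimic)
    ringA <- toy[endsWith(toy$elety, "A") & grepl(.ring_core_pattern, toy$elety), , drop = FALSE]
    frame <- .toy_frame(ch$orientation)
    anchor_dir <- frame$e2  # out of the chromophore plane
    g <- .axyz(ringA)
    gstar <- g[which.max(g %*% anchor_dir), ]
    cys <- .place_template("CYS", gstar + 1.9 * anchor_dir, anchor_dir)
    atoms[[length(atoms) + 1L]] <- .fixture_atoms(cys, parent_ids[k], 1L, "CYS", TRUE)
    atoms[[length(atoms) + 1L]] <- .fixture_atoms(toy, parent_ids[k], 201L, .toy_code, FALSE)
    chrom_meta[[k]] <- list(id = .chrom_id(parent_ids[k], 201L, .toy_code),
                            chain = parent_ids[k], center = ch$center,
                            role = ch$role, region = ch$region)
  }

  decoy_meta <- list()
  used <- integer(nch)  # per-chromophore approach-direction counter
  for (i in seq_along(spec$decoys)) {
    d <- spec$decoys[[i]]
    toy <- placed[[d$target]]
    ch <- spec$chromophores[[d$target]]
    tgt <- if (d$ring == "conjugated") {
      toy[grepl(.ring_core_pattern, toy$elety) | grepl(.bridge_pattern, toy$elety), , drop = FALSE]
    } else {
      toy[endsWith(toy$elety, d$ring) & grepl(.ring_core_pattern, toy$elety), , drop = FALSE]
    }
    frame <- .toy_frame(ch$orientation)
    dirs <- .approach_dirs(frame$e2, frame$e0, frame$e1)
    used[d$target] <- used[d$target] + 1L
    u <- dirs[[(used[d$target] - 1L) %% length(dirs) + 1L]]
    g <- .axyz(tgt)
    gstar <- g[which.max(g %*% u), ]
    res <- .place_template(d$type, gstar + d$distance * u, u)
    atoms[[length(atoms) + 1L]] <- .fixture_atoms(res, decoy_ids[i], 1L, d$type, TRUE)
    decoy_meta[[i]] <- list(chain = decoy_ids[i], resno = 1L, type = d$type,
                            target_id = chrom_meta[[d$target]]$id,
                            target_ring = d$ring, intended = d$distance)
  }

  at <- do.call(rbind, atoms)
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    n <- nrow(at)
    # uniform inside a ball of radius jitter
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    r <- spec$jitter * stats::runif(n)^(1 / 3)
    at$x <- at$x + v[, 1] * r
    at$y <- at$y + v[, 2] * r
    at$z <- at$z + v[, 3] * r
  }
  rownames(at) <- NULL
  model <- .new_assembly(at, source = list(path = NA_character_, format = "fixture"))

  cif <- file.path(dir, paste0(name, ".cif"))
  pdb <- file.path(dir, paste0(name, ".pdb"))
  write_assembly_cif(model, cif)
  write_assembly_pdb(model, pdb)

  ann_cfg <- list(chains = c(
    stats::setNames(lapply(chrom_meta, function(m) {
      c(list(role = m$role), m$region[c("compartment", "cylinder", "layer", "rod_name", "hexamer_index")])
    }), vapply(chrom_meta, `[[`, character(1), "chain")),
    stats::setNames(lapply(decoy_meta, function(m) list(role = "other")),
                    vapply(decoy_meta, `[[`, character(1), "chain"))),
    patterns = list())
  ann_path <- file.path(dir, paste0(name, "_annotation.yaml"))
  yaml::write_yaml(.yaml_sanitize(ann_cfg), ann_path)

  # re-read from the written file and verify every planted distance
  reread <- read_assembly(cif, format = "mmcif")
  reread <- annotate_subunits(reread, read_annotation_config(ann_path))
  chroms <- extract_chromophores(reread, .toy_code)
  cid <- vapply(chroms, `[[`, character(1), "id")
  tol <- 0.011 + 2 * spec$jitter
  for (i in seq_along(decoy_meta)) {
    m <- decoy_meta[[i]]
    realized <- residue_ring_distance(reread, m$chain, m$resno,
                                      chroms[[match(m$target_id, cid)]],
                                      target = if (m$target_ring == "conjugated") "conjugated" else m$target_ring)
    if (abs(realized - m$intended) > tol) {
      stop(sprintf("fixture verification failed: decoy %s realised %.3f A vs intended %.3f A",
                   m$chain, realized, m$intended), call. = FALSE)
    }
    decoy_meta[[i]]$realized <- realized
  }

  manifest <- list(seed = spec$seed, jitter = spec$jitter,
                   component_code = .toy_code,
                   chromophores = chrom_meta, decoys = decoy_meta,
                   files = list(cif = cif, pdb = pdb, annotation = ann_path))
  manifest_path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(cif = cif, pdb = pdb, annotation = ann_path,
       manifest_path = manifest_path, manifest = manifest, model = reread)
}

# Orthonormal frame of a placed toy chromophore: e0 = molecular long axis,
# e1 = in-plane, e2 = ring-plane normal.
.toy_frame <- function(orientation) {
  list(e0 = as.numeric(orientation %*% c(1, 0, 0)),
       e1 = as.numeric(orientation %*% c(0, 1, 0)),
       e2 = as.numeric(orientation %*% c(0, 0, 1)))
}

.fixture_atoms <- function(tbl, chain, resno, resid, is_polymer) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = resid, elety = tbl$elety, elesy = tbl$elesy,
             x = tbl$x, y = tbl$y, z = tbl$z, o = 1,
             is_polymer = is_polymer, model = 1L, stringsAsFactors = FALSE)
}

# yaml::write_yaml chokes on NA integers inside lists; map them to NULL-free
.yaml_sanitize <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .yaml_sanitize)
    x[!vapply(x, is.null, logical(1))]
  } else if (length(x) == 1 && is.na(x)) NULL else x
}

#' Plant a chromophore chain with a unique sub-cutoff path
#'
#' Places `n` toy chromophores on a circular arc with consecutive
#' conjugated-centroid spacing `step` and every non-consecutive pair
#' strictly farther than `cutoff` under the min-conjugated-atom metric
#' (verified by enumeration on the written file). The chromophores stand
#' perpendicular to the arc plane so atom extent cannot create shortcut
#' edges. The last node is labelled ApcD (a terminal emitter), the first
#' sits in a rod region, intermediates in core layers; the expected path is
#' the chain in order.
#'
#' Feasibility: by the triangle inequality a two-step neighbour can never
#' exceed `2*step`, so the construction requires `cutoff < 2*step` (minus
#' the ~2.4 A in-plane atom extent); infeasible requests error with a
#' parameter suggestion.
#'
#' @param n number of chromophores (>= 2).
#' @param step consecutive centroid spacing in Angstrom (< cutoff).
#' @param cutoff network cutoff the fixture is planted against.
#' @param seed fixture seed.
#' @param dir,name output location, as in [make_assembly()].
#' @return the [make_assembly()] result, plus `expected_path` (chromophore
#'   ids in planted order) and `cutoff`.
#' @export
plant_path <- function(n, step = 20, cutoff = 35, seed = 1L,
                       dir = tempdir(), name = "planted") {
  if (n < 2) stop("plant_path needs n >= 2", call. = FALSE)
  if (step >= cutoff) stop("step must be smaller than cutoff", call. = FALSE)
  margin <- 2 * .pentagon_radius + 0.2
  if (cutoff + margin >= 2 * step) {
    stop(sprintf(paste0("fixture spec error: cutoff %.1f is infeasible for step %.1f ",
                        "(two-step distances cannot exceed 2*step = %.1f by the triangle ",
                        "inequality); choose cutoff < %.1f or a larger step"),
                 cutoff, step, 2 * step, 2 * step - margin), call. = FALSE)
  }
  # arc turning angle: two-step chord 2*step*cos(phi/2) must clear cutoff+margin
  cmin <- (cutoff + margin) / (2 * step)
  phi <- 2 * acos((1 + cmin) / 2)
  if ((n - 1) * phi > pi) {
    stop(sprintf("fixture spec error: n = %d is too large for this step/cutoff (arc wraps); reduce n to <= %d",
                 n, floor(pi / phi) + 1L), call. = FALSE)
  }
  R <- step / (2 * sin(phi / 2))
  centers <- lapply(0:(n - 1), function(k) R * c(cos(k * phi), sin(k * phi), 0))
  upright <- .rotation_xyz(0, -pi / 2, 0)  # molecular long axis -> global z
  chroms <- lapply(seq_len(n), function(k) {
    if (k == 1) {
      list(center = centers[[k]], orientation = upright, role = "CpcB",
           region = list(compartment = "rod", rod_name = "R1", hexamer_index = 1L))
    } else if (k == n) {
      list(center = centers[[k]], orientation = upright, role = "ApcD",
           region = list(compartment = "core", cylinder = "A", layer = 4L))
    } else {
      list(center = centers[[k]], orientation = upright, role = "ApcA",
           region = list(compartment = "core", cylinder = "A", layer = min(k, 4L)))
    }
  })
  spec <- fixture_spec(chroms, decoys = list(), seed = seed, jitter = 0)
  out <- make_assembly(spec, dir = dir, name = name)

  # verify planted geometry from the written file by enumeration
  chrom_objs <- extract_chromophores(out$model, .toy_code)
  ids <- vapply(chrom_objs, `[[`, character(1), "id")
  ord <- match(vapply(out$manifest$chromophores, `[[`, character(1), "id"), ids)
  dm <- chromophore_distance_matrix(chrom_objs, metric = "min_conjugated_atom")
  pos <- match(dm$id1, ids[ord]); pos2 <- match(dm$id2, ids[ord])
  consec <- abs(pos - pos2) == 1
  if (any(dm$distance[consec] > cutoff) || any(dm$distance[!consec] <= cutoff)) {
    stop("fixture verification failed: planted chain is not the unique sub-cutoff path",
         call. = FALSE)
  }
  out$expected_path <- ids[ord]
  out$cutoff <- cutoff
  out$manifest$expected_path <- out$expected_path
  out$manifest$cutoff <- cutoff
  jsonlite::write_json(out$manifest, out$manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out
}
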