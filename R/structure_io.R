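#' Read an atomic assembly from mmCIF or PDB
#'
#' Parses a multi-chain coordinate file into a `pbs_assembly`: a flat atom
#' table plus per-chain summaries and a ligand-group inventory. Polymer and
#' ligand atoms are separated by component code (standard amino acids are
#' polymer; any other component, e.g. a bilin, is a ligand group). Waters are
#' dropped from the ligand inventory. Coordinates are kept exactly as read.
#'
#' Alternate locations are resolved to the highest-occupancy conformer (ties
#' broken by file order). Hydrogens are removed: all downstream distances use
#' the heavy-atom convention, and deposited cryo-EM models carry no hydrogens.
#'
#' @param path path to a `.cif`/`.mmcif` or `.pdb`/`.ent` file.
#' @param format `"auto"` (default, sniffed from extension then content),
#'   `"mmcif"` or `"pdb"`.
#' @param model model number to keep for multi-model files (default 1;
#'   deposited cryo-EM structures are single-model).
#' @return an object of class `pbs_assembly` with elements `atoms`
#'   (data.frame: chain, resno, insert, resid, elety, elesy, x, y, z, o,
#'   is_polymer, model), `chains`, `ligand_groups`, `annotations` (NULL until
#'   [annotate_subunits()]), and `source`.
#' @seealso [write_assembly_cif()], [annotate_subunits()],
#'   [extract_chromophores()]
#' @export
read_assembly <- function(path, format = c("auto", "mmcif", "pdb"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read structure file '%s': no such file", path), call. = FALSE)
  if (file.size(path) == 0) stop(sprintf("empty model: '%s' contains no atoms", path), call. = FALSE)
  if (format == "auto") format <- .sniff_format(path)

  pdb <- switch(format,
    mmcif = suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    pdb   = suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = (model > 1), verbose = FALSE)),
    stop(sprintf("unknown structure format '%s'", format), call. = FALSE))

  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop(sprintf("empty model: no atoms parsed from '%s'", path), call. = FALSE)
  }
  if (model > 1) {
    xyz <- pdb$xyz
    if (is.matrix(xyz) && nrow(xyz) >= model) {
      m <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
      at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
    } else {
      stop(sprintf("model %d requested but file has %d model(s)", model,
                   if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L), call. = FALSE)
    }
  }

  at$chain[is.na(at$chain)] <- " "
  # alternate locations: keep highest occupancy, ties by file order
  if (any(!is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- !duplicated(key[order(-occ, seq_len(nrow(at)))])
    keep <- keep[order(order(-occ, seq_len(nrow(at))))]
    at <- at[keep, , drop = FALSE]
  }
  # heavy atoms only
  ele <- toupper(ifelse(is.na(at$elesy) | at$elesy == "", .guess_element(at$elety), at$elesy))
  hyd <- ele %in% c("H", "D")
  at <- at[!hyd, , drop = FALSE]
  ele <- ele[!hyd]
  if (nrow(at) == 0) stop(sprintf("empty model: no heavy atoms in '%s'", path), call. = FALSE)

  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesy = ele,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    is_polymer = as.character(at$resid) %in% .aa3,
    model = as.integer(model),
    stringsAsFactors = FALSE)
  rownames(atoms) <- NULL

  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in atom records", call. = FALSE)
  }

  .new_assembly(atoms, source = list(path = path, format = format))
}

.new_assembly <- function(atoms, source = list(path = NA_character_, format = "memory"),
                          annotations = NULL) {
  pol <- atoms[atoms$is_polymer, , drop = FALSE]
  ch_ids <- sort(unique(atoms$chain))
  chains <- data.frame(
    chain = ch_ids,
    n_atoms = vapply(ch_ids, function(cid) sum(atoms$chain == cid), integer(1)),
    n_res = vapply(ch_ids, function(cid) {
      p <- pol[pol$chain == cid, , drop = FALSE]
      length(unique(paste(p$resno, p$insert)))
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(chains) <- NULL

  lig <- atoms[!atoms$is_polymer & !(atoms$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(lig)) {
    lg <- unique(lig[, c("chain", "resno", "resid")])
    lg <- lg[order(lg$chain, lg$resno), , drop = FALSE]
  } else {
    lg <- data.frame(chain = character(), resno = integer(), resid = character(),
                     stringsAsFactors = FALSE)
  }
  rownames(lg) <- NULL

  structure(list(atoms = atoms, chains = chains, ligand_groups = lg,
                 annotations = annotations, source = source),
            class = "pbs_assembly")
}

.sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^_atom_site\\.", head)) || any(grepl("^data_", head))) return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|CRYST1)", head))) return("pdb")
  stop(sprintf("unknown structure format for '%s' (not mmCIF, not PDB)", path), call. = FALSE)
}

.guess_element <- function(name) {
  n <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(n, 1, 2))
  one <- toupper(substr(n, 1, 1))
  ifelse(two %in% c("FE", "MG", "ZN", "MN", "CU", "NA", "CL", "BR"), two, one)
}

#' @export
print.pbs_assembly <- function(x, ...) {
  cat(sprintf("pbs_assembly: %d atoms, %d chains, %d ligand groups\n",
              nrow(x$atoms), nrow(x$chains), nrow(x$ligand_groups)))
  if (!is.null(x$annotations)) {
    tb <- table(x$annotations$role)
    cat("  roles:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  cat(sprintf("  source: %s (%s)\n", x$source$path %||% "<memory>", x$source$format))
  invisible(x)
}

#' Write an assembly to mmCIF
#'
#' Emits a minimal PDBx/mmCIF file (data block + `atom_site` loop in the
#' standard RCSB column order) that round-trips through [read_assembly()]
#' with identical atom counts and coordinates.
#'
#' @param model a `pbs_assembly`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly_cif <- function(model, path) {
  stopifnot(inherits(model, "pbs_assembly"))
  a <- model$atoms
  cols <- c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
            "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
            "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
            "auth_comp_id", "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")
  grp <- ifelse(a$is_polymer, "ATOM", "HETATM")
  ins <- ifelse(a$insert == "", "?", a$insert)
  # label_seq_id: sequential per-chain polymer numbering; "." for ligands
  seqid <- rep(".", nrow(a))
  for (cid in unique(a$chain)) {
    sel <- which(a$chain == cid & a$is_polymer)
    if (length(sel)) seqid[sel] <- as.character(match(a$resno[sel], sort(unique(a$resno[sel]))))
  }
  rows <- paste(grp, seq_len(nrow(a)), a$elesy, a$elety, ".", a$resid, a$chain,
                "1", seqid, ins,
                sprintf("%.3f", a$x), sprintf("%.3f", a$y), sprintf("%.3f", a$z),
                sprintf("%.2f", a$o), "0.00", "?",
                a$resno, a$resid, a$chain, a$elety, a$model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_pbsnet", "#", "loop_",
               paste0("_atom_site.", cols), rows, "#"), con)
  invisible(path)
}

#' Write an assembly to PDB format
#'
#' @param model a `pbs_assembly`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly_pdb <- function(model, path) {
  stopifnot(inherits(model, "pbs_assembly"))
  a <- model$atoms
  rec <- ifelse(a$is_polymer, "ATOM  ", "HETATM")
  lines <- sprintf("%s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, (seq_len(nrow(a)) - 1L) %% 99999 + 1L,
                   ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
                   " ", a$resid, substr(a$chain, 1, 1), a$resno,
                   substr(paste0(a$insert, " "), 1, 1),
                   a$x, a$y, a$z, a$o, 0, a$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Assembly dimensions along principal axes
#'
#' Rotates the atom point cloud to its principal axes and reports the sorted
#' box extents: the largest is the assembly length, the smallest its
#' thickness. For a hemidiscoidal phycobilisome these correspond to the
#' published length/height/thickness convention.
#'
#' @param model a `pbs_assembly`.
#' @return named numeric vector `c(length=, height=, thickness=)` in Angstrom.
#' @export
assembly_dimensions <- function(model) {
  stopifnot(inherits(model, "pbs_assembly"))
  xyz <- .axyz(model$atoms)
  if (nrow(xyz) < 3) stop("degenerate geometry: fewer than 3 atoms", call. = FALSE)
  X <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(X, nu = 0)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate geometry: atoms are collinear", call. = FALSE)
  }
  P <- X %*% sv$v
  ext <- sort(apply(P, 2, function(v) diff(range(v))), decreasing = TRUE)
  c(length = ext[1], height = ext[2], thickness = ext[3])
}

# ---- subunit annotation -----------------------------------------------------

.blank_region <- function() {
  list(compartment = "none", cylinder = "none", layer = NA_integer_,
       rod_name = "none", hexamer_index = NA_integer_)
}

.validate_region <- function(region, chain) {
  region <- utils::modifyList(.blank_region(), region[!vapply(region, is.null, logical(1))])
  if (!region$compartment %in% .pbs_compartments)
    stop(sprintf("chain %s: unknown compartment '%s'", chain, region$compartment), call. = FALSE)
  if (!region$cylinder %in% .pbs_cylinders)
    stop(sprintf("chain %s: unknown cylinder '%s'", chain, region$cylinder), call. = FALSE)
  if (!region$rod_name %in% .rod_names)
    stop(sprintf("chain %s: unknown rod name '%s'", chain, region$rod_name), call. = FALSE)
  if (!is.na(region$layer) && !(region$layer %in% 1:4))
    stop(sprintf("chain %s: layer must be 1..4", chain), call. = FALSE)
  if (region$compartment == "core" && region$cylinder == "none")
    stop(sprintf("chain %s: core region requires a cylinder label", chain), call. = FALSE)
  if (region$compartment == "rod" && region$rod_name == "none")
    stop(sprintf("chain %s: rod region requires a rod name", chain), call. = FALSE)
  region
}

#' Read a subunit-annotation config
#'
#' YAML with two optional sections: `chains` (map from chain id to
#' `role` + region fields `compartment`, `cylinder`, `layer`, `rod_name`,
#' `hexamer_index`) and `patterns` (list of rules with a `match` regular
#' expression on chain ids plus the same fields). See
#' `system.file("extdata", "annotation-template.yaml", package = "pbsnet")`.
#'
#' @param path YAML file path.
#' @return a config list usable by [annotate_subunits()].
#' @export
read_annotation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$chains <- cfg$chains %||% list()
  cfg$patterns <- cfg$patterns %||% list()
  cfg
}

#' Attach subunit roles and core/rod region labels to chains
#'
#' Applies a role-mapping config to every chain. Explicit `chains` entries
#' and `patterns` rules are matched together; a chain matched by two rules
#' that disagree on the role is an error naming both rules. Unmatched chains
#' get role `"other"` (with a warning).
#'
#' @param model a `pbs_assembly`.
#' @param config list with `chains` and/or `patterns`, as from
#'   [read_annotation_config()].
#' @return the model with an `annotations` data.frame (chain, role,
#'   compartment, cylinder, layer, rod_name, hexamer_index) attached.
#' @export
annotate_subunits <- function(model, config) {
  stopifnot(inherits(model, "pbs_assembly"))
  chains <- model$chains$chain
  rules <- list()
  for (cid in names(config$chains %||% list())) {
    e <- config$chains[[cid]]
    rules[[length(rules) + 1L]] <- list(label = sprintf("chains[%s]", cid),
                                        target = cid, exact = TRUE, spec = e)
  }
  for (i in seq_along(config$patterns %||% list())) {
    e <- config$patterns[[i]]
    if (is.null(e$match)) stop(sprintf("patterns[%d] has no 'match' field", i), call. = FALSE)
    rules[[length(rules) + 1L]] <- list(label = sprintf("patterns[%d] (match '%s')", i, e$match),
                                        pattern = e$match, exact = FALSE, spec = e)
  }

  ann <- vector("list", length(chains))
  for (k in seq_along(chains)) {
    cid <- chains[k]
    hits <- Filter(function(r) {
      if (isTRUE(r$exact)) identical(r$target, cid) else grepl(r$pattern, cid)
    }, rules)
    if (length(hits) > 1L) {
      roles <- vapply(hits, function(r) r$spec$role %||% "other", character(1))
      if (length(unique(roles)) > 1L) {
        stop(sprintf("ambiguous annotation for chain %s: rules %s assign roles %s",
                     cid, paste(vapply(hits, `[[`, character(1), "label"), collapse = " and "),
                     paste(unique(roles), collapse = " vs ")), call. = FALSE)
      }
    }
    if (length(hits) == 0L) {
      ann[[k]] <- c(list(chain = cid, role = "other", unmatched = TRUE), .blank_region())
      next
    }
    spec <- hits[[1L]]$spec
    role <- spec$role %||% "other"
    if (!role %in% .pbs_roles)
      stop(sprintf("chain %s: unknown role '%s'", cid, role), call. = FALSE)
    region <- .validate_region(spec[setdiff(names(spec), c("role", "match"))], cid)
    ann[[k]] <- c(list(chain = cid, role = role), region)
  }
  unmatched <- vapply(ann, function(a) isTRUE(a$unmatched), logical(1))
  if (any(unmatched)) {
    warning(sprintf("%d chain(s) matched no annotation rule (role set to 'other'): %s",
                    sum(unmatched), paste(chains[unmatched], collapse = ", ")),
            call. = FALSE)
  }
  model$annotations <- do.call(rbind, lapply(ann, function(a) {
    data.frame(chain = a$chain, role = a$role, compartment = a$compartment,
               cylinder = a$cylinder, layer = a$layer, rod_name = a$rod_name,
               hexamer_index = a$hexamer_index %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
  rownames(model$annotations) <- NULL
  model
}

#' Propose a draft subunit annotation from chain heuristics
#'
#' Guesses phycobiliprotein roles from chain length and bilin content:
#' alpha/beta subunits are ~160-175 residues with 1-3 bilins, the
#' core-membrane linker ApcE is very long (>= 600 residues) and
#' chromophorylated, ApcC is short (< 80 residues) and bilin-free; other
#' bilin-free chains are proposed as rod/rod-core linkers. The result is a
#' *draft* config for the user to confirm and refine (roles that depend on
#' sequence, such as ApcD vs ApcA or ApcF vs ApcB, cannot be decided from
#' geometry alone and are labelled with the generic candidate).
#'
#' @param model a `pbs_assembly`.
#' @param bilin_codes ligand component codes counted as bilins.
#' @param write_to optional path: write the draft config as YAML.
#' @return config list (invisibly writes YAML when `write_to` is given).
#' @export
auto_annotate <- function(model, bilin_codes = .bilin_codes, write_to = NULL) {
  stopifnot(inherits(model, "pbs_assembly"))
  lg <- model$ligand_groups
  out <- list()
  for (k in seq_len(nrow(model$chains))) {
    cid <- model$chains$chain[k]
    nres <- model$chains$n_res[k]
    nbil <- sum(lg$chain == cid & lg$resid %in% bilin_codes)
    role <- if (nres >= 600 && nbil >= 1) "ApcE"
      else if (nres < 80 && nbil == 0 && nres > 0) "ApcC"
      else if (nbil >= 2) "CpcB"         # beta-PC carries 2 bilins
      else if (nbil == 1 && nres >= 120) "ApcA"
      else if (nbil == 0 && nres >= 150) "CpcC"
      else "other"
    out[[cid]] <- list(role = role)
  }
  cfg <- list(chains = out, patterns = list())
  if (!is.null(write_to)) yaml::write_yaml(cfg, write_to)
  invisible(cfg)
}

# ---- census -----------------------------------------------------------------

.require_annotation <- function(model) {
  if (is.null(model$annotations))
    stop("annotation required: call annotate_subunits() first", call. = FALSE)
  invisible(TRUE)
}

#' Chain census by role and region
#'
#' Counts annotated chains per role within each region, optionally filtered.
#'
#' @param model an annotated `pbs_assembly`.
#' @param role optional character vector of roles to keep.
#' @param compartment optional `"core"` or `"rod"` filter.
#' @return data.frame role, compartment, cylinder, layer, rod_name, count.
#' @export
count_subunits <- function(model, role = NULL, compartment = NULL) {
  stopifnot(inherits(model, "pbs_assembly"))
  .require_annotation(model)
  an <- model$annotations
  if (!is.null(role)) an <- an[an$role %in% role, , drop = FALSE]
  if (!is.null(compartment)) an <- an[an$compartment %in% compartment, , drop = FALSE]
  if (nrow(an) == 0) {
    return(data.frame(role = character(), compartment = character(),
                      cylinder = character(), layer = integer(),
                      rod_name = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- c("role", "compartment", "cylinder", "layer", "rod_name")
  grp <- an[key]
  grp$layer <- ifelse(is.na(grp$layer), "none", as.character(grp$layer))
  k <- do.call(paste, c(grp, sep = "\r"))
  tb <- table(k)
  parts <- do.call(rbind, strsplit(names(tb), "\r", fixed = TRUE))
  agg <- data.frame(role = parts[, 1], compartment = parts[, 2],
                    cylinder = parts[, 3],
                    layer = suppressWarnings(as.integer(parts[, 4])),
                    rod_name = parts[, 5], count = as.integer(tb),
                    stringsAsFactors = FALSE)
  agg <- agg[order(agg$role, agg$compartment, agg$cylinder, agg$layer, agg$rod_name,
                   na.last = TRUE), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Count alpha-beta monomers per trimer layer
#'
#' A phycobiliprotein alpha-beta monomer is one alpha-role chain paired with
#' one beta-role chain in the same trimer layer (same compartment, cylinder,
#' layer, rod name and hexamer index). The count per layer is
#' `min(n_alpha, n_beta)`; for complete trimers this equals 3.
#'
#' @param model an annotated `pbs_assembly`.
#' @param family `"APC"` (alpha roles ApcA/ApcD/ApcE, beta roles ApcB/ApcF)
#'   or `"PC"` (CpcA / CpcB).
#' @param compartment optional `"core"`/`"rod"` filter.
#' @return integer monomer count.
#' @export
count_monomers <- function(model, family = c("APC", "PC"), compartment = NULL) {
  stopifnot(inherits(model, "pbs_assembly"))
  .require_annotation(model)
  family <- match.arg(family)
  a_roles <- if (family == "APC") .alpha_roles_apc else "CpcA"
  b_roles <- if (family == "APC") .beta_roles_apc else "CpcB"
  an <- model$annotations
  if (!is.null(compartment)) an <- an[an$compartment %in% compartment, , drop = FALSE]
  an <- an[an$role %in% c(a_roles, b_roles), , drop = FALSE]
  if (nrow(an) == 0) return(0L)
  key <- paste(an$compartment, an$cylinder, an$layer, an$rod_name, an$hexamer_index, sep = "|")
  total <- 0L
  for (k in unique(key)) {
    sub <- an[key == k, , drop = FALSE]
    total <- total + min(sum(sub$role %in% a_roles), sum(sub$role %in% b_roles))
  }
  total
}
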