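# Rigid-body placements of PBS copies and inter-complex bilin contacts.
# Placements come from an external fitting (e.g. into a tomographic array
# map); this module consumes the transforms and runs the distance check.

#' Construct a rigid-body placement
#'
#' @param rotation 3x3 proper orthonormal matrix (checked to 1e-6).
#' @param translation length-3 numeric vector in Angstrom.
#' @param label text label appended to chain ids when applied.
#' @return a `placement` object.
#' @export
placement <- function(rotation = diag(3), translation = c(0, 0, 0), label = "copy") {
  .check_rotation(rotation)
  stopifnot(length(translation) == 3)
  structure(list(rotation = matrix(as.numeric(rotation), 3, 3),
                 translation = as.numeric(translation), label = as.character(label)),
            class = "placement")
}

#' Read placements from a transform file
#'
#' Two formats: plain text with one placement per line -- 12 whitespace-
#' separated numbers, the row-major 3x3 rotation followed by the translation
#' (lines starting with `#` ignored; labels default to `copy1`, `copy2`,
#' ...) -- or a JSON file: an array of objects with fields `rotation` (9
#' numbers, row-major, or 3x3 nested), `translation` (3 numbers), `label`.
#'
#' @param path file path (`.json` triggers the JSON reader).
#' @return list of `placement` objects.
#' @export
read_placements <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read placements: '%s' not found", path), call. = FALSE)
  if (tolower(tools::file_ext(path)) == "json") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    return(lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      R <- matrix(as.numeric(unlist(r$rotation)), 3, 3, byrow = TRUE)
      placement(R, as.numeric(r$translation), r$label %||% sprintf("copy%d", i))
    }))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    v <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
    if (length(v) != 12 || anyNA(v)) {
      stop(sprintf("placement line %d: expected 12 numbers (row-major rotation + translation)", i),
           call. = FALSE)
    }
    placement(matrix(v[1:9], 3, 3, byrow = TRUE), v[10:12], sprintf("copy%d", i))
  })
}

#' Apply a rigid-body placement to an assembly
#'
#' Every atom position is mapped `x -> R x + t`. Annotations are preserved
#' (re-keyed to the new chain ids); the placement label is appended to each
#' chain id so that copies remain distinguishable after merging.
#'
#' @param model a `pbs_assembly`.
#' @param placement a `placement`.
#' @return the transformed `pbs_assembly`.
#' @export
apply_placement <- function(model, placement) {
  stopifnot(inherits(model, "pbs_assembly"), inherits(placement, "placement"))
  .check_rotation(placement$rotation)
  a <- model$atoms
  xyz <- .axyz(a) %*% t(placement$rotation)
  a$x <- xyz[, 1] + placement$translation[1]
  a$y <- xyz[, 2] + placement$translation[2]
  a$z <- xyz[, 3] + placement$translation[3]
  suffix <- paste0("_", placement$label)
  ann <- model$annotations
  if (!is.null(ann)) ann$chain <- paste0(ann$chain, suffix)
  a$chain <- paste0(a$chain, suffix)
  out <- .new_assembly(a, source = list(path = model$source$path,
                                        format = paste0(model$source$format, "+placed")),
                       annotations = ann)
  out
}

#' Inter-complex bilin contacts between two placed PBS copies
#'
#' All cross-copy chromophore pairs at or below the cutoff (default 40 A,
#' the permissive transfer bound for stacked complexes), ascending by
#' distance, with each side's region labels. The summary flags whether every
#' contact involves a layer-1 or layer-4 basal-cylinder bilin of at least
#' one copy -- the geometry by which adjacent cores stack first layer
#' against fourth layer.
#'
#' @param copyA,copyB `pbs_assembly` objects (each carrying bilins).
#' @param cutoff contact cutoff in Angstrom.
#' @param metric distance metric, see [chromophore_distance()].
#' @param component_codes bilin component codes.
#' @return data.frame idA, idB, distance, compartmentA, cylinderA, layerA,
#'   compartmentB, cylinderB, layerB; attribute `"summary"` holds
#'   `n_contacts`, `min_distance`, `all_via_layer_1_or_4`.
#' @export
inter_complex_contacts <- function(copyA, copyB, cutoff = 40,
                                   metric = c("min_conjugated_atom", "min_any_atom", "centroid"),
                                   component_codes = .bilin_codes) {
  metric <- match.arg(metric)
  ca <- extract_chromophores(copyA, component_codes)
  cb <- extract_chromophores(copyB, component_codes)
  if (length(ca) == 0 || length(cb) == 0) {
    stop("empty input: both copies must carry chromophores", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(ca)) {
    xa <- .chrom_xyz(ca[[i]], metric)
    for (j in seq_along(cb)) {
      d <- .min_cross_dist(xa, .chrom_xyz(cb[[j]], metric))
      if (d <= cutoff) {
        ra <- ca[[i]]$region; rb <- cb[[j]]$region
        rows[[length(rows) + 1L]] <- data.frame(
          idA = ca[[i]]$id, idB = cb[[j]]$id, distance = d,
          compartmentA = ra$compartment, cylinderA = ra$cylinder, layerA = ra$layer,
          compartmentB = rb$compartment, cylinderB = rb$cylinder, layerB = rb$layer,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(idA = character(), idB = character(), distance = numeric(),
               compartmentA = character(), cylinderA = character(), layerA = integer(),
               compartmentB = character(), cylinderB = character(), layerB = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  basal <- function(cyl, lay) cyl %in% c("A", "A'") & lay %in% c(1L, 4L)
  attr(out, "summary") <- list(
    n_contacts = nrow(out),
    min_distance = if (nrow(out)) min(out$distance) else NA_real_,
    all_via_layer_1_or_4 = if (nrow(out))
      all(basal(out$cylinderA, out$layerA) | basal(out$cylinderB, out$layerB))
    else NA)
  out
}
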