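# Pipeline orchestration: census -> network -> paths -> environment,
# mirroring the order in which a PBS structural analysis is reported.

#' Assemble a pipeline run configuration
#'
#' Defaults are resolved here so the summary report can echo the full
#' effective configuration.
#'
#' @param input path to an mmCIF/PDB structure.
#' @param annotation path to an annotation YAML ([read_annotation_config()]),
#'   or `NULL` to run unannotated (census and emitter report are skipped).
#' @param outdir output directory.
#' @param metric chromophore distance metric (default min conjugated atom).
#' @param cutoff network edge cutoff in Angstrom (default 40).
#' @param weight_mode path objective weights (default `distance_power6`).
#' @param shells neighbourhood shells in Angstrom (default 5 and 10).
#' @param component_codes bilin component codes to extract.
#' @param pi_thresholds pi-interaction thresholds, see
#'   [classify_pi_interaction()].
#' @param seed integer seed echoed into the report (the pipeline itself is
#'   deterministic).
#' @param verbose print one line per stage.
#' @return a `run_config` list.
#' @export
run_config <- function(input, annotation = NULL, outdir = tempfile("pbsnet_run_"),
                       metric = "min_conjugated_atom", cutoff = 40,
                       weight_mode = "distance_power6", shells = c(5, 10),
                       component_codes = .bilin_codes,
                       pi_thresholds = .default_pi_thresholds,
                       seed = 1L, verbose = TRUE) {
  stopifnot(cutoff > 0, all(shells > 0))
  structure(list(input = input, annotation = annotation, outdir = outdir,
                 metric = metric, cutoff = cutoff, weight_mode = weight_mode,
                 shells = shells, component_codes = component_codes,
                 pi_thresholds = utils::modifyList(.default_pi_thresholds, pi_thresholds),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Pre-flight diagnostics for a pipeline configuration
#'
#' Checks file existence, format sniffing, annotation coverage and
#' chromophore presence without mutating anything.
#'
#' @param config a `run_config`.
#' @return data.frame severity ("error"/"warning"/"info"), check, message.
#' @export
validate_inputs <- function(config) {
  diags <- list()
  add <- function(severity, check, message) {
    diags[[length(diags) + 1L]] <<- data.frame(severity = severity, check = check,
                                               message = message, stringsAsFactors = FALSE)
  }
  if (!file.exists(config$input)) {
    add("error", "input", sprintf("input file '%s' does not exist", config$input))
  } else {
    fmt <- tryCatch(.sniff_format(config$input), error = function(e) NA_character_)
    if (is.na(fmt)) {
      add("error", "format", sprintf("cannot sniff format of '%s'", config$input))
    } else {
      add("info", "format", sprintf("input format: %s", fmt))
      model <- tryCatch(read_assembly(config$input), error = function(e) NULL)
      if (is.null(model)) {
        add("error", "parse", "input file failed to parse")
      } else {
        chroms <- extract_chromophores(model, config$component_codes)
        if (length(chroms) == 0) {
          add("warning", "chromophores",
              sprintf("no chromophores matched component codes %s",
                      paste(config$component_codes, collapse = ",")))
        } else {
          add("info", "chromophores", sprintf("%d chromophores found", length(chroms)))
        }
        if (!is.null(config$annotation)) {
          if (!file.exists(config$annotation)) {
            add("error", "annotation", sprintf("annotation file '%s' does not exist", config$annotation))
          } else {
            cfg <- tryCatch(read_annotation_config(config$annotation), error = function(e) NULL)
            if (is.null(cfg)) {
              add("error", "annotation", "annotation config failed to parse")
            } else {
              m2 <- tryCatch(suppressWarnings(annotate_subunits(model, cfg)),
                             error = function(e) NULL)
              if (is.null(m2)) {
                add("error", "annotation", "annotation rules failed to apply")
              } else {
                cov <- mean(m2$annotations$role != "other")
                lvl <- if (cov < 1) "warning" else "info"
                add(lvl, "annotation_coverage",
                    sprintf("%.0f%% of chains annotated with a specific role", 100 * cov))
              }
            }
          }
        } else {
          add("warning", "annotation", "no annotation config: census and emitter report will be skipped")
        }
      }
    }
  }
  do.call(rbind, diags)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load + annotate; chromophore table; subunit and
#' chromophore censuses; EET network (GraphML + edge TSV); terminal-emitter
#' path report (JSON); per-chromophore contact shells with pi/cation-pi
#' classification (TSV); aromatic census (TSV); summary JSON echoing the
#' effective configuration. Outputs are written into `config$outdir`; a
#' MANIFEST file records which stages completed, so partial output from a
#' failed run is identifiable.
#'
#' @param config a `run_config`.
#' @return invisible list with the summary and the main in-memory objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$outdir, "MANIFEST")
  done <- character(0)
  note <- function(stage, msg) {
    done <<- c(done, stage)
    writeLines(done, manifest_path)
    if (config$verbose) message(sprintf("[%s] %s", stage, msg))
  }
  fail <- function(stage, e) {
    writeLines(c(done, paste0("FAILED:", stage)), manifest_path)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  }

  model <- tryCatch({
    m <- read_assembly(config$input)
    if (!is.null(config$annotation)) {
      m <- annotate_subunits(m, read_annotation_config(config$annotation))
    }
    m
  }, error = function(e) fail("load", e))
  note("load", sprintf("%d atoms, %d chains, %d ligand groups",
                       nrow(model$atoms), nrow(model$chains), nrow(model$ligand_groups)))

  chroms <- tryCatch(extract_chromophores(model, config$component_codes),
                     error = function(e) fail("extract", e))
  if (length(chroms) == 0) fail("extract", simpleError("no chromophores matched"))
  ctab <- chromophore_table(chroms)
  utils::write.table(.round_cols(ctab), file.path(config$outdir, "chromophores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("extract", sprintf("%d chromophores", length(chroms)))

  census <- NULL
  if (!is.null(model$annotations)) {
    census <- tryCatch(count_subunits(model), error = function(e) fail("census", e))
    utils::write.table(census, file.path(config$outdir, "subunit_census.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp <- table(factor(ctab$compartment, levels = c("core", "rod", "none")))
    chrom_census <- data.frame(compartment = names(comp), count = as.integer(comp),
                               stringsAsFactors = FALSE)
    chrom_census <- rbind(chrom_census,
                          data.frame(compartment = "total_chromophores",
                                     count = length(chroms), stringsAsFactors = FALSE))
    utils::write.table(chrom_census, file.path(config$outdir, "chromophore_census.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("census", sprintf("%d chains in census; %d bilins (core %d / rod %d)",
                           sum(census$count), length(chroms),
                           comp[["core"]], comp[["rod"]]))
  }

  net <- tryCatch(build_network(chroms, cutoff = config$cutoff, metric = config$metric,
                                weight_mode = config$weight_mode),
                  error = function(e) fail("network", e))
  write_network(net, graphml = file.path(config$outdir, "network.graphml"),
                tsv = file.path(config$outdir, "network_edges.tsv"))
  note("network", sprintf("%d nodes, %d edges", nrow(net$nodes), nrow(net$edges)))

  emitter_report <- NULL
  if (any(net$nodes$emitter) && any(net$nodes$compartment == "rod")) {
    emitter_report <- tryCatch(terminal_emitter_report(net), error = function(e) fail("paths", e))
    paths <- attr(emitter_report, "paths")
    jsonlite::write_json(
      list(report = emitter_report,
           paths = lapply(paths, function(p) p[c("nodes", "step_distances",
                                                 "total_weight", "bottleneck")])),
      file.path(config$outdir, "emitter_paths.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("paths", sprintf("%d source-emitter routes", nrow(emitter_report)))
  }

  contacts <- tryCatch({
    rows <- lapply(chroms, function(ch) {
      nb <- chromophore_neighborhood(model, ch, cutoff = max(config$shells))
      if (nrow(nb) == 0) return(nb)
      cls <- vapply(seq_len(nrow(nb)), function(i) {
        ann <- tryCatch(classify_residue_bilin(model, nb$chain[i], nb$resno[i], ch,
                                               thresholds = config$pi_thresholds),
                        error = function(e) NULL)
        if (is.null(ann)) "none" else ann$kind
      }, character(1))
      nb$interaction <- cls
      nb
    })
    do.call(rbind, rows)
  }, error = function(e) fail("contacts", e))
  utils::write.table(.round_cols(contacts), file.path(config$outdir, "contacts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("contacts", sprintf("%d residue-bilin contacts within %.1f A",
                           nrow(contacts), max(config$shells)))

  arom <- NULL
  if (!is.null(model$annotations)) {
    arom <- tryCatch(aromatic_census(model, chroms, cutoff = min(config$shells),
                                     grouping = "role"),
                     error = function(e) fail("aromatic_census", e))
    utils::write.table(.round_cols(arom), file.path(config$outdir, "aromatic_census.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("aromatic_census", sprintf("%d group(s)", nrow(arom)))
  }

  summary <- list(
    config = config[c("input", "annotation", "metric", "cutoff", "weight_mode",
                      "shells", "component_codes", "pi_thresholds", "seed")],
    n_atoms = nrow(model$atoms), n_chains = nrow(model$chains),
    n_chromophores = length(chroms),
    n_core = sum(ctab$compartment == "core"),
    n_rod = sum(ctab$compartment == "rod"),
    total_chromophores = length(chroms),
    n_edges = nrow(net$edges),
    n_emitters = sum(net$nodes$emitter),
    emitter_routes = if (!is.null(emitter_report)) nrow(emitter_report) else 0L,
    recovered_paths = if (!is.null(emitter_report)) {
      lapply(attr(emitter_report, "paths"), `[[`, "nodes")
    } else NULL,
    stages = done)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("summary", sprintf("written to %s", config$outdir))
  invisible(list(summary = summary, model = model, chromophores = chroms,
                 network = net, emitter_report = emitter_report,
                 contacts = contacts, census = census, aromatic = arom))
}

# round numeric columns to 2 decimals for TSV output (full precision stays
# in the JSON reports)
.round_cols <- function(df) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], 2)
  df
}
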