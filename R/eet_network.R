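# Distance-weighted chromophore graphs and energy-transfer path deduction.
#
# "Most probable path" is operationalised three ways: additive distance,
# additive distance^6 (Forster-like steep distance dependence; the default),
# and bottleneck (minimise the longest hop). All tie-breaking is
# deterministic: among equal-weight optima the lexicographically smallest
# node-id sequence is returned.

#' Build an excitation-energy-transfer network over chromophores
#'
#' All-pairs distances are computed under the chosen metric and pairs at or
#' below the cutoff become undirected edges. The default cutoff of 40
#' Angstrom is the permissive bilin-pair contact bound used when assessing
#' transfer between stacked complexes. Terminal-emitter flags are set for
#' chromophores whose parent subunit is ApcD or ApcE (the alpha-LCM domain);
#' ApcF bilins, the conserved bridge to alpha-LCM, are flagged separately.
#'
#' @param chromophores list of `chromophore` objects (>= 1).
#' @param cutoff edge cutoff in Angstrom (> 0), default 40.
#' @param metric distance metric, see [chromophore_distance()].
#' @param weight_mode `"distance_power6"` (default) or `"distance"`.
#' @return an `eet_network`: list with `nodes` (id, role, emitter, apcf,
#'   compartment, cylinder, layer, rod_name), `edges` (id1, id2, distance,
#'   weight), `cutoff`, `metric`, `weight_mode`.
#' @export
build_network <- function(chromophores, cutoff = 40,
                          metric = c("min_conjugated_atom", "min_any_atom", "centroid"),
                          weight_mode = c("distance_power6", "distance")) {
  metric <- match.arg(metric)
  weight_mode <- match.arg(weight_mode)
  if (length(chromophores) < 1) stop("need at least one chromophore", call. = FALSE)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)

  ord <- order(vapply(chromophores, `[[`, character(1), "chain"),
               vapply(chromophores, `[[`, numeric(1), "resno"))
  chromophores <- chromophores[ord]
  nodes <- do.call(rbind, lapply(chromophores, function(ch) {
    role <- ch$parent_role %||% NA_character_
    data.frame(id = ch$id, role = role,
               emitter = isTRUE(role %in% c("ApcD", "ApcE")),
               apcf = isTRUE(role %in% "ApcF"),
               compartment = ch$region$compartment, cylinder = ch$region$cylinder,
               layer = ch$region$layer, rod_name = ch$region$rod_name,
               stringsAsFactors = FALSE)
  }))
  rownames(nodes) <- NULL

  dm <- chromophore_distance_matrix(chromophores, metric = metric)
  edges <- dm[dm$distance <= cutoff, c("id1", "id2", "distance"), drop = FALSE]
  edges$weight <- .edge_weight(edges$distance, weight_mode)
  edges <- edges[order(edges$id1, edges$id2), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges, cutoff = cutoff,
                 metric = metric, weight_mode = weight_mode),
            class = "eet_network")
}

.edge_weight <- function(d, weight_mode) {
  switch(weight_mode, distance = d, distance_power6 = d^6,
         stop(sprintf("unknown weight_mode '%s'", weight_mode), call. = FALSE))
}

#' @export
print.eet_network <- function(x, ...) {
  cat(sprintf("eet_network: %d nodes, %d edges (cutoff %.1f A, metric %s, weights %s)\n",
              nrow(x$nodes), nrow(x$edges), x$cutoff, x$metric, x$weight_mode))
  if (any(x$nodes$emitter)) {
    cat("  terminal emitters:", paste(x$nodes$id[x$nodes$emitter], collapse = ", "), "\n")
  }
  invisible(x)
}

.check_node <- function(network, id) {
  if (!id %in% network$nodes$id) {
    stop(sprintf("unknown node id '%s'", id), call. = FALSE)
  }
  invisible(TRUE)
}

# igraph view of the network (names = node ids, edge attrs distance/weight).
.as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges[, c("id1", "id2", "distance", "weight"), drop = FALSE],
    directed = FALSE,
    vertices = network$nodes[, "id", drop = FALSE])
}

# Adjacency list: for each node, data.frame of (neighbour, distance, weight),
# neighbours sorted lexicographically. Basis for deterministic traversal.
.adjacency <- function(network) {
  e <- network$edges
  both <- rbind(
    data.frame(from = e$id1, to = e$id2, distance = e$distance, weight = e$weight,
               stringsAsFactors = FALSE),
    data.frame(from = e$id2, to = e$id1, distance = e$distance, weight = e$weight,
               stringsAsFactors = FALSE))
  both <- both[order(both$from, both$to), , drop = FALSE]
  split(both[, c("to", "distance", "weight")], both$from)
}

.path_result <- function(network, nodes) {
  if (length(nodes) == 1) {
    return(structure(list(nodes = nodes, step_distances = numeric(0),
                          total_weight = 0, bottleneck = 0,
                          weight_mode = network$weight_mode), class = "eet_path"))
  }
  e <- network$edges
  key <- paste(pmin(e$id1, e$id2), pmax(e$id1, e$id2))
  want <- paste(pmin(nodes[-length(nodes)], nodes[-1]), pmax(nodes[-length(nodes)], nodes[-1]))
  idx <- match(want, key)
  if (anyNA(idx)) stop("internal error: path step is not a network edge", call. = FALSE)
  structure(list(nodes = nodes, step_distances = e$distance[idx],
                 total_weight = sum(e$weight[idx]),
                 bottleneck = max(e$distance[idx]),
                 weight_mode = network$weight_mode), class = "eet_path")
}

#' @export
print.eet_path <- function(x, ...) {
  cat(sprintf("eet_path: %d node(s), total weight %.6g (%s), bottleneck %.2f A\n",
              length(x$nodes), x$total_weight, x$weight_mode, x$bottleneck))
  cat(" ", paste(x$nodes, collapse = " -> "), "\n")
  invisible(x)
}

# Lexicographically smallest minimum-weight path from source to sink within
# an igraph g (edge attribute "weight"), or NULL when disconnected. Greedy
# walk along the shortest-path DAG: at each node take the smallest-id
# neighbour that stays optimal (distance-to-sink certificate).
.lex_shortest <- function(g, source, sink, rel_tol = 1e-9) {
  if (source == sink) return(source)
  vn <- igraph::V(g)$name
  if (!(source %in% vn) || !(sink %in% vn)) return(NULL)
  dts <- igraph::distances(g, v = sink, weights = igraph::E(g)$weight)[1, ]
  if (!is.finite(dts[[source]])) return(NULL)
  path <- source
  cur <- source
  visited <- character(0)
  while (cur != sink) {
    visited <- c(visited, cur)
    nb <- igraph::neighbors(g, cur)$name
    nb <- sort(setdiff(nb, visited))
    found <- FALSE
    for (u in nb) {
      eid <- igraph::get_edge_ids(g, c(cur, u))
      w <- igraph::E(g)$weight[eid]
      tol <- rel_tol * max(1, abs(dts[[cur]]))
      if (abs(w + dts[[u]] - dts[[cur]]) <= tol) {
        path <- c(path, u)
        cur <- u
        found <- TRUE
        break
      }
    }
    if (!found) return(NULL)  # numerically stuck; cannot certify optimality
  }
  path
}

#' Shortest (most probable) energy-transfer path
#'
#' Minimal total-weight simple path under the network's weight mode, with
#' deterministic tie-breaking: among equal-weight optima the
#' lexicographically smallest node-id sequence is returned. `NULL` when the
#' two chromophores are in different components.
#'
#' @param network an `eet_network`.
#' @param source,sink node ids.
#' @return an `eet_path` (nodes, step_distances, total_weight, bottleneck)
#'   or `NULL`.
#' @export
eet_shortest_path <- function(network, source, sink) {
  .check_node(network, source); .check_node(network, sink)
  if (source == sink) return(.path_result(network, source))
  g <- .as_igraph(network)
  nodes <- .lex_shortest(g, source, sink)
  if (is.null(nodes)) return(NULL)
  .path_result(network, nodes)
}

#' k shortest loopless energy-transfer paths
#'
#' Yen's algorithm over the lexicographic shortest-path routine: returns up
#' to `k` simple paths in non-decreasing total weight (ties ordered
#' lexicographically); the first element equals [eet_shortest_path()].
#'
#' @param network an `eet_network`.
#' @param source,sink node ids.
#' @param k maximum number of paths (>= 1).
#' @return list of `eet_path`, possibly shorter than `k`; empty when
#'   disconnected.
#' @export
eet_k_shortest_paths <- function(network, source, sink, k) {
  .check_node(network, source); .check_node(network, sink)
  stopifnot(k >= 1)
  if (source == sink) return(list(.path_result(network, source)))
  g <- .as_igraph(network)
  first <- .lex_shortest(g, source, sink)
  if (is.null(first)) return(list())
  A <- list(first)
  B <- list()   # candidate node sequences
  while (length(A) < k) {
    prev <- A[[length(A)]]
    for (j in seq_len(length(prev) - 1L)) {
      spur <- prev[j]
      root <- prev[seq_len(j)]
      g2 <- g
      # remove edges that would reproduce an already-accepted path
      for (p in A) {
        if (length(p) > j && identical(p[seq_len(j)], root)) {
          eid <- suppressWarnings(igraph::get_edge_ids(g2, c(p[j], p[j + 1L])))
          if (length(eid) && eid > 0) g2 <- igraph::delete_edges(g2, eid)
        }
      }
      # remove root-path nodes except the spur node
      if (j > 1L) g2 <- igraph::delete_vertices(g2, root[seq_len(j - 1L)])
      tail_nodes <- .lex_shortest(g2, spur, sink)
      if (is.null(tail_nodes)) next
      cand <- c(root[-j], tail_nodes)
      if (!any(vapply(c(A, B), identical, logical(1), y = cand))) {
        B[[length(B) + 1L]] <- cand
      }
    }
    if (length(B) == 0) break
    w <- vapply(B, function(p) .path_result(network, p)$total_weight, numeric(1))
    lex <- vapply(B, paste, character(1), collapse = "\r")
    best <- order(w, lex)[1]
    A[[length(A) + 1L]] <- B[[best]]
    B <- B[-best]
  }
  lapply(A, .path_result, network = network)
}

#' Bottleneck (minimax) energy-transfer path
#'
#' Path minimising the longest hop distance; an alternative reading of
#' "shortest distances between bilin pairs" where the limiting step, not the
#' sum, matters. Ties are broken by total weight, then lexicographically.
#'
#' @param network an `eet_network`.
#' @param source,sink node ids.
#' @return an `eet_path` or `NULL` when disconnected.
#' @export
eet_bottleneck_path <- function(network, source, sink) {
  .check_node(network, source); .check_node(network, sink)
  if (source == sink) return(.path_result(network, source))
  e <- network$edges
  if (nrow(e) == 0) return(NULL)
  thresholds <- sort(unique(e$distance))
  g_full <- .as_igraph(network)
  reachable <- function(t) {
    keep <- which(e$distance <= t)
    g <- igraph::subgraph_from_edges(g_full, keep, delete.vertices = FALSE)
    d <- igraph::distances(g, v = source, to = sink, weights = NA)
    is.finite(d[1, 1])
  }
  lo <- 1L; hi <- length(thresholds)
  if (!reachable(thresholds[hi])) return(NULL)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (reachable(thresholds[mid])) hi <- mid else lo <- mid + 1L
  }
  t_star <- thresholds[lo]
  g <- igraph::subgraph_from_edges(g_full, which(e$distance <= t_star),
                                   delete.vertices = FALSE)
  nodes <- .lex_shortest(g, source, sink)
  if (is.null(nodes)) return(NULL)
  .path_result(network, nodes)
}

#' Best routes from source bilins to the terminal emitters
#'
#' For each source chromophore, finds the minimum-weight path to the nearest
#' (by path weight) ApcD bilin and ApcE (alpha-LCM) bilin, reports the
#' ordered region trace (compartment/cylinder/layer or rod labels along the
#' route), and flags whether an ApcF bilin lies on the alpha-LCM route --
#' the conserved bridge geometry of the basal-cylinder third layer.
#'
#' @param network an `eet_network` built from an annotated assembly.
#' @param sources character vector of source node ids, or `NULL` for all
#'   rod-compartment bilins.
#' @return data.frame with one row per (source, emitter class): columns
#'   source, emitter_role, sink, n_steps, total_weight, bottleneck,
#'   region_trace, apcf_on_route; the paths themselves are attached as the
#'   `"paths"` attribute (list of `eet_path`).
#' @export
terminal_emitter_report <- function(network, sources = NULL) {
  nodes <- network$nodes
  if (!any(nodes$emitter)) {
    stop("configuration error: no terminal emitters flagged (no ApcD/ApcE bilins)",
         call. = FALSE)
  }
  if (is.null(sources)) {
    sources <- nodes$id[nodes$compartment == "rod"]
    if (length(sources) == 0) {
      stop("no rod-compartment bilins to use as sources; pass `sources` explicitly",
           call. = FALSE)
    }
  }
  for (s in sources) .check_node(network, s)

  region_label <- function(id) {
    r <- nodes[nodes$id == id, , drop = FALSE]
    if (r$compartment == "core") {
      sprintf("core:%s%s", r$cylinder, ifelse(is.na(r$layer), "", r$layer))
    } else if (r$compartment == "rod") {
      sprintf("rod:%s", r$rod_name)
    } else "none"
  }

  rows <- list()
  paths <- list()
  for (s in sources) {
    for (em_role in c("ApcD", "ApcE")) {
      sinks <- nodes$id[nodes$role %in% em_role]
      best <- NULL
      for (t in sort(sinks)) {
        p <- eet_shortest_path(network, s, t)
        if (is.null(p)) next
        if (is.null(best) || p$total_weight < best$total_weight ||
            (p$total_weight == best$total_weight &&
             paste(p$nodes, collapse = "\r") < paste(best$nodes, collapse = "\r"))) {
          best <- p
        }
      }
      if (is.null(best)) next
      trace <- vapply(best$nodes, region_label, character(1))
      apcf_on <- any(nodes$apcf[match(best$nodes, nodes$id)])
      rows[[length(rows) + 1L]] <- data.frame(
        source = s, emitter_role = em_role, sink = best$nodes[length(best$nodes)],
        n_steps = length(best$step_distances), total_weight = best$total_weight,
        bottleneck = best$bottleneck,
        region_trace = paste(trace, collapse = " > "),
        apcf_on_route = apcf_on, stringsAsFactors = FALSE)
      paths[[sprintf("%s|%s", s, em_role)]] <- best
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), emitter_role = character(), sink = character(),
               n_steps = integer(), total_weight = numeric(), bottleneck = numeric(),
               region_trace = character(), apcf_on_route = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "paths") <- paths
  out
}

#' Export a network as GraphML and/or a TSV edge list
#'
#' @param network an `eet_network`.
#' @param graphml,tsv output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_network <- function(network, graphml = NULL, tsv = NULL) {
  written <- list()
  if (!is.null(graphml)) {
    g <- .as_igraph(network)
    n <- network$nodes
    idx <- match(igraph::V(g)$name, n$id)
    igraph::V(g)$role <- ifelse(is.na(n$role[idx]), "", n$role[idx])
    igraph::V(g)$emitter <- n$emitter[idx]
    igraph::V(g)$region <- paste(n$compartment[idx], n$cylinder[idx],
                                 n$layer[idx], n$rod_name[idx], sep = "|")
    igraph::write_graph(g, graphml, format = "graphml")
    written$graphml <- graphml
  }
  if (!is.null(tsv)) {
    utils::write.table(network$edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written$tsv <- tsv
  }
  invisible(written)
}
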