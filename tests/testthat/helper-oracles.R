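`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures and independent brute-force oracles for the test suite.
# The oracles deliberately avoid the package's own graph/distance code
# paths: exhaustive enumeration and direct double loops only.

# Exhaustive minimum distance between two atom coordinate matrices.
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# All simple paths between two nodes of an undirected weighted graph given
# as a symmetric weight matrix with NA for missing edges. Returns a list of
# integer node vectors.
enumerate_simple_paths <- function(W, from, to) {
  n <- nrow(W)
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!is.na(W[cur, nxt]) && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(from)
  out
}

path_total <- function(W, path, power = 1) {
  if (length(path) < 2) return(0)
  sum(mapply(function(i, j) W[i, j]^power, path[-length(path)], path[-1]))
}

path_bottleneck <- function(W, path) {
  if (length(path) < 2) return(0)
  max(mapply(function(i, j) W[i, j], path[-length(path)], path[-1]))
}

# Best simple path by exhaustive enumeration under an additive objective
# (ties: lexicographically smallest node sequence). Returns NULL when the
# nodes are disconnected.
oracle_shortest <- function(W, from, to, power = 1) {
  paths <- enumerate_simple_paths(W, from, to)
  if (length(paths) == 0) return(NULL)
  w <- vapply(paths, path_total, numeric(1), W = W, power = power)
  lex <- vapply(paths, paste, character(1), collapse = ",")
  paths[[order(w, lex)[1]]]
}

oracle_k_shortest <- function(W, from, to, k, power = 1) {
  paths <- enumerate_simple_paths(W, from, to)
  if (length(paths) == 0) return(list())
  w <- vapply(paths, path_total, numeric(1), W = W, power = power)
  lex <- vapply(paths, paste, character(1), collapse = ",")
  paths[order(w, lex)][seq_len(min(k, length(paths)))]
}

oracle_bottleneck <- function(W, from, to, power = 1) {
  paths <- enumerate_simple_paths(W, from, to)
  if (length(paths) == 0) return(NULL)
  b <- vapply(paths, path_bottleneck, numeric(1), W = W)
  w <- vapply(paths, path_total, numeric(1), W = W, power = power)
  lex <- vapply(paths, paste, character(1), collapse = ",")
  paths[[order(b, w, lex)[1]]]
}

# Random connected-ish undirected distance graph on n nodes; returns the
# symmetric matrix with NA off-edges. Node ids are n01, n02, ... so that
# lexicographic and numeric orders agree.
random_distance_graph <- function(n, p_edge = 0.5, d_range = c(5, 40)) {
  W <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        W[i, j] <- W[j, i] <- stats::runif(1, d_range[1], d_range[2])
      }
    }
  }
  W
}

# Wrap a weight matrix as an eet_network (container built directly; the
# algorithms under test consume it through the public API).
net_from_matrix <- function(W, weight_mode = "distance", roles = NULL) {
  n <- nrow(W)
  ids <- sprintf("n%02d", seq_len(n))
  roles <- roles %||% rep(NA_character_, n)
  nodes <- data.frame(id = ids, role = roles,
                      emitter = roles %in% c("ApcD", "ApcE"),
                      apcf = roles %in% "ApcF",
                      compartment = "none", cylinder = "none",
                      layer = NA_integer_, rod_name = "none",
                      stringsAsFactors = FALSE)
  es <- which(upper.tri(W) & !is.na(W), arr.ind = TRUE)
  edges <- data.frame(id1 = ids[es[, 1]], id2 = ids[es[, 2]],
                      distance = W[es], stringsAsFactors = FALSE)
  edges$weight <- if (weight_mode == "distance_power6") edges$distance^6 else edges$distance
  edges <- edges[order(edges$id1, edges$id2), , drop = FALSE]
  structure(list(nodes = nodes, edges = edges, cutoff = max(W, na.rm = TRUE),
                 metric = "centroid", weight_mode = weight_mode),
            class = "eet_network")
}

# A small standard fixture: 3 bilins (one per role ApcA/ApcD/ApcF) with two
# decoy residues at known distances. Cached per session.
basic_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(
        chromophores = list(
          list(center = c(0, 0, 0), role = "CpcB",
               region = list(compartment = "rod", rod_name = "R1", hexamer_index = 1L)),
          list(center = c(20, 0, 0), role = "ApcA",
               region = list(compartment = "core", cylinder = "A", layer = 3L)),
          list(center = c(40, 5, 0), role = "ApcD",
               region = list(compartment = "core", cylinder = "A", layer = 4L))),
        decoys = list(
          list(type = "TYR", target = 3L, ring = "D", distance = 5.0),
          list(type = "ARG", target = 2L, ring = "B", distance = 4.0),
          list(type = "PHE", target = 2L, ring = "A", distance = 4.5)),
        seed = 11L)
      cache <<- make_assembly(spec, dir = tempfile("basicfx"), name = "basic")
    }
    cache
  }
})

rotate_model <- function(model, R, t = c(0, 0, 0)) {
  apply_placement(model, placement(R, t, label = "rot"))
}

random_rotation_matrix <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}
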