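test_that("network edges equal brute-force pair enumeration under the cutoff", {
  centers <- list(c(0, 0, 0), c(18, 0, 0), c(30, 14, 0), c(55, 0, 0), c(70, 20, 0))
  chroms <- lapply(centers, function(ctr) {
    list(center = ctr, region = list(compartment = "core", cylinder = "A", layer = 1L))
  })
  fx <- make_assembly(fixture_spec(chroms, seed = 5L), dir = tempfile(), name = "net5")
  objs <- extract_chromophores(fx$model)
  cutoff <- 25
  net <- build_network(objs, cutoff = cutoff, metric = "min_conjugated_atom")
  # oracle: all 10 pairs by brute force over conjugated atoms
  ids <- vapply(objs, `[[`, character(1), "id")
  want <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    a <- as.matrix(objs[[i]]$atoms[objs[[i]]$conjugated, c("x", "y", "z")])
    b <- as.matrix(objs[[j]]$atoms[objs[[j]]$conjugated, c("x", "y", "z")])
    d <- brute_min_dist(a, b)
    if (d <= cutoff) want[[length(want) + 1L]] <- c(ids[i], ids[j], d)
  }
  expect_equal(nrow(net$edges), length(want))
  for (w in want) {
    row <- net$edges[net$edges$id1 == w[1] & net$edges$id2 == w[2], ]
    expect_equal(row$distance, as.numeric(w[3]), tolerance = 1e-9)
  }
  # no self-edges; each unordered pair once; weights follow the mode
  expect_false(any(net$edges$id1 == net$edges$id2))
  expect_false(any(duplicated(paste(net$edges$id1, net$edges$id2))))
  expect_equal(net$edges$weight, net$edges$distance^6)
  # two chromophores farther than the cutoff -> no edge
  far <- build_network(objs[c(1, 4)], cutoff = 40)
  expect_equal(nrow(far$edges), 0)
})

test_that("shortest, k-shortest and bottleneck paths agree with exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    W <- random_distance_graph(n, p_edge = 0.55)
    for (mode in c("distance", "distance_power6")) {
      pw <- if (mode == "distance_power6") 6 else 1
      net <- net_from_matrix(W, weight_mode = mode)
      ids <- net$nodes$id
      from <- 1L; to <- n
      want <- oracle_shortest(W, from, to, power = pw)
      got <- eet_shortest_path(net, ids[from], ids[to])
      if (is.null(want)) {
        expect_null(got)
        expect_equal(eet_k_shortest_paths(net, ids[from], ids[to], 3), list())
        expect_null(eet_bottleneck_path(net, ids[from], ids[to]))
        next
      }
      expect_equal(got$nodes, ids[want])
      expect_equal(got$total_weight, path_total(W, want, pw), tolerance = 1e-9)

      wantk <- oracle_k_shortest(W, from, to, 4, power = pw)
      gotk <- eet_k_shortest_paths(net, ids[from], ids[to], 4)
      expect_equal(length(gotk), length(wantk))
      expect_equal(lapply(gotk, function(p) unname(p$nodes)),
                   lapply(wantk, function(p) ids[p]))
      # first element equals the shortest path
      expect_equal(gotk[[1]]$nodes, got$nodes)

      wantb <- oracle_bottleneck(W, from, to, power = pw)
      gotb <- eet_bottleneck_path(net, ids[from], ids[to])
      expect_equal(gotb$bottleneck, path_bottleneck(W, wantb), tolerance = 1e-9)
    }
  }
})

test_that("path algorithms cross-check against igraph on a random graph", {
  set.seed(77)
  W <- random_distance_graph(8, p_edge = 0.6)
  net <- net_from_matrix(W, weight_mode = "distance")
  g <- igraph::graph_from_data_frame(net$edges[, c("id1", "id2", "weight")],
                                     directed = FALSE,
                                     vertices = net$nodes$id)
  ref <- igraph::distances(g, v = "n01", to = "n08", weights = igraph::E(g)$weight)[1, 1]
  p <- eet_shortest_path(net, "n01", "n08")
  if (is.finite(ref)) {
    expect_equal(p$total_weight, ref, tolerance = 1e-9)
  } else {
    expect_null(p)
  }
})

test_that("trivial path cases behave per contract", {
  W <- matrix(NA_real_, 3, 3)
  W[1, 2] <- W[2, 1] <- 10
  net <- net_from_matrix(W)
  # source = sink -> single-node path of weight 0
  p <- eet_shortest_path(net, "n01", "n01")
  expect_equal(p$nodes, "n01")
  expect_equal(p$total_weight, 0)
  expect_equal(p$bottleneck, 0)
  expect_equal(eet_bottleneck_path(net, "n02", "n02")$bottleneck, 0)
  # disconnected -> NULL / empty list
  expect_null(eet_shortest_path(net, "n01", "n03"))
  expect_equal(eet_k_shortest_paths(net, "n01", "n03", 5), list())
  # unknown node id errors by name
  expect_error(eet_shortest_path(net, "n01", "zz"), "zz")
})

test_that("equal-weight optima break ties toward the lexicographically smallest route", {
  W <- matrix(NA_real_, 4, 4)
  W[1, 2] <- W[2, 1] <- 10
  W[1, 3] <- W[3, 1] <- 10
  W[2, 4] <- W[4, 2] <- 10
  W[3, 4] <- W[4, 3] <- 10
  net <- net_from_matrix(W)
  p <- eet_shortest_path(net, "n01", "n04")
  expect_equal(p$nodes, c("n01", "n02", "n04"))
  ps <- eet_k_shortest_paths(net, "n01", "n04", 2)
  expect_equal(lapply(ps, `[[`, "nodes"),
               list(c("n01", "n02", "n04"), c("n01", "n03", "n04")))
  b <- eet_bottleneck_path(net, "n01", "n04")
  expect_equal(b$nodes, c("n01", "n02", "n04"))
})

test_that("bottleneck routing prefers two short hops over one long edge", {
  W <- matrix(NA_real_, 3, 3)
  W[1, 3] <- W[3, 1] <- 30           # direct edge
  W[1, 2] <- W[2, 1] <- 18           # two-hop route
  W[2, 3] <- W[3, 2] <- 18
  net <- net_from_matrix(W)
  p <- eet_bottleneck_path(net, "n01", "n03")
  expect_equal(p$nodes, c("n01", "n02", "n03"))
  expect_equal(p$bottleneck, 18)
})

test_that("k-shortest weights are non-decreasing and adding edges never hurts", {
  set.seed(31)
  for (rep in 1:10) {
    W <- random_distance_graph(7, p_edge = 0.6)
    net <- net_from_matrix(W)
    ps <- eet_k_shortest_paths(net, "n01", "n07", 5)
    if (length(ps) >= 2) {
      w <- vapply(ps, `[[`, numeric(1), "total_weight")
      expect_true(all(diff(w) >= -1e-9))
    }
    # add one new edge: shortest-path weight cannot increase
    empty <- which(is.na(W) & upper.tri(W), arr.ind = TRUE)
    if (nrow(empty) && length(ps)) {
      ij <- empty[1, ]
      W2 <- W
      W2[ij[1], ij[2]] <- W2[ij[2], ij[1]] <- stats::runif(1, 5, 40)
      p2 <- eet_shortest_path(net_from_matrix(W2), "n01", "n07")
      expect_lte(p2$total_weight, ps[[1]]$total_weight + 1e-9)
    }
  }
})

test_that("distance^6 weighting prefers a direct hop unless both relay hops are much shorter", {
  # single hop d vs two hops a, b: d^6 < a^6 + b^6 whenever both a,b > d/2^(1/6)
  d <- 20
  thr <- d * 2^(-1 / 6)
  for (ab in list(c(thr + 0.1, thr + 0.1), c(16, 16))) {
    W <- matrix(NA_real_, 3, 3)
    W[1, 3] <- W[3, 1] <- d
    W[1, 2] <- W[2, 1] <- ab[1]
    W[2, 3] <- W[3, 2] <- ab[2]
    net <- net_from_matrix(W, weight_mode = "distance_power6")
    p <- eet_shortest_path(net, "n01", "n03")
    if (all(ab > thr)) {
      expect_equal(p$nodes, c("n01", "n03"))
    } else {
      expect_equal(p$nodes, c("n01", "n02", "n03"))
    }
  }
})

test_that("terminal emitter report traces planted routes and flags ApcF bridges", {
  # rod source -> B-cylinder relay -> ApcF bridge -> ApcE sink, plus an
  # ApcD sink reachable through the same relay
  chroms <- list(
    list(center = c(0, 0, 0), role = "CpcB",
         region = list(compartment = "rod", rod_name = "R2", hexamer_index = 1L)),
    list(center = c(20, 0, 0), role = "ApcA",
         region = list(compartment = "core", cylinder = "B", layer = 1L)),
    list(center = c(40, 0, 0), role = "ApcF",
         region = list(compartment = "core", cylinder = "A", layer = 3L)),
    list(center = c(60, 0, 0), role = "ApcE",
         region = list(compartment = "core", cylinder = "A", layer = 3L)),
    list(center = c(40, 20, 0), role = "ApcD",
         region = list(compartment = "core", cylinder = "A", layer = 4L)))
  up <- pbsnet:::.rotation_xyz(0, -pi / 2, 0)
  for (i in seq_along(chroms)) chroms[[i]]$orientation <- up
  fx <- make_assembly(fixture_spec(chroms, seed = 9L), dir = tempfile(), name = "ter")
  objs <- extract_chromophores(fx$model)
  net <- build_network(objs, cutoff = 30)
  rep_ <- terminal_emitter_report(net)
  ids <- vapply(objs, `[[`, character(1), "id")
  apcd <- rep_[rep_$emitter_role == "ApcD", ]
  apce <- rep_[rep_$emitter_role == "ApcE", ]
  expect_equal(apcd$source, ids[1])
  expect_match(apcd$region_trace, "^rod:R2 > core:B1")
  expect_true(apce$apcf_on_route)
  expect_match(apce$region_trace, "core:A3 > core:A3$")
  # a network with no emitters is a configuration error
  noem <- build_network(objs[1:2], cutoff = 30)
  expect_error(terminal_emitter_report(noem, sources = noem$nodes$id[1]),
               "no terminal emitters")
})

test_that("network export writes GraphML and TSV", {
  fx <- basic_fixture()
  net <- build_network(extract_chromophores(fx$model), cutoff = 40)
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  write_network(net, graphml = gml, tsv = tsv)
  expect_true(file.exists(gml) && file.size(gml) > 0)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
})
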