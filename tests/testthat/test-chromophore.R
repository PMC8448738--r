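test_that("ring partition follows the bilin atom nomenclature", {
  names <- c("NA", "C1A", "C2A", "C3A", "C4A", "CHB", "NB", "C1B",
             "CBA", "CMA", "O1A", "CAB")
  expect_warning(pr <- partition_rings(names), "partial ring")
  expect_equal(names[pr$A], c("NA", "C1A", "C2A", "C3A", "C4A"))
  expect_equal(names[pr$HB], "CHB")
  expect_equal(names[pr$B], c("NB", "C1B"))
  # side-chain atoms (propionate CBA/CAB, methyl CMA, carbonyl O1A) excluded
  side <- c("CBA", "CMA", "O1A", "CAB")
  expect_false(any(match(side, names) %in% pr$conjugated))
  expect_error(partition_rings(c("XX", "YY")), "nomenclature")
})

test_that("toy chromophores partition into four 5-atom rings and three bridges", {
  tc <- toy_chromophore(c(3, -2, 7))
  expect_equal(nrow(tc), 23)
  pr <- partition_rings(tc$elety)
  expect_equal(unname(vapply(pr[c("A", "B", "C", "D")], length, integer(1))),
               rep(5L, 4))
  expect_equal(unname(vapply(pr[c("HB", "HC", "HD")], length, integer(1))),
               rep(1L, 3))
  ctr <- colMeans(tc[pr$conjugated, c("x", "y", "z")])
  expect_lt(max(abs(ctr - c(3, -2, 7))), 1e-6)
})

test_that("chromophore distances are symmetric, metric-consistent and match brute force", {
  fx <- basic_fixture()
  chroms <- extract_chromophores(fx$model)
  expect_length(chroms, 3)
  for (m in c("min_conjugated_atom", "min_any_atom", "centroid")) {
    d12 <- chromophore_distance(chroms[[1]], chroms[[2]], m)
    d21 <- chromophore_distance(chroms[[2]], chroms[[1]], m)
    expect_identical(d12, d21)
    expect_equal(chromophore_distance(chroms[[1]], chroms[[1]], m), 0)
  }
  # min-any over a superset of pairs can only be smaller
  expect_lte(chromophore_distance(chroms[[1]], chroms[[2]], "min_any_atom"),
             chromophore_distance(chroms[[1]], chroms[[2]], "min_conjugated_atom"))
  # brute-force oracle over every atom pair
  a <- as.matrix(chroms[[1]]$atoms[, c("x", "y", "z")])
  b <- as.matrix(chroms[[2]]$atoms[, c("x", "y", "z")])
  expect_equal(chromophore_distance(chroms[[1]], chroms[[2]], "min_any_atom"),
               brute_min_dist(a, b), tolerance = 1e-12)
  # centroid bound: min over conjugated pairs <= centroid dist + both radii
  dc <- chromophore_distance(chroms[[1]], chroms[[2]], "centroid")
  rad <- function(ch) {
    xyz <- as.matrix(ch$atoms[ch$conjugated, c("x", "y", "z")])
    max(sqrt(rowSums(sweep(xyz, 2, ch$centroid)^2)))
  }
  expect_lte(chromophore_distance(chroms[[1]], chroms[[2]], "min_conjugated_atom"),
             dc + rad(chroms[[1]]) + rad(chroms[[2]]) + 1e-9)
})

test_that("distances are invariant under rigid motion to 1e-6 A", {
  fx <- basic_fixture()
  chroms <- extract_chromophores(fx$model)
  set.seed(7)
  R <- random_rotation_matrix()
  m2 <- rotate_model(fx$model, R, c(-30, 12, 99))
  chroms2 <- extract_chromophores(m2)
  for (m in c("min_conjugated_atom", "min_any_atom", "centroid")) {
    expect_lt(abs(chromophore_distance(chroms[[1]], chroms[[3]], m) -
                  chromophore_distance(chroms2[[1]], chroms2[[3]], m)), 1e-6)
  }
})

test_that("parent roles come from the nearest polymer chain", {
  fx <- basic_fixture()
  chroms <- extract_chromophores(fx$model)
  expect_equal(vapply(chroms, `[[`, character(1), "parent_role"),
               c("CpcB", "ApcA", "ApcD"))
  expect_equal(vapply(chroms, function(ch) ch$region$compartment, character(1)),
               c("rod", "core", "core"))
  # empty component set -> empty list, not an error
  expect_length(extract_chromophores(fx$model, character(0)), 0)
})

test_that("residue-to-ring distances hit engineered values and validate selections", {
  fx <- basic_fixture()
  chroms <- extract_chromophores(fx$model)
  # decoy TYR planted at exactly 5.0 A from ring D of the ApcD bilin
  tyr <- fx$manifest$decoys[[1]]
  d <- residue_ring_distance(fx$model, tyr$chain, tyr$resno, chroms[[3]], target = "D")
  expect_equal(d, 5.0, tolerance = 0.011 / 5)
  expect_equal(round_half_up(d, 0), 5)
  # an exact in-memory construction: one TYR OH atom at 5 A from a ring-D atom
  tc <- toy_chromophore(c(0, 0, 0))
  ringD <- tc[grepl("^(N|C[1-4])D$", tc$elety), ]
  probe <- c(ringD$x[1], ringD$y[1], ringD$z[1] + 5)
  atoms <- rbind(
    data.frame(chain = "X", resno = 1L, insert = "", resid = "TYR",
               elety = c("OH", "N", "CA", "C", "O"), elesy = c("O", "N", "C", "C", "O"),
               x = c(probe[1], 99, 99, 99, 99), y = c(probe[2], 99, 99, 99, 99),
               z = c(probe[3], 99, 99, 99, 99), o = 1, is_polymer = TRUE, model = 1L),
    data.frame(chain = "X", resno = 201L, insert = "", resid = "TBL",
               elety = tc$elety, elesy = tc$elesy, x = tc$x, y = tc$y, z = tc$z,
               o = 1, is_polymer = FALSE, model = 1L))
  m <- pbsnet:::.new_assembly(atoms)
  ch <- extract_chromophores(m)[[1]]
  expect_equal(residue_ring_distance(m, "X", 1L, ch, target = "D"), 5.0,
               tolerance = 1e-9)
  # side-chain-free residue under the default selection errors
  gly <- m
  gly$atoms$elety[gly$atoms$resid == "TYR"] <- c("CA", "N", "C", "O", "OXT")
  expect_error(residue_ring_distance(gly, "X", 1L, ch), "side-chain")
  # unknown residue and absent ring label error informatively
  expect_error(residue_ring_distance(m, "Z", 1L, ch), "not found")
  degen <- ch
  degen$ring_map$B <- integer(0)
  expect_error(residue_ring_distance(m, "X", 1L, degen, target = "B"), "no ring B")
})
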