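# hexagon ring helper: radius 1.4 A in the plane spanned by (e1, e2)
hexagon <- function(center, e1 = c(1, 0, 0), e2 = c(0, 1, 0), r = 1.4) {
  ang <- 2 * pi * (0:5) / 6
  t(sapply(ang, function(a) center + r * cos(a) * e1 + r * sin(a) * e2))
}

test_that("parallel stacked rings classify as pi-pi parallel with ~0 degree angle", {
  r1 <- hexagon(c(0, 0, 0))
  r2 <- hexagon(c(0, 0, 3.5))
  ann <- classify_pi_interaction(r1, r2)
  expect_equal(ann$kind, "pi_pi_parallel")
  expect_lt(ann$interplanar_angle, 1e-6)
  expect_equal(ann$centroid_distance, 3.5, tolerance = 1e-9)
  expect_lt(ann$offset, 1e-9)
})

test_that("perpendicular rings at 5 A classify as T-shaped with ~90 degree angle", {
  r1 <- hexagon(c(0, 0, 0))
  r2 <- hexagon(c(0, 0, 5), e1 = c(1, 0, 0), e2 = c(0, 0, 1))
  ann <- classify_pi_interaction(r1, r2)
  expect_equal(ann$kind, "pi_pi_tshaped")
  expect_gt(ann$interplanar_angle, 89.999)
  expect_equal(ann$centroid_distance, 5, tolerance = 1e-9)
})

test_that("interplanar angles match the closed-form normal-vector value", {
  # second ring tilted by exactly 30 degrees about x
  th <- 30 * pi / 180
  e2b <- c(0, cos(th), sin(th))
  r1 <- hexagon(c(0, 0, 0))
  r2 <- hexagon(c(0, 0, 4), e1 = c(1, 0, 0), e2 = e2b)
  ann <- classify_pi_interaction(r1, r2)
  # oracle: dot product of the two known normals
  n1 <- c(0, 0, 1)
  n2 <- c(0, -sin(th), cos(th))
  want <- acos(abs(sum(n1 * n2))) * 180 / pi
  expect_equal(ann$interplanar_angle, want, tolerance = 1e-6)
  # classification is invariant to atom input order
  ann2 <- classify_pi_interaction(r1[sample(6), ], r2[sample(6), ])
  expect_equal(ann2$interplanar_angle, ann$interplanar_angle, tolerance = 1e-9)
  expect_identical(ann2$kind, ann$kind)
  # collinear "ring" -> degenerate plane error
  line <- cbind(1:5, 0, 0)
  expect_error(classify_pi_interaction(line, r2), "degenerate|collinear")
})

test_that("cation-pi classification follows the centroid distance threshold", {
  ring <- hexagon(c(0, 0, 0))
  gua <- rbind(c(0, 0, 4), c(1.2, 0, 4.4), c(-1.2, 0, 4.4), c(0, 1.2, 4.6))
  near <- classify_cation_pi(gua, ring)
  expect_equal(near$kind, "cation_pi")
  far <- classify_cation_pi(gua + matrix(rep(c(0, 0, 8), each = 4), 4), ring)
  expect_equal(far$kind, "none")
  expect_error(classify_cation_pi(matrix(numeric(0), 0, 3), ring), "empty selection")
})

test_that("classification geometry is invariant under rigid motion", {
  set.seed(19)
  R <- random_rotation_matrix()
  t <- c(14, -3, 28)
  r1 <- hexagon(c(0, 0, 0)); r2 <- hexagon(c(1, 0.5, 3.6))
  a1 <- classify_pi_interaction(r1, r2)
  a2 <- classify_pi_interaction(r1 %*% t(R) + rep(1, 6) %o% t,
                                r2 %*% t(R) + rep(1, 6) %o% t)
  expect_lt(abs(a1$centroid_distance - a2$centroid_distance), 1e-6)
  expect_lt(abs(a1$interplanar_angle - a2$interplanar_angle), 1e-6)
  expect_identical(a1$kind, a2$kind)
})

test_that("neighbourhood search matches a brute-force scan and respects the cutoff", {
  fx <- basic_fixture()
  m <- fx$model
  chroms <- extract_chromophores(m)
  ch <- chroms[[2]]  # ApcA bilin, targets of ARG (4.0 A, ring B) and PHE (4.5, ring A)
  nb <- chromophore_neighborhood(m, ch, cutoff = 10, target = "any")
  # oracle: loop over every polymer residue and atom pair
  pol <- m$atoms[m$atoms$is_polymer & !(m$atoms$elety %in% c("N", "CA", "C", "O", "OXT")), ]
  keys <- unique(paste(pol$chain, pol$resno))
  lig <- as.matrix(ch$atoms[, c("x", "y", "z")])
  want <- list()
  for (k in keys) {
    parts <- strsplit(k, " ")[[1]]
    res <- pol[pol$chain == parts[1] & pol$resno == as.integer(parts[2]), ]
    d <- brute_min_dist(as.matrix(res[, c("x", "y", "z")]), lig)
    if (d <= 10) want[[k]] <- d
  }
  expect_equal(nrow(nb), length(want))
  for (i in seq_len(nrow(nb))) {
    expect_equal(nb$min_distance[i], want[[paste(nb$chain[i], nb$resno[i])]],
                 tolerance = 1e-9)
  }
  expect_true(!is.unsorted(nb$min_distance))
  # shrinking the cutoff below the nearest planted decoy (4.0 A) while
  # excluding the anchor cysteine empties the shell
  tight <- chromophore_neighborhood(m, ch, cutoff = 3.9, target = "conjugated",
                                    exclude_attachment = TRUE)
  expect_equal(nrow(tight), 0)
  # the planted ARG appears at its intended distance with the right ring
  arg <- nb[nb$resid == "ARG", ]
  expect_equal(nrow(arg), 1)
  expect_equal(arg$min_distance, 4.0, tolerance = 0.011 / 4)
  expect_equal(arg$nearest_ring, "B")
})

test_that("residue-level dispatcher classifies planted decoys correctly", {
  fx <- basic_fixture()
  m <- fx$model
  chroms <- extract_chromophores(m)
  arg_meta <- fx$manifest$decoys[[2]]
  ann <- classify_residue_bilin(m, arg_meta$chain, arg_meta$resno, chroms[[2]])
  expect_equal(ann$kind, "cation_pi")
  expect_equal(ann$ring, "B")
  tyr_meta <- fx$manifest$decoys[[1]]
  ann2 <- classify_residue_bilin(m, tyr_meta$chain, tyr_meta$resno, chroms[[3]])
  expect_equal(ann2$residue$resid, "TYR")
  expect_true(ann2$kind %in% c("pi_pi_parallel", "pi_pi_tshaped", "none"))
  expect_equal(ann2$ring, "D")
})

test_that("aromatic census counts planted residues and grows with the cutoff", {
  # 4 TYR around one bilin, none around the other
  chroms <- list(
    list(center = c(0, 0, 0), role = "ApcA",
         region = list(compartment = "core", cylinder = "A", layer = 1L)),
    list(center = c(60, 0, 0), role = "ApcB",
         region = list(compartment = "core", cylinder = "A", layer = 2L)))
  decoys <- lapply(1:4, function(i) list(type = "TYR", target = 1L,
                                         ring = c("A", "B", "C", "D")[i],
                                         distance = 4.0 + 0.2 * i))
  fx <- make_assembly(fixture_spec(chroms, decoys, seed = 23L),
                      dir = tempfile(), name = "census")
  m <- fx$model
  objs <- extract_chromophores(m)
  cen <- aromatic_census(m, objs, cutoff = 6, grouping = "role")
  oth <- cen[cen$group == "other", ]
  expect_equal(oth$TYR, 4)
  expect_equal(oth$total, 4)
  # census totals are non-decreasing in the cutoff
  cen_small <- aromatic_census(m, objs, cutoff = 4.5, grouping = "role")
  expect_lte(sum(cen_small$total), sum(cen$total))
  # polarization: all 4 aromatics sit near chromophore 1
  ids <- vapply(objs, `[[`, character(1), "id")
  pol <- sapply(fx$manifest$decoys, function(d) d$chain)
  for (dc in pol) {
    lp <- linker_polarization(m, objs, dc, proximal_ids = ids[1], cutoff = 6)
    expect_equal(lp$polarization, 1.0)
  }
})
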