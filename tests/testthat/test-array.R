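test_that("placements validate rotations and transform coordinates exactly", {
  fx <- basic_fixture()
  m <- fx$model
  # identity placement leaves coordinates unchanged
  m_id <- apply_placement(m, placement(diag(3), c(0, 0, 0), "id"))
  expect_equal(max(abs(m_id$atoms$x - m$atoms$x)), 0)
  # chain ids stay distinct across copies
  expect_true(all(endsWith(m_id$atoms$chain, "_id")))
  # pure translation shifts the centroid by exactly the translation
  m_tx <- apply_placement(m, placement(diag(3), c(10, 0, 0), "tx"))
  expect_equal(mean(m_tx$atoms$x) - mean(m$atoms$x), 10, tolerance = 1e-12)
  expect_equal(mean(m_tx$atoms$y) - mean(m$atoms$y), 0, tolerance = 1e-12)
  # non-orthonormal rotation is rejected with the residual
  bad <- diag(3); bad[1, 1] <- 1.01
  expect_error(placement(bad), "orthonormal")
  expect_error(apply_placement(m, structure(list(rotation = bad,
                                                 translation = c(0, 0, 0), label = "x"),
                                            class = "placement")),
               "orthonormal")
})

test_that("rigid placement preserves all intra-copy chromophore distances", {
  fx <- basic_fixture()
  set.seed(3)
  R <- random_rotation_matrix()
  moved <- apply_placement(fx$model, placement(R, c(7, -20, 31), "mv"))
  d0 <- chromophore_distance_matrix(extract_chromophores(fx$model), "min_any_atom")
  d1 <- chromophore_distance_matrix(extract_chromophores(moved), "min_any_atom")
  expect_lt(max(abs(d0$distance - d1$distance)), 1e-6)
})

test_that("placement files round-trip in both text and JSON formats", {
  p1 <- placement(pbsnet:::.rotation_xyz(0.2, -0.4, 1.1), c(5, 6, 7), "a")
  txt <- tempfile(fileext = ".txt")
  writeLines(c("# transform", paste(c(t(p1$rotation), p1$translation), collapse = " ")), txt)
  got <- read_placements(txt)
  expect_length(got, 1)
  expect_lt(max(abs(got[[1]]$rotation - p1$rotation)), 1e-12)
  expect_lt(max(abs(got[[1]]$translation - p1$translation)), 1e-12)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(rotation = as.numeric(t(p1$rotation)),
                                 translation = p1$translation, label = "copyA")),
                       js, auto_unbox = TRUE, digits = NA)
  gotj <- read_placements(js)
  expect_equal(gotj[[1]]$label, "copyA")
  expect_lt(max(abs(gotj[[1]]$rotation - p1$rotation)), 1e-12)
  # malformed line errors with its number
  bad <- tempfile(); writeLines("1 2 3", bad)
  expect_error(read_placements(bad), "12 numbers")
})

test_that("inter-complex contacts match brute-force cross enumeration and are symmetric", {
  fx <- basic_fixture()
  a <- apply_placement(fx$model, placement(diag(3), c(0, 0, 0), "A"))
  b <- apply_placement(fx$model, placement(diag(3), c(0, 35, 0), "B"))
  tab <- inter_complex_contacts(a, b, cutoff = 40, metric = "min_any_atom")
  # oracle: full cross product of chromophore pairs
  ca <- extract_chromophores(a); cb <- extract_chromophores(b)
  want <- 0L
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      d <- brute_min_dist(as.matrix(ca[[i]]$atoms[, c("x", "y", "z")]),
                          as.matrix(cb[[j]]$atoms[, c("x", "y", "z")]))
      if (d <= 40) {
        want <- want + 1L
        row <- tab[tab$idA == ca[[i]]$id & tab$idB == cb[[j]]$id, ]
        expect_equal(row$distance, d, tolerance = 1e-9)
      }
    }
  }
  expect_equal(nrow(tab), want)
  expect_true(!is.unsorted(tab$distance))
  # symmetry: swapping the copies swaps the id columns
  rev <- inter_complex_contacts(b, a, cutoff = 40, metric = "min_any_atom")
  expect_equal(sort(paste(tab$idA, tab$idB)), sort(paste(rev$idB, rev$idA)))
  # far-apart copies produce an empty table, not an error
  far <- apply_placement(fx$model, placement(diag(3), c(500, 0, 0), "F"))
  none <- inter_complex_contacts(a, far, cutoff = 40)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "summary")$n_contacts, 0)
})

test_that("co-moving both copies leaves the contact table invariant", {
  fx <- basic_fixture()
  a <- apply_placement(fx$model, placement(diag(3), c(0, 0, 0), "A"))
  b <- apply_placement(fx$model, placement(diag(3), c(0, 30, 0), "B"))
  t0 <- inter_complex_contacts(a, b, cutoff = 40)
  set.seed(12)
  R <- random_rotation_matrix()
  mv <- placement(R, c(-8, 14, 3), "mv")
  t1 <- inter_complex_contacts(apply_placement(a, mv), apply_placement(b, mv), cutoff = 40)
  expect_equal(nrow(t0), nrow(t1))
  expect_lt(max(abs(t0$distance - t1$distance)), 1e-6)
})

test_that("layer-1/4 basal contact flag reflects the stacking geometry", {
  # one copy's layer-1 bilin meets the other's layer-4 bilin at ~35 A
  mk <- function(layer) {
    fixture_spec(list(list(center = c(0, 0, 0), role = "ApcA",
                           region = list(compartment = "core", cylinder = "A",
                                         layer = layer))), seed = 4L)
  }
  f1 <- make_assembly(mk(1L), dir = tempfile(), name = "l1")
  f4 <- make_assembly(mk(4L), dir = tempfile(), name = "l4")
  a <- apply_placement(f1$model, placement(diag(3), c(0, 0, 0), "A"))
  b <- apply_placement(f4$model, placement(diag(3), c(0, 35, 0), "B"))
  tab <- inter_complex_contacts(a, b, cutoff = 40, metric = "centroid")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$distance, 35, tolerance = 1e-6)
  expect_true(attr(tab, "summary")$all_via_layer_1_or_4)
  # assemblies without chromophores are rejected
  empty <- pbsnet:::.new_assembly(a$atoms[a$atoms$is_polymer, , drop = FALSE])
  expect_error(inter_complex_contacts(empty, b), "empty input")
})
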