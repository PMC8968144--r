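test_that("atlas loading preserves row order and captures columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parcel,legend,group,network",
               "B,b,Fro,DMN",
               "A,a,Fro,SMN"), f)
  atlas <- load_atlas(f)
  expect_equal(atlas$parcel, c("B", "A"))
  expect_equal(atlas$legend, c("b", "a"))
  expect_equal(atlas$group, c("Fro", "Fro"))
  expect_equal(names(atlas), c("parcel", "legend", "group", "network"))
})

test_that("atlas loading rejects duplicates and missing legends", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parcel,legend", "A,a", "A,b"), f)
  expect_error(load_atlas(f), "A", class = "cw_format_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parcel,legend", "A,a", "B,"), f2)
  expect_error(load_atlas(f2), "row 2", class = "cw_format_error")
})

test_that("label loading preserves order and strips whitespace", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("B", " A ", "C", ""), f)
  expect_equal(load_labels(f), c("B", "A", "C"))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), f2)
  expect_error(load_labels(f2), "empty", class = "cw_format_error")
})

test_that("matrix loading enforces square/symmetric/non-negative contract", {
  f <- withr::local_tempfile()
  writeLines(c("0 1", "1 0"), f)
  m <- load_matrix(f)
  expect_equal(m, matrix(c(0, 1, 1, 0), 2, 2))

  # within-tolerance asymmetry is repaired by averaging
  writeLines(c("0 1", "0.999999999 0"), f)
  expect_equal(load_matrix(f)[1, 2], 0.9999999995)

  writeLines(c("0 1 0", "1 0 1"), f)
  expect_error(load_matrix(f), "square", class = "cw_dimension_error")

  writeLines(c("0 1", "0.9 0"), f)
  expect_error(load_matrix(f), "asymmetric", class = "cw_symmetry_error")

  writeLines(c("0 -1", "-1 0"), f)
  expect_error(load_matrix(f), "negative", class = "cw_domain_error")

  writeLines(c("2, 1", "1, 0"), f)  # comma dialect + nonzero diagonal
  expect_warning(m2 <- load_matrix(f), "diagonal")
  expect_equal(diag(m2), c(0, 0))
})

test_that("matrix save/reload round-trips at the printed precision", {
  w <- generate_random_network(8, 0.5, seed = 3)
  f <- withr::local_tempfile()
  save_matrix(w, f, digits = 10)
  back <- load_matrix(f)
  expect_identical(back, unname(round(w, 10)))
  f2 <- withr::local_tempfile()
  save_matrix(back, f2, digits = 10)
  expect_identical(readLines(f), readLines(f2))
})

test_that("assembly aligns labels to atlas display order", {
  atlas <- mk_atlas(3)
  atlas$parcel <- c("A", "B", "C")
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 5  # edge C-A in label order (C,A,B)

  net_id <- assemble_network(atlas, c("A", "B", "C"), m)
  expect_equal(net_id$perm, 1:3)

  net <- assemble_network(atlas, c("C", "A", "B"), m)
  # oracle: among all 3! permutations, exactly one maps each label onto its
  # atlas position
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  match_ok <- vapply(perms, function(p) {
    all(atlas$parcel[p] == c("C", "A", "B"))
  }, logical(1))
  expect_equal(net$perm, perms[[which(match_ok)]])
  expect_equal(net$perm, c(3, 1, 2))
  expect_equal(display_matrix(net)["A", "C"], 5)

  expect_error(assemble_network(atlas, c("A", "B", "X"), m), "X",
               class = "cw_lookup_error")
  expect_error(assemble_network(atlas, c("A", "B"), m),
               class = "cw_dimension_error")
})

test_that("display-order projection equals the double-loop permutation oracle", {
  for (seed in 1:5) {
    w <- generate_random_network(5, 0.6, seed = seed)
    atlas <- mk_atlas(5)
    labels <- with_seed_helper(seed, sample(atlas$parcel))
    net <- assemble_network(atlas, labels, w)
    expect_equal(unname(display_matrix(net)), oracle_permute(w, net$perm))
    # perm then inverse is identity
    expect_equal(net$perm[order(net$perm)], 1:5)
  }
})

test_that("loader rejects generated broken matrices", {
  f <- withr::local_tempfile()
  # non-square, asymmetric, negative, ragged
  broken <- list(
    c("0 1 1", "1 0 1"),
    c("0 2", "1 0"),
    c("0 1", "1 -0.5"),
    c("0 1", "1")
  )
  for (txt in broken) {
    writeLines(txt, f)
    expect_error(load_matrix(f))
  }
})

test_that("bundled atlas template has the full 165-parcel composition", {
  atlas <- destrieux_template()
  expect_equal(nrow(atlas), 165)
  expect_equal(sum(atlas$hemisphere == "L"), 82)
  expect_equal(sum(atlas$hemisphere == "R"), 82)
  expect_equal(sum(grepl("^Sbc", atlas$group)), 14)
  expect_equal(sum(atlas$group == "Bst"), 1)
  # assembles against a matching matrix
  w <- generate_random_network(165, 0.1, seed = 1)
  net <- assemble_network(atlas, atlas$parcel, w)
  expect_equal(n_nodes(net), 165)
})
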