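test_that("circular layout places the first parcel on top, clockwise", {
  atlas <- mk_atlas(4)
  lay <- circular_layout(atlas)
  # quarter turns: top, right, bottom, left (angles modulo 2*pi)
  expect_equal(lay$x, c(0, 1, 0, -1), tolerance = 1e-12)
  expect_equal(lay$y, c(1, 0, -1, 0), tolerance = 1e-12)
  expect_equal(lay$angle[1], pi / 2)
  expect_true(all(diff(lay$angle) < 0))

  one <- circular_layout(mk_atlas(1))
  expect_equal(c(one$x, one$y), c(0, 1), tolerance = 1e-12)

  big <- circular_layout(mk_atlas(165, groups = rep(sprintf("G%02d", 1:15),
                                                    each = 11)))
  expect_equal(unique(round(-diff(big$angle), 12)),
               round(2 * pi / 165, 12))
  expect_true(all(abs(big$x^2 + big$y^2 - 1) < 1e-12))
})

test_that("hyperbolic arcs satisfy the orthogonal-circle identities", {
  a <- poincare_arc(c(1, 0), c(0, 1))
  expect_equal(c(a$cx, a$cy), c(1, 1), tolerance = 1e-12)
  expect_equal(a$r, 1, tolerance = 1e-12)

  chord <- poincare_arc(c(1, 0), c(-1, 0))
  expect_equal(chord$kind, "chord")

  with_seed_helper(42, {
    for (rep in 1:50) {
      th <- runif(2, 0, 2 * pi)
      u <- c(cos(th[1]), sin(th[1]))
      v <- c(cos(th[2]), sin(th[2]))
      if (sqrt(sum((u - v)^2)) < 1e-6 || sqrt(sum((u + v)^2)) < 1e-6) next
      arc <- poincare_arc(u, v)
      cc <- c(arc$cx, arc$cy)
      expect_lt(abs(sum(u * cc) - 1), 1e-9)
      expect_lt(abs(sum(v * cc) - 1), 1e-9)
      expect_lt(abs(sum(cc^2) - arc$r^2 - 1), 1e-9)
      # both endpoints on the arc circle
      expect_lt(abs(sqrt(sum((u - cc)^2)) - arc$r), 1e-9)
      expect_lt(abs(sqrt(sum((v - cc)^2)) - arc$r), 1e-9)
      # interpolated arc stays inside the unit disk
      pts <- connectoweave:::arc_points(arc, 100)
      expect_lt(max(pts$x^2 + pts$y^2), 1 + 1e-9)
    }
  })
  expect_error(poincare_arc(c(2, 0), c(0, 1)), class = "cw_geometry_error")
})

test_that("connectogram arc count equals kept-edge count", {
  net <- mk_net(complete_graph(4), groups = c("a", "a", "b", "b"))
  cg <- build_connectogram(net)
  expect_equal(nrow(cg$arcs), 6)

  masked <- build_connectogram(net, mask = omit_within_group_edges(net))
  expect_equal(nrow(masked$arcs), 4)

  for (seed in 1:10) {
    net_r <- rand_net(12, with_seed_helper(seed, runif(1, 0.2, 0.8)),
                      seed = seed)
    w <- display_matrix(net_r)
    cg_r <- build_connectogram(net_r)
    expect_equal(nrow(cg_r$arcs), sum(w[upper.tri(w)] > 0))
    # arcs are sorted ascending weight so strong edges draw last (on top)
    expect_true(!is.unsorted(cg_r$arcs$weight))
  }
})

test_that("style controls hide labels and suppress node edges", {
  net <- mk_net(complete_graph(4), groups = c("a", "a", "b", "b"))
  cg <- build_connectogram(net, style = list(hide_labels = "P01"))
  expect_equal(cg$nodes$label_visible, c(FALSE, TRUE, TRUE, TRUE))

  sup <- build_connectogram(net, style = list(suppress_nodes = "P02"))
  expect_equal(nrow(sup$arcs), 3)
  expect_false(any(sup$arcs$i == 2 | sup$arcs$j == 2))
  expect_equal(nrow(sup$nodes), 4)  # node stays on the ring

  expect_error(build_connectogram(net,
                                  style = list(node_color_metric = "bogus")),
               class = "cw_configuration_error")
})

test_that("rendering writes deterministic SVG plus PNG", {
  net <- rand_net(10, 0.4, seed = 6,
                  groups = rep(c("Fro-L", "Occ-R"), each = 5))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  render_connectogram(net, out_dir = d1, name = "fig",
                      style = list(edge_color_mode = "weight"))
  render_connectogram(net, out_dir = d2, name = "fig",
                      style = list(edge_color_mode = "weight"))
  f1 <- file.path(d1, "fig.svg")
  f2 <- file.path(d2, "fig.svg")
  expect_true(file.exists(f1))
  expect_true(file.exists(file.path(d1, "fig.png")))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("local index plot highlights k nodes per class", {
  net <- rand_net(165, 0.3, seed = 8,
                  groups = rep(sprintf("G%02d", 1:15), each = 11))
  loc <- local_metrics(net)
  p <- plot_local_index(loc, "degree")
  built <- ggplot2::ggplot_build(p)
  pt_layer <- built$data[[length(built$data)]]
  expect_equal(nrow(pt_layer), 165)
  cls <- highlight_classes(loc$degree)
  expect_equal(sum(cls == "top"), 17)
  expect_equal(sum(cls == "bottom"), 17)
  expect_error(plot_local_index(loc, "nope"),
               class = "cw_configuration_error")
})

test_that("run folders and manifests are created per execution", {
  base <- withr::local_tempdir()
  d1 <- create_run_dir(base)
  d2 <- create_run_dir(base)
  expect_true(dir.exists(d1) && dir.exists(d2) && d1 != d2)
  mf <- write_run_manifest(d1, list(seed = 7, mean_over = "all"))
  got <- jsonlite::read_json(mf)
  expect_equal(got$seed, 7)
  expect_equal(got$package, "connectoweave")
})
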