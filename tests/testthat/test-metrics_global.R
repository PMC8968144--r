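test_that("closed forms on complete and path graphs", {
  k5 <- mk_net(complete_graph(5))
  gm <- global_metrics(k5, nulls = 2, louvain_reps = 5, cp_reps = 5,
                       seed = 1)
  v <- gm$values
  expect_equal(v[["average_degree"]], 4)
  expect_equal(v[["char_path_length"]], 1)
  expect_equal(v[["global_efficiency"]], 1)
  expect_equal(v[["clustering_coef"]], 1)
  expect_equal(v[["density"]], 100)
  expect_equal(v[["modularity"]], 0)

  p3 <- mk_net(path_graph(3))
  gp <- global_metrics(p3, nulls = 2, louvain_reps = 5, cp_reps = 5,
                       seed = 1)
  expect_equal(gp$values[["char_path_length"]], 4 / 3)
  expect_equal(gp$values[["global_efficiency"]], 5 / 6)
})

test_that("path lengths and efficiencies agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:8) {
    net <- rand_net(12, 0.35, seed = seed)
    w <- unname(display_matrix(net))
    gm <- global_metrics(net, nulls = 2, louvain_reps = 5, cp_reps = 5,
                         seed = 1)
    a <- (w > 0) * 1
    db <- igraph::distances(ig_graph(a, weighted = FALSE))
    off_b <- db[row(db) != col(db)]
    expect_equal(gm$values[["char_path_length"]],
                 mean(off_b[is.finite(off_b)]), tolerance = 1e-12)
    expect_equal(gm$values[["global_efficiency"]],
                 mean(ifelse(is.finite(off_b), 1 / off_b, 0)),
                 tolerance = 1e-12)
    # weighted: igraph with reciprocal max-normalized weights as lengths
    wn <- w / max(w)
    gw <- ig_graph(wn)
    dw <- igraph::distances(gw, weights = 1 / igraph::E(gw)$weight)
    off_w <- dw[row(dw) != col(dw)]
    expect_equal(gm$values[["char_path_length_w"]],
                 mean(off_w[is.finite(off_w)]), tolerance = 1e-12)
    expect_equal(gm$values[["global_efficiency_w"]],
                 mean(ifelse(is.finite(off_w), 1 / off_w, 0)),
                 tolerance = 1e-12)
    expect_equal(gm$values[["average_degree"]], mean(rowSums(a)))
    expect_equal(gm$values[["average_strength_w"]], mean(rowSums(w)))
  }
})

test_that("global efficiency and path length bounds hold; unreachable pairs reported", {
  for (seed in 1:10) {
    net <- rand_net(10, with_seed_helper(seed, runif(1, 0.25, 0.9)),
                    seed = seed)
    gm <- global_metrics(net, nulls = 2, louvain_reps = 5, cp_reps = 5,
                         seed = 1)
    e <- gm$values[["global_efficiency"]]
    l <- gm$values[["char_path_length"]]
    expect_gt(e, 0)
    expect_lte(e, 1)
    expect_gte(l, 1)
    if (gm$values[["density"]] == 100) {
      expect_equal(e, 1)
      expect_equal(l, 1)
    } else {
      expect_lt(e, 1)
      expect_gt(l, 1)
    }
  }
  # two disconnected dyads: unreachable pairs counted, efficiency < 1
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  gm2 <- global_metrics(mk_net(w), nulls = 2, louvain_reps = 5,
                        cp_reps = 5, seed = 1)
  expect_equal(unname(gm2$unreachable_pairs["binary"]), 8)
  expect_equal(gm2$values[["char_path_length"]], 1)

  empty <- matrix(0, 4, 4)
  expect_error(global_metrics(mk_net(empty), seed = 1),
               class = "cw_domain_error")
})

test_that("sigma of degree-matched random graphs is about 1", {
  sig <- vapply(1:25, function(seed) {
    net <- rand_net(25, 0.35, seed = 100 + seed)
    global_metrics(net, nulls = 5, louvain_reps = 2, cp_reps = 2,
                   seed = seed)$values[["small_worldness"]]
  }, numeric(1))
  expect_lt(abs(mean(sig) - 1), 0.15)
})

test_that("rewired nulls preserve the degree sequence", {
  net <- rand_net(20, 0.3, seed = 3)
  a <- (unname(display_matrix(net)) > 0) * 1
  ar <- with_seed_helper(5, connectoweave:::rewire_degree_preserving(a, 10))
  expect_equal(rowSums(ar), rowSums(a))
  expect_symmetric_zero_diag(ar)
  expect_false(identical(ar, a))
})

test_that("global metrics tidy/glance views are consistent", {
  net <- rand_net(10, 0.5, seed = 4)
  gm <- global_metrics(net, nulls = 2, louvain_reps = 5, cp_reps = 5,
                       seed = 2)
  td <- tidy(gm)
  expect_equal(nrow(td), 12)
  gl <- glance(gm)
  expect_equal(gl$average_degree, gm$values[["average_degree"]])
  expect_equal(gl$n, 10)
  # deterministic for a fixed seed
  gm2 <- global_metrics(net, nulls = 2, louvain_reps = 5, cp_reps = 5,
                        seed = 2)
  expect_equal(gm$values, gm2$values)
})
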