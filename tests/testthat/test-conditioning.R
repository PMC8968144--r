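test_that("density counts nonzero upper-triangle fraction in percent", {
  expect_equal(network_density(complete_graph(4)), 100)
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  expect_equal(network_density(w), 50)
  expect_error(network_density(matrix(0, 1, 1)), class = "cw_domain_error")
})

test_that("density thresholding keeps the k strongest edges", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.1
  out <- apply_density_threshold(w, 1 / 3)
  expect_equal(out[1, 2], 0.9)
  expect_equal(sum(out > 0) / 2, 1)

  expect_equal(apply_density_threshold(w, 1), w)
  expect_warning(
    apply_density_threshold(apply_density_threshold(w, 1 / 3), 2 / 3),
    "unchanged")

  bin <- apply_density_threshold(w, 2 / 3, binarize = TRUE)
  expect_setequal(unique(as.vector(bin)), c(0, 1))
})

test_that("threshold survivors match the full-sort oracle and nest by density", {
  for (seed in 1:5) {
    w <- generate_random_network(10, 0.8, seed = seed)
    e_max <- 10 * 9 / 2
    out <- apply_density_threshold(w, 0.30)
    k <- round(0.30 * e_max)
    surv <- which(upper.tri(out) & out > 0, arr.ind = TRUE)
    expect_equal(surv[order(surv[, 1], surv[, 2]), , drop = FALSE],
                 {
                   o <- oracle_topk(w, k)
                   o[order(o[, 1], o[, 2]), , drop = FALSE]
                 })
    # achieved density is exact for distinct weights
    expect_equal(network_density(out), 100 * k / e_max)
    # monotone nesting of survivor sets
    prev <- w
    for (d in c(0.6, 0.4, 0.2, 0.1)) {
      cur <- apply_density_threshold(w, d)
      expect_true(all(prev[cur > 0] > 0))
      prev <- cur
    }
    expect_symmetric_zero_diag(out)
  }
})

test_that("max normalization scales to [0,1], preserves ratios, idempotent", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 2
  w[1, 3] <- w[3, 1] <- 4
  out <- normalize_by_max(w)
  expect_equal(out[1, 2], 0.5)
  expect_equal(max(out), 1)
  expect_equal(normalize_by_max(out), out)

  wr <- generate_random_network(8, 0.5, seed = 7) * 37.5
  nr <- normalize_by_max(wr)
  nz <- which(upper.tri(wr) & wr > 0)
  expect_equal(nr[nz][1] / nr[nz][2], wr[nz][1] / wr[nz][2])
  expect_error(normalize_by_max(matrix(0, 3, 3)), class = "cw_domain_error")
})

test_that("volume normalization divides by summed parcel volumes", {
  w <- matrix(0, 2, 2)
  w[1, 2] <- w[2, 1] <- 10
  expect_equal(normalize_by_parcel_volumes(w, c(3, 7))[1, 2], 1)

  w5 <- generate_random_network(5, 0.7, seed = 9)
  vols <- c(1.5, 2, 0.5, 3, 1)
  out <- normalize_by_parcel_volumes(w5, vols)
  for (i in 1:5) {
    for (j in 1:5) {
      if (i != j) expect_equal(out[i, j], w5[i, j] / (vols[i] + vols[j]))
    }
  }
  expect_symmetric_zero_diag(out)
  expect_equal(normalize_by_parcel_volumes(w, c(0.5, 0.5)), w)
  expect_error(normalize_by_parcel_volumes(w5, c(1, -1, 1, 1, 1)),
               class = "cw_domain_error")
  expect_error(normalize_by_parcel_volumes(w5, 1:3),
               class = "cw_dimension_error")
})

test_that("consensus applies the shared-by-at-least rule with mean weights", {
  # edge present in 2/3 subjects (0.667 >= 0.53): kept at mean over all
  mk <- function(v) {
    m <- matrix(0, 2, 2)
    m[1, 2] <- m[2, 1] <- v
    m
  }
  cons <- build_group_matrix(list(mk(0.3), mk(0.6), mk(0)), presence = 0.53)
  expect_equal(cons[1, 2], mean(c(0.3, 0.6, 0)))

  cons_p <- build_group_matrix(list(mk(0.3), mk(0.6), mk(0)),
                               presence = 0.53, mean_over = "present")
  expect_equal(cons_p[1, 2], 0.45)

  # presence 1 keeps the intersection; presence 0 the union
  a <- mk(1); b <- mk(0)
  b[1, 2] <- b[2, 1] <- 0
  expect_equal(build_group_matrix(list(a, b), presence = 1)[1, 2], 0)
  expect_gt(build_group_matrix(list(a, b), presence = 0)[1, 2], 0)

  expect_error(build_group_matrix(list(a, matrix(0, 3, 3))),
               class = "cw_dimension_error")
})

test_that("17-subject stacks: 9/17 presence dropped, 10/17 retained at 53%", {
  stack9 <- generate_subject_stack(12, 17, core_density = 0.15,
                                   variable_density = 0.1, n_present = 9,
                                   seed = 21)
  cons9 <- build_group_matrix(stack9$matrices, presence = 0.53)
  expect_true(all(cons9[stack9$variable_edges] == 0))
  expect_true(all(cons9[stack9$core_edges] > 0))

  stack10 <- generate_subject_stack(12, 17, core_density = 0.15,
                                    variable_density = 0.1, n_present = 10,
                                    seed = 22)
  cons10 <- build_group_matrix(stack10$matrices, presence = 0.53)
  expect_true(all(cons10[stack10$variable_edges] > 0))

  # consensus edge count is non-increasing in the presence threshold
  counts <- vapply(c(0, 0.25, 0.53, 0.75, 1), function(p) {
    sum(build_group_matrix(stack9$matrices, presence = p) > 0) / 2
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_symmetric_zero_diag(cons9)
})
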