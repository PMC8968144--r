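# Synthetic fixture generators. These emulate the structure of
# parcellation-scale structural connectivity data (ordered atlas with
# contiguous lobe-like groups and a hemisphere attribute, symmetric
# non-negative weight matrices at controlled density, per-subject stacks
# with known edge-presence fractions, planted community structure) so the
# whole pipeline is testable without any imaging data. Weight magnitudes
# are uniform, not tractography-realistic.

#' Generate a toy atlas and matching label list
#'
#' Parcels are named `P001, P002, ...` with short legends, grouped into
#' `n_groups` contiguous blocks (`G01, G02, ...`) emulating anatomical
#' lobes, with a `hemisphere` attribute column splitting the parcels into
#' `L`/`R` halves. Deterministic for a given seed. Optionally writes the
#' atlas (`.csv`) and label (`.txt`) files in the accepted dialects, with
#' the seed recorded in the filenames.
#'
#' @param n_nodes Number of parcels.
#' @param n_groups Number of contiguous groups (`<= n_nodes`).
#' @param seed RNG seed (recorded; generation itself is deterministic).
#' @param dir If given, write `atlas_s<seed>.csv` and `labels_s<seed>.txt`
#'   there.
#' @param shuffle_labels If `TRUE`, the label list (and hence matrix
#'   order) is a seeded permutation of the atlas order, exercising the
#'   label-to-atlas alignment.
#' @return List with `atlas` (tibble), `labels` (character), and `files`
#'   (paths, if written).
#' @export
generate_toy_atlas <- function(n_nodes, n_groups, seed = 1, dir = NULL,
                               shuffle_labels = FALSE) {
  if (n_groups > n_nodes) {
    stop_cw("n_groups (", n_groups, ") exceeds n_nodes (", n_nodes, ")",
            class = "cw_spec_error")
  }
  parcel <- sprintf("P%03d", seq_len(n_nodes))
  sizes <- diff(floor(seq(0, n_nodes, length.out = n_groups + 1)))
  group <- rep(sprintf("G%02d", seq_len(n_groups)), times = sizes)
  hemisphere <- rep(c("L", "R"), c(ceiling(n_nodes / 2), floor(n_nodes / 2)))
  atlas <- tibble::tibble(
    parcel = parcel,
    legend = tolower(parcel),
    group = group,
    hemisphere = hemisphere
  )
  labels <- if (shuffle_labels) {
    with_seed(seed, sample(parcel))
  } else {
    parcel
  }
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, sprintf("atlas_s%d.csv", seed))
    fl <- file.path(dir, sprintf("labels_s%d.txt", seed))
    readr::write_csv(atlas, fa, progress = FALSE)
    writeLines(labels, fl)
    files <- c(atlas = fa, labels = fl)
  }
  list(atlas = atlas, labels = labels, files = files)
}

#' Generate a random weighted connectivity matrix at exact density
#'
#' Symmetric, zero-diagonal, with uniform `(0, 1]` weights on exactly
#' `round(density * n(n-1)/2)` edges (half away from zero), sampled
#' uniformly over the possible edges. Reproducible by seed.
#'
#' @param n Number of nodes.
#' @param density Target edge density in (0, 1].
#' @param seed RNG seed.
#' @param binary If `TRUE`, surviving weights are 1.
#' @return A square weight matrix.
#' @export
generate_random_network <- function(n, density, seed = 1, binary = FALSE) {
  if (n < 2 || density <= 0 || density > 1) {
    stop_cw("need n >= 2 and density in (0, 1]", class = "cw_spec_error")
  }
  e_max <- n * (n - 1) / 2
  k <- round_half_up(density * e_max)
  up <- upper_pairs(n)
  w <- matrix(0, n, n)
  with_seed(seed, {
    pick <- sample.int(e_max, k)
    wt <- if (binary) rep(1, k) else 1 - stats::runif(k)
    sel <- up[pick, , drop = FALSE]
    w[sel] <- wt
    w[sel[, c(2, 1), drop = FALSE]] <- wt
  })
  w
}

#' Generate a per-subject matrix stack with controlled edge presence
#'
#' Builds `n_subjects` same-order matrices over a designated edge design:
#' a core edge set present in every subject and a variable edge set present
#' in exactly `n_present` subjects each (which subjects differ per edge).
#' Weights are uniform `(0, 1]`, redrawn per subject. The returned ground
#' truth makes consensus construction exactly predictable.
#'
#' @param n Number of nodes.
#' @param n_subjects Number of subjects (>= 2).
#' @param core_density Fraction of possible edges in the always-present
#'   core set.
#' @param variable_density Fraction of possible edges in the variable set
#'   (disjoint from the core set).
#' @param n_present Number of subjects carrying each variable edge.
#' @param seed RNG seed.
#' @return List with `matrices` (list of matrices), `core_edges` and
#'   `variable_edges` (two-column index matrices), and `n_present`.
#' @export
generate_subject_stack <- function(n, n_subjects, core_density = 0.2,
                                   variable_density = 0.1,
                                   n_present = n_subjects, seed = 1) {
  if (n_subjects < 2) {
    stop_cw("need at least 2 subjects", class = "cw_spec_error")
  }
  if (n_present < 0 || n_present > n_subjects) {
    stop_cw("n_present must be in 0..n_subjects", class = "cw_spec_error")
  }
  e_max <- n * (n - 1) / 2
  n_core <- round_half_up(core_density * e_max)
  n_var <- round_half_up(variable_density * e_max)
  if (n_core + n_var > e_max) {
    stop_cw("core + variable densities exceed 1", class = "cw_spec_error")
  }
  up <- upper_pairs(n)
  with_seed(seed, {
    pick <- sample.int(e_max, n_core + n_var)
    core_e <- up[pick[seq_len(n_core)], , drop = FALSE]
    var_e <- up[pick[n_core + seq_len(n_var)], , drop = FALSE]
    present <- matrix(FALSE, n_var, n_subjects)
    for (e in seq_len(n_var)) {
      present[e, sample.int(n_subjects, n_present)] <- TRUE
    }
    mats <- lapply(seq_len(n_subjects), function(s) {
      w <- matrix(0, n, n)
      if (n_core > 0) {
        wt <- 1 - stats::runif(n_core)
        w[core_e] <- wt
        w[core_e[, c(2, 1), drop = FALSE]] <- wt
      }
      on_s <- which(present[, s])
      if (length(on_s) > 0) {
        wt <- 1 - stats::runif(length(on_s))
        ee <- var_e[on_s, , drop = FALSE]
        w[ee] <- wt
        w[ee[, c(2, 1), drop = FALSE]] <- wt
      }
      w
    })
    list(matrices = mats, core_edges = core_e, variable_edges = var_e,
         n_present = n_present)
  })
}

#' Generate a planted two-block (or k-block) community graph
#'
#' Binary stochastic block model with within-block edge probability `p_in`
#' and between-block probability `p_out`; with `p_in >> p_out` the
#' planted partition is recoverable by community detection.
#'
#' @param n Number of nodes.
#' @param blocks Number of equal-sized blocks.
#' @param p_in,p_out Within/between-block edge probabilities
#'   (`p_in > p_out`).
#' @param seed RNG seed.
#' @return List with `weights` (binary matrix) and `membership` (planted
#'   block id per node).
#' @export
generate_planted_partition <- function(n, blocks = 2, p_in = 0.9,
                                       p_out = 0.05, seed = 1) {
  if (p_in <= p_out) {
    stop_cw("p_in must exceed p_out for a recoverable planting",
            class = "cw_spec_error")
  }
  membership <- rep(seq_len(blocks), length.out = n)
  membership <- sort(membership)
  same <- outer(membership, membership, "==")
  prob <- ifelse(same, p_in, p_out)
  w <- matrix(0, n, n)
  up <- upper_pairs(n)
  with_seed(seed, {
    on <- stats::runif(nrow(up)) < prob[up]
    w[up[on, , drop = FALSE]] <- 1
    w[up[on, c(2, 1), drop = FALSE]] <- 1
  })
  list(weights = w, membership = membership)
}
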