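# Internal helpers shared across modules.

# Round half away from zero (0.10 * 165 = 16.5 -> 17). Base round() is
# banker's rounding, which would give 16.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Upper-triangle edge index pairs (i < j) of an n x n matrix, in
# lexicographic (i, j) order.
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cw <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "connectoweave_error"))
}
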