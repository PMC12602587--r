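# Internal helpers shared across the package.

#' @keywords internal
#' @noRd
stop_ising <- function(class, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "ising_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

# Evaluate `code` under a locally seeded RNG, restoring global state after.
# All stochastic entry points route through this so no call touches global
# RNG state and identical (inputs, seed) give bit-identical output.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_ising("ising_seed_error", "`seed` must be a single finite integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# log(sum(exp(x))) without overflow; weights of magnitude ~5 on 9 nodes
# already overflow naive exponentiation.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# Unordered pair index table for m nodes, column-major over the upper
# triangle: (1,2), (1,3), (2,3), (1,4), ... Matches which(upper.tri(.)).
#' @keywords internal
#' @noRd
pair_index <- function(m) {
  which(upper.tri(diag(m)), arr.ind = TRUE)
}

#' @keywords internal
#' @noRd
upper_tri_values <- function(mat) {
  mat[upper.tri(mat)]
}

# Rebuild a symmetric zero-diagonal matrix from its upper-triangle vector.
#' @keywords internal
#' @noRd
matrix_from_upper <- function(values, m) {
  out <- matrix(0, m, m)
  out[upper.tri(out)] <- values
  out + t(out)
}

#' @keywords internal
#' @noRd
check_binary_matrix <- function(data, what = "data") {
  if (!is.matrix(data)) {
    data <- as.matrix(data)
  }
  if (!all(data %in% c(0, 1))) {
    bad <- which(!(data %in% c(0, 1)))[1L]
    rc <- arrayInd(bad, dim(data))
    stop_ising(
      "ising_binary_error",
      sprintf(
        "%s must contain only 0/1 entries; found %s at row %d, column %d",
        what, format(data[bad]), rc[1L], rc[2L]
      )
    )
  }
  storage.mode(data) <- "double"
  data
}
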