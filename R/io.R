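# Serialization: models and fits as JSON, datasets as CSV with a JSON
# sidecar carrying the selection provenance (cutoff, seed). Reals are
# written with 17 significant digits so round-trips are bit-exact.

#' @keywords internal
#' @noRd
num17 <- function(x) {
  # 17 significant digits uniquely identify a double
  vapply(x, function(v) sprintf("%.17g", v), character(1L))
}

#' Write / read an Ising model as JSON
#'
#' The document is `{"m": ..., "tau": [...], "omega": [[...]]}`. The
#' reader validates the model invariants (symmetric omega, zero diagonal,
#' finite entries) and refuses violating files; values round-trip
#' bit-exactly.
#'
#' @param model an [ising_model].
#' @param path file path.
#' @return `write_ising_model` returns `path` invisibly;
#'   `read_ising_model` returns an [ising_model].
#' @export
write_ising_model <- function(model, path) {
  doc <- list(
    m = model$m,
    tau = I(num17(model$tau)),
    omega = lapply(seq_len(model$m), function(i) I(num17(model$omega[i, ])))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE)
  # numbers were pre-formatted as strings; strip the quotes around them
  json <- gsub('"(-?[0-9][^"]*)"', "\\1", json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_ising_model
#' @export
read_ising_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$tau) || is.null(doc$omega)) {
    stop_ising("ising_validation_error",
               sprintf("'%s' is not an Ising model document", path))
  }
  omega <- as.matrix(doc$omega)
  ising_model(tau = doc$tau, omega = omega)
}

#' Write / read a binary dataset as CSV
#'
#' The table has a header `v1..vm` and 0/1 entries; the selection cutoff
#' and seed travel in a JSON sidecar `<path>.json`. The reader validates
#' that entries are binary and that every row sum reaches the recorded
#' cutoff.
#'
#' @param data 0/1 matrix, e.g. from [ising_sample()].
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_ising_data` returns `path` invisibly; `read_ising_data`
#'   returns the matrix with `cutoff` and `seed` attributes restored.
#' @export
write_ising_data <- function(data, path) {
  data <- check_binary_matrix(data)
  m <- ncol(data)
  df <- as.data.frame(data)
  colnames(df) <- paste0("v", seq_len(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(cutoff = attr(data, "cutoff") %||% 0L,
               seed = attr(data, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_ising_data
#' @export
read_ising_data <- function(path) {
  df <- utils::read.csv(path)
  mat <- as.matrix(df)
  bad <- which(!(mat %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(mat))
    stop_ising(
      "ising_validation_error",
      sprintf("non-binary entry %s at row %d, column %d of '%s'",
              format(mat[bad[1L]]), rc[1L], rc[2L], path)
    )
  }
  storage.mode(mat) <- "double"
  cutoff <- 0L
  seed <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    cutoff <- as.integer(meta$cutoff %||% 0L)
    seed <- if (is.null(meta$seed)) NULL else as.integer(meta$seed)
  }
  rs <- rowSums(mat)
  if (any(rs < cutoff)) {
    bad <- which(rs < cutoff)[1L]
    stop_ising(
      "ising_validation_error",
      sprintf("row %d of '%s' has sum score %d below the recorded cutoff %d",
              bad, path, rs[bad], cutoff)
    )
  }
  attr(mat, "cutoff") <- cutoff
  attr(mat, "seed") <- seed
  mat
}

#' Write / read a fit result as JSON
#'
#' Serialises the estimates, edge mask and method metadata of an
#' `ising_fit`; parameters round-trip bit-exactly.
#'
#' @param fit an `ising_fit`.
#' @param path file path.
#' @export
write_ising_fit <- function(fit, path) {
  m <- fit$m
  doc <- list(
    method = fit$method,
    corrected = fit$corrected,
    k = fit$k,
    n = fit$n,
    m = m,
    alpha = fit$alpha,
    gamma = fit$gamma,
    converged = fit$converged,
    loglik = num17(fit$loglik),
    tau = I(num17(fit$tau)),
    omega = lapply(seq_len(m), function(i) I(num17(fit$omega[i, ]))),
    edge_mask = lapply(seq_len(m), function(i) I(fit$edge_mask[i, ])),
    diagnostics = list(
      dropped_rows = fit$diagnostics$dropped_rows,
      separation = fit$diagnostics$separation
    )
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null")
  json <- gsub('"(-?[0-9][^"]*)"', "\\1", json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_ising_fit
#' @export
read_ising_fit <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  m <- doc$m
  mask <- as.matrix(doc$edge_mask)
  new_ising_fit(
    method = doc$method, corrected = doc$corrected, k = as.integer(doc$k),
    k_norm = if (isTRUE(doc$corrected)) as.integer(doc$k) else 0L,
    tau = doc$tau, omega = as.matrix(doc$omega), edge_mask = mask,
    alpha = doc$alpha, gamma = doc$gamma, loglik = doc$loglik,
    converged = doc$converged, n = as.integer(doc$n), m = as.integer(m),
    diagnostics = as.list(doc$diagnostics)
  )
}
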