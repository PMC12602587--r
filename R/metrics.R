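# Network recovery metrics: how well an estimated network matches the
# data-generating one.

#' @keywords internal
#' @noRd
get_omega <- function(x) {
  if (inherits(x, "ising_fit") || inherits(x, "ising_model")) {
    return(x$omega)
  }
  as.matrix(x)
}

#' @keywords internal
#' @noRd
get_edge_mask <- function(x) {
  if (inherits(x, "ising_fit")) {
    return(x$edge_mask)
  }
  get_omega(x) != 0
}

#' @keywords internal
#' @noRd
check_same_m <- function(true, est) {
  wt <- get_omega(true)
  we <- get_omega(est)
  if (!all(dim(wt) == dim(we))) {
    stop_ising("ising_dim_error",
               sprintf("networks differ in size: %d vs %d nodes",
                       ncol(wt), ncol(we)))
  }
  list(true = wt, est = we)
}

#' Total edge weight error
#'
#' Sum over unordered node pairs of the absolute difference between true
#' and estimated edge weights; 0 iff the networks agree edge for edge.
#'
#' @param true the data-generating [ising_model] (or weight matrix).
#' @param est an `ising_fit` (or weight matrix).
#' @return a non-negative scalar.
#' @export
total_edge_weight_error <- function(true, est) {
  w <- check_same_m(true, est)
  sum(abs(upper_tri_values(w$est) - upper_tri_values(w$true)))
}

#' Sensitivity and specificity of edge recovery
#'
#' Sensitivity is the proportion of truly present edges that are estimated
#' as nonzero (sign-agnostic: a negative estimate of a positive edge still
#' counts as detected); specificity is the proportion of truly absent
#' edges estimated as exactly zero. Nonzero status of the estimate is read
#' from its edge-inclusion mask. When the truth has no present (or no
#' absent) edges the corresponding proportion is undefined and returned as
#' `NA`.
#'
#' @inheritParams total_edge_weight_error
#' @return a named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(true, est) {
  w <- check_same_m(true, est)
  true_present <- upper_tri_values(w$true) != 0
  est_present <- upper_tri_values(get_edge_mask(est))
  sens <- if (any(true_present)) {
    mean(est_present[true_present])
  } else {
    NA_real_
  }
  spec <- if (any(!true_present)) {
    mean(!est_present[!true_present])
  } else {
    NA_real_
  }
  c(sensitivity = sens, specificity = spec)
}

#' Proportion of spurious negative edges
#'
#' Proportion of unordered pairs where a negative edge is estimated while
#' the true weight is non-negative — the signature of sum-score selection
#' bias in all-positive networks. By default the denominator is all
#' unordered pairs; set `denominator = "present"` to divide by the number
#' of truly present edges instead.
#'
#' @inheritParams total_edge_weight_error
#' @param denominator `"all"` (default) or `"present"`.
#' @return a proportion in `[0, 1]`.
#' @export
prop_spurious_negative <- function(true, est, denominator = c("all", "present")) {
  denominator <- match.arg(denominator)
  w <- check_same_m(true, est)
  wt <- upper_tri_values(w$true)
  we <- upper_tri_values(w$est)
  spurious <- we < 0 & wt >= 0
  denom <- switch(denominator, all = length(wt), present = sum(wt != 0))
  if (denom == 0) {
    return(NA_real_)
  }
  sum(spurious) / denom
}

#' All four recovery metrics at once
#'
#' @inheritParams total_edge_weight_error
#' @return a named list with `total_edge_weight_error`, `sensitivity`,
#'   `specificity`, and `prop_spurious_negative`.
#' @export
recovery_metrics <- function(true, est) {
  ss <- sensitivity_specificity(true, est)
  list(
    total_edge_weight_error = total_edge_weight_error(true, est),
    sensitivity = unname(ss["sensitivity"]),
    specificity = unname(ss["specificity"]),
    prop_spurious_negative = prop_spurious_negative(true, est)
  )
}
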