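
# (birth, death) matrix of one dimension of a diagram
dim_matrix <- function(diagram, dim) {
  rows <- diagram$dimension == dim
  cbind(diagram$birth[rows], diagram$death[rows])
}

# bare-numeric bottleneck between two (birth, death) matrices; hot path
bottleneck_value <- function(a_mat, b_mat) {
  bottleneck_cpp(a_mat, b_mat, FALSE)$value
}

#' Bottleneck distance between two persistence diagrams
#'
#' The bottleneck distance is the infimum over partial matchings of the
#' maximum L-infinity cost, where an unmatched feature pairs to the diagonal
#' at cost `persistence / 2`.  It is computed exactly by binary search over
#' the finite set of candidate costs (all half-persistences and all pairwise
#' L-infinity feature costs), with a bipartite-matching feasibility check at
#' each candidate.  Capped deaths enter at their capped (finite) values; if
#' the two diagrams were computed with different cap radii and either has a
#' capped feature in the compared dimension, a warning is raised, since such
#' distances mix incomparable caps (pairwise analyses should use the joint
#' maximum dissimilarity as a shared cap).
#'
#' @param a,b `"persistence_diagram"` objects (either may be empty in
#'   `dim`).
#' @param dim Homology dimension to compare (nonnegative integer).
#' @param matching If `TRUE`, also return an optimal matching: rows
#'   `(feature_a, feature_b)` indexing the dimension-restricted features,
#'   with `NA` for the diagonal.
#' @return A `"diagram_distance"`: list with `value`, `dim`, and optionally
#'   `matching`.  `value` is 0 exactly when the two dimension-restricted
#'   multisets coincide.
#' @examples
#' sq <- rdm_from_points(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' pd <- rips_diagram(sq)
#' bottleneck_distance(pd, pd, dim = 1)$value # 0
#' @export
bottleneck_distance <- function(a, b, dim = 1, matching = FALSE) {
  if (!is_count(dim) || dim < 0)
    rta_stop("dim must be a nonnegative integer", "rta_validation_error")
  ra <- attr(a, "max_radius"); rb <- attr(b, "max_radius")
  am <- dim_matrix(a, dim); bm <- dim_matrix(b, dim)
  if (!is.null(ra) && !is.null(rb) && ra != rb) {
    capped <- any(a$death_capped[a$dimension == dim]) ||
      any(b$death_capped[b$dimension == dim])
    if (capped)
      warning(sprintf(
        "comparing diagrams with different cap radii (%g vs %g) and capped deaths in dimension %d",
        ra, rb, dim))
  }
  res <- bottleneck_cpp(am, bm, isTRUE(matching))
  out <- list(value = res$value, dim = as.integer(dim))
  if (isTRUE(matching)) {
    m <- res$matching
    colnames(m) <- c("feature_a", "feature_b")
    out$matching <- m
  }
  class(out) <- "diagram_distance"
  out
}

#' @export
print.diagram_distance <- function(x, ...) {
  cat(sprintf("Bottleneck distance (H%d): %g\n", x$dim, x$value))
  invisible(x)
}

#' @export
as.double.diagram_distance <- function(x, ...) x$value
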