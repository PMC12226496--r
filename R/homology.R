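#' Build a Vietoris-Rips filtration from an RDM
#'
#' Enumerates every simplex up to dimension `max_dim + 1` (the dimension
#' needed to compute homology through `max_dim`) whose vertices are pairwise
#' within `max_radius`.  A simplex's filtration value is the largest pairwise
#' dissimilarity among its vertices; vertices enter at 0.  Simplices are
#' ordered by (filtration value, dimension, lexicographic vertex tuple),
#' which fixes the persistence pairing and representative cycles
#' deterministically.
#'
#' @param rdm An `"rdm"` object (or a matrix accepted by [validate_rdm()]).
#' @param max_dim Highest homology dimension to support (1, 2 or 3).
#'   Dimension 1 (loops) covers most representational analyses; dimension 2
#'   (voids) is substantially more expensive.
#' @param max_radius Connectivity cutoff; defaults to the maximum RDM entry,
#'   at which scale the complex is fully connected.
#' @return A `"vr_filtration"` object.
#' @seealso [compute_persistence()], [rips_diagram()]
#' @examples
#' sq <- rdm_from_points(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' f <- build_vr_filtration(sq, max_dim = 1)
#' table(f$dim)
#' @export
build_vr_filtration <- function(rdm, max_dim = 1, max_radius = NULL) {
  rdm <- if (inherits(rdm, "rdm")) rdm else validate_rdm(rdm)
  if (!is_count(max_dim) || max_dim < 0)
    rta_stop("max_dim must be a nonnegative integer", "rta_validation_error")
  if (max_dim < 1 || max_dim > 3)
    rta_stop("max_dim must be 1, 2 or 3", "rta_validation_error")
  d <- rdm_matrix(rdm)
  max_radius <- max_radius %||% max(d)
  if (max_radius < 0)
    rta_stop("max_radius must be nonnegative", "rta_validation_error")
  filt <- rips_filtration_cpp(d, as.integer(max_dim), max_radius)
  structure(list(vertices = filt$vertices, value = filt$value,
                 dim = filt$dim, n = filt$n, max_dim = as.integer(max_dim),
                 max_radius = max_radius, items = rdm_items(rdm)),
            class = "vr_filtration")
}

#' @export
print.vr_filtration <- function(x, ...) {
  cat(sprintf("Vietoris-Rips filtration: %d points, %d simplices (up to dim %d), max radius %g\n",
              x$n, length(x$value), max(x$dim), x$max_radius))
  print(table(dimension = x$dim))
  invisible(x)
}

new_persistence_diagram <- function(red, max_radius, max_dim, items = NULL) {
  pd <- data.frame(dimension = red$dimension, birth = red$birth,
                   death = red$death, death_capped = red$death_capped)
  attr(pd, "max_radius") <- max_radius
  attr(pd, "max_dim") <- max_dim
  attr(pd, "items") <- items
  if (!is.null(red$cycles)) attr(pd, "cycles") <- red$cycles
  class(pd) <- c("persistence_diagram", "data.frame")
  pd
}

#' Compute persistent homology of a filtration
#'
#' Standard persistence pairing by column reduction of the boundary matrix
#' over the field with two elements.  Features with zero persistence
#' (death equal to birth) are dropped; features that never die within the
#' filtration are reported with `death = max_radius` and `death_capped =
#' TRUE`.
#'
#' @param filtration A `"vr_filtration"` object.
#' @param cycles If `TRUE`, record a representative cycle for every loop
#'   (dimension-1 feature); retrieve them with [representative_cycle()].
#' @param method `"twist"` (default) uses the clearing optimization;
#'   `"standard"` is the plain left-to-right reduction.  Both produce
#'   identical pairings.
#' @return A `"persistence_diagram"`: a data frame with columns
#'   `dimension`, `birth`, `death`, `death_capped`, ordered by
#'   (dimension, birth, death).
#' @examples
#' sq <- rdm_from_points(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' compute_persistence(build_vr_filtration(sq))
#' @export
compute_persistence <- function(filtration, cycles = FALSE,
                                method = c("twist", "standard")) {
  method <- match.arg(method)
  if (!inherits(filtration, "vr_filtration"))
    rta_stop("filtration must be a 'vr_filtration' object", "rta_validation_error")
  red <- reduce_filtration_cpp(filtration$vertices, filtration$value,
                               filtration$dim, filtration$max_radius,
                               as.integer(filtration$max_dim),
                               isTRUE(cycles), method == "twist")
  new_persistence_diagram(red, filtration$max_radius, filtration$max_dim,
                          filtration$items)
}

#' Rips persistence diagram straight from an RDM
#'
#' Convenience wrapper: [build_vr_filtration()] followed by
#' [compute_persistence()].
#'
#' @inheritParams build_vr_filtration
#' @inheritParams compute_persistence
#' @return A `"persistence_diagram"`.
#' @export
rips_diagram <- function(rdm, max_dim = 1, max_radius = NULL, cycles = FALSE) {
  compute_persistence(build_vr_filtration(rdm, max_dim, max_radius),
                      cycles = cycles)
}

# hot path used by the resampling machinery: no validation, no labels
rips_pd_fast <- function(d, max_dim = 1L, max_radius = max(d)) {
  filt <- rips_filtration_cpp(d, as.integer(max_dim), max_radius)
  red <- reduce_filtration_cpp(filt$vertices, filt$value, filt$dim,
                               max_radius, as.integer(max_dim), FALSE, TRUE)
  new_persistence_diagram(red, max_radius, max_dim)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram: %d features (max radius %g)\n",
              nrow(x), attr(x, "max_radius")))
  for (d in sort(unique(x$dimension)))
    cat(sprintf("  H%d: %d features\n", d, sum(x$dimension == d)))
  NextMethod()
}

#' The most persistent feature of a diagram in one dimension
#'
#' Returns the feature maximizing `death - birth`.  Ties are broken by
#' earlier birth; an exact tie after that is reported with a warning (the
#' ordering of equally persistent loops in noisy data is not stable) and the
#' first feature in the diagram's deterministic order is returned.
#'
#' @param diagram A `"persistence_diagram"`.
#' @param dim Homology dimension to search (default 1, loops).
#' @return A one-row data frame; its row name indexes into `diagram`.
#' @export
most_persistent_feature <- function(diagram, dim = 1) {
  rows <- which(diagram$dimension == dim)
  if (length(rows) == 0)
    rta_stop(sprintf("no features in dimension %d", dim), "rta_no_features")
  pers <- diagram$death[rows] - diagram$birth[rows]
  best <- rows[pers == max(pers)]
  if (length(best) > 1) {
    best <- best[diagram$birth[best] == min(diagram$birth[best])]
    if (length(best) > 1)
      warning(sprintf("%d equally persistent features in dimension %d; returning the first",
                      length(best), dim))
  }
  diagram[best[1], , drop = FALSE]
}

#' Representative cycle of a loop feature
#'
#' Extracts a set of edges realizing a given dimension-1 feature: the chain
#' recorded by the boundary-matrix reduction at the feature's pairing time.
#' The edges form one or more closed cycles (every vertex has even degree)
#' and every edge's filtration value is at most the feature's birth.  The
#' cycle is deterministic given the filtration ordering, but like any
#' homology generator it is only one representative of its class.
#'
#' @param filtration A `"vr_filtration"` object.
#' @param feature A one-row data frame (as returned by
#'   [most_persistent_feature()]) or a numeric `c(birth, death)` pair
#'   identifying a dimension-1 feature of the filtration's diagram.
#' @return A `"representative_cycle"`: list with `edges` (m x 2 matrix of
#'   1-based vertex indices), `vertices`, `birth`, `death`, `dim`.
#' @export
representative_cycle <- function(filtration, feature) {
  if (is.data.frame(feature)) {
    if (nrow(feature) != 1)
      rta_stop("feature must identify a single diagram row", "rta_validation_error")
    b <- feature$birth; dth <- feature$death
    if (!is.null(feature$dimension) && feature$dimension != 1)
      rta_stop("representative cycles are computed for dimension-1 features only",
               "rta_validation_error")
  } else if (is.numeric(feature) && length(feature) == 2) {
    b <- feature[1]; dth <- feature[2]
  } else {
    rta_stop("feature must be a one-row data frame or c(birth, death)",
             "rta_validation_error")
  }
  pd <- compute_persistence(filtration, cycles = TRUE)
  hit <- which(pd$dimension == 1 &
                 abs(pd$birth - b) <= 1e-12 & abs(pd$death - dth) <= 1e-12)
  if (length(hit) == 0)
    rta_stop(sprintf("no dimension-1 feature with birth %g and death %g", b, dth),
             "rta_feature_not_found")
  edges <- attr(pd, "cycles")[[hit[1]]]
  colnames(edges) <- c("v1", "v2")
  structure(list(dim = 1L, edges = edges,
                 vertices = sort(unique(as.vector(edges))),
                 birth = pd$birth[hit[1]], death = pd$death[hit[1]],
                 items = filtration$items),
            class = "representative_cycle")
}

#' @export
print.representative_cycle <- function(x, ...) {
  cat(sprintf("Representative cycle (H1, birth %g, death %g): %d edges over %d vertices\n",
              x$birth, x$death, nrow(x$edges), length(x$vertices)))
  invisible(x)
}

#' Write a persistence diagram to CSV
#'
#' Columns `dimension,birth,death,death_capped`.
#'
#' @param diagram A `"persistence_diagram"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path) {
  utils::write.csv(as.data.frame(diagram), path, row.names = FALSE)
  invisible(path)
}

#' Read a persistence diagram from CSV
#' @param path CSV with columns `dimension,birth,death,death_capped`.
#' @param max_radius Optional cap radius to attach to the diagram.
#' @return A `"persistence_diagram"`.
#' @export
read_diagram <- function(path, max_radius = NULL) {
  df <- utils::read.csv(path)
  need <- c("dimension", "birth", "death", "death_capped")
  if (!all(need %in% names(df)))
    rta_stop("diagram CSV must have columns dimension,birth,death,death_capped",
             "rta_parse_error")
  new_persistence_diagram(list(dimension = as.integer(df$dimension),
                               birth = df$birth, death = df$death,
                               death_capped = as.logical(df$death_capped)),
                          max_radius %||% max(df$death), max(df$dimension))
}

#' Write a representative cycle as a CSV edge list with a JSON sidecar
#'
#' The CSV has columns `v1,v2`; the sidecar `<path>.json` names the feature
#' the cycle represents.
#'
#' @param cycle A `"representative_cycle"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycle <- function(cycle, path) {
  utils::write.csv(as.data.frame(cycle$edges), path, row.names = FALSE)
  jsonlite::write_json(list(dim = cycle$dim, birth = cycle$birth,
                            death = cycle$death),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
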