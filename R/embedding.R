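#' Classical (Torgerson) multidimensional scaling of an RDM
#'
#' Wraps [stats::cmdscale()] (double-centering of `-D^2/2` followed by
#' eigendecomposition, coordinates scaled by the square roots of the
#' eigenvalues) and post-processes for reproducible plotting: columns whose
#' eigenvalue is not positive are zeroed with a warning, and each column's
#' sign is fixed so that its largest-magnitude entry is positive, removing
#' the reflection ambiguity.
#'
#' @param rdm An `"rdm"` object.
#' @param k Embedding dimension (default 2); must be smaller than the
#'   number of items.
#' @return An `"mds_embedding"`: list with `coords` (n x k, columns ordered
#'   by descending eigenvalue, each column summing to 0) and `eigenvalues`
#'   (the first k eigenvalues of the double-centered matrix).
#' @examples
#' sq <- rdm_from_points(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' emb <- classical_mds(sq)
#' max(abs(dist(emb$coords) - dist(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))))
#' @export
classical_mds <- function(rdm, k = 2) {
  rdm <- if (inherits(rdm, "rdm")) rdm else validate_rdm(rdm)
  n <- nrow(rdm)
  if (!is_count(k) || k < 1)
    rta_stop("k must be a positive integer", "rta_validation_error")
  if (k >= n)
    rta_stop(sprintf("k (%d) must be smaller than the number of items (%d)",
                     k, n), "rta_validation_error")
  res <- suppressWarnings(stats::cmdscale(rdm_matrix(rdm), k = k, eig = TRUE))
  pts <- res$points
  if (ncol(pts) < k) {
    warning(sprintf(
      "only %d of the first %d eigenvalues are positive; remaining coordinates set to 0",
      ncol(pts), k))
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rdm_items(rdm)
  structure(list(coords = pts, eigenvalues = res$eig[seq_len(k)]),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d items in %d dimensions (eigenvalues %s)\n",
              nrow(x$coords), ncol(x$coords),
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' Write an MDS embedding as CSV
#' @param embedding An `"mds_embedding"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(item = rownames(embedding$coords),
                   x = embedding$coords[, 1],
                   y = if (ncol(embedding$coords) >= 2) embedding$coords[, 2] else 0)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Vietoris-Rips graph of an RDM at a fixed scale
#'
#' Nodes are all items; edges connect every pair with dissimilarity at most
#' `epsilon`.  This is the 1-skeleton of the Rips complex at that scale.
#'
#' @param rdm An `"rdm"` object.
#' @param epsilon Linkage radius (>= 0).
#' @return An [igraph::graph] with vertex attributes `name` (item label)
#'   and `index` (row index in the RDM), and edge attribute
#'   `dissimilarity`.
#' @export
vr_graph <- function(rdm, epsilon) {
  rdm <- if (inherits(rdm, "rdm")) rdm else validate_rdm(rdm)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0)
    rta_stop("epsilon must be a single nonnegative number", "rta_validation_error")
  d <- rdm_matrix(rdm)
  n <- nrow(d)
  sel <- which(upper.tri(d) & d <= epsilon, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rdm_items(rdm))
  g <- igraph::set_vertex_attr(g, "index", value = seq_len(n))
  if (nrow(sel) > 0) {
    g <- igraph::add_edges(g, t(sel[, c(1, 2), drop = FALSE]))
    g <- igraph::set_edge_attr(g, "dissimilarity", value = d[sel])
  }
  g
}

#' Connected component of a Rips graph containing a representative cycle
#'
#' @param graph A graph from [vr_graph()].
#' @param cycle A `"representative_cycle"` (or an integer vector of vertex
#'   indices).
#' @return The induced subgraph of the component holding the cycle's
#'   vertices.  At any scale at or above the cycle's birth the cycle lies
#'   in one component; vertices spanning several components are an error.
#' @export
loop_component <- function(graph, cycle) {
  verts <- if (inherits(cycle, "representative_cycle")) cycle$vertices
           else as.integer(cycle)
  if (any(verts < 1 | verts > igraph::vcount(graph)))
    rta_stop("cycle vertices outside the graph", "rta_validation_error")
  comp <- igraph::components(graph)
  members <- unique(comp$membership[verts])
  if (length(members) > 1)
    rta_stop("cycle vertices span multiple components (epsilon below the cycle birth?)",
             "rta_validation_error")
  igraph::induced_subgraph(graph, which(comp$membership == members))
}

default_plrg_colors <- function() {
  list(pink = c(255, 105, 180), green = c(0, 128, 0),
       blue = c(0, 0, 255), orange = c(255, 165, 0))
}

#' Map 2D MDS coordinates to node colors
#'
#' Each axis is min-max normalized to `[0, 1]`.  The horizontal axis
#' interpolates linearly in RGB from pink (left) to green (right), the
#' vertical axis from blue (bottom) to orange (top); a node's color is the
#' channel-wise mean of its two axis colors (so the top-right corner is the
#' average of green and orange, a brown).  A degenerate axis (zero range)
#' contributes its midpoint color uniformly.
#'
#' @param embedding An `"mds_embedding"` with at least 2 columns.
#' @param endpoints List with RGB triplets `pink`, `green`, `blue`,
#'   `orange` (0-255); see `default_plrg_colors()` values in the default.
#' @return An n x 3 matrix of RGB values in 0-255 with attribute `"hex"`.
#' @export
node_colors <- function(embedding, endpoints = default_plrg_colors()) {
  coords <- if (inherits(embedding, "mds_embedding")) embedding$coords
            else as.matrix(embedding)
  if (ncol(coords) < 2)
    rta_stop("node colors need a 2D embedding", "rta_validation_error")
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0.5, length(v)))
    (v - rng[1]) / diff(rng)
  }
  tx <- norm01(coords[, 1])
  ty <- norm01(coords[, 2])
  lerp <- function(a, b, t) outer(1 - t, a) + outer(t, b)
  horiz <- lerp(endpoints$pink, endpoints$green, tx)
  vert <- lerp(endpoints$blue, endpoints$orange, ty)
  rgbm <- (horiz + vert) / 2
  colnames(rgbm) <- c("r", "g", "b")
  rownames(rgbm) <- rownames(coords)
  attr(rgbm, "hex") <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3],
                                      maxColorValue = 255)
  rgbm
}

#' Build a proximity-labeled Rips graph (PLRG)
#'
#' A PLRG is a snapshot of an RDM's topology annotated with its geometry:
#' the Rips graph at the birth scale of the most persistent loop, restricted
#' to the connected component containing that loop's representative cycle,
#' with nodes colored by their classical-MDS coordinates
#' ([node_colors()]) and laid out by the Fruchterman-Reingold algorithm
#' under a fixed seed.  Color gradients that follow the graph indicate
#' agreement between geometry (MDS) and topology (the Rips graph); clashing
#' colors on adjacent nodes indicate structure that linear projection
#' missed.
#'
#' @param rdm An `"rdm"` object.
#' @param diagram Optional `"persistence_diagram"` of `rdm` computed with
#'   `cycles = TRUE`; computed internally when missing.
#' @param cycle Optional `"representative_cycle"`; defaults to the cycle of
#'   the most persistent loop.
#' @param epsilon Linkage radius; `NULL` (default) uses the birth of the
#'   most persistent loop.
#' @param mds `"full"` (default) embeds the whole RDM for coloring;
#'   `"component"` embeds only the plotted component's sub-RDM.
#' @param endpoints Axis endpoint colors, as in [node_colors()].
#' @param layout_seed Seed for the force-directed layout (default 42).
#' @param layout_niter Fruchterman-Reingold iterations (default 500).
#' @return A `"plrg"`: list with `graph` (igraph with vertex attributes
#'   `x`, `y`, `r`, `g`, `b`, `label`, `in_cycle` and edge attribute
#'   `dissimilarity`), `epsilon`, `feature`, `cycle`, `layout_seed`.
#' @export
build_plrg <- function(rdm, diagram = NULL, cycle = NULL, epsilon = NULL,
                       mds = c("full", "component"),
                       endpoints = default_plrg_colors(),
                       layout_seed = 42, layout_niter = 500) {
  mds <- match.arg(mds)
  rdm <- if (inherits(rdm, "rdm")) rdm else validate_rdm(rdm)
  if (is.null(diagram))
    diagram <- rips_diagram(rdm, max_dim = 1, cycles = TRUE)
  feature <- most_persistent_feature(diagram, 1)
  if (is.null(cycle)) {
    cyc_list <- attr(diagram, "cycles")
    if (!is.null(cyc_list)) {
      row <- as.integer(rownames(feature))
      edges <- cyc_list[[row]]
      colnames(edges) <- c("v1", "v2")
      cycle <- structure(list(dim = 1L, edges = edges,
                              vertices = sort(unique(as.vector(edges))),
                              birth = feature$birth, death = feature$death,
                              items = rdm_items(rdm)),
                         class = "representative_cycle")
    } else {
      cycle <- representative_cycle(build_vr_filtration(rdm, max_dim = 1),
                                    feature)
    }
  }
  epsilon <- epsilon %||% feature$birth
  g <- vr_graph(rdm, epsilon)
  comp <- loop_component(g, cycle)
  kept <- igraph::vertex_attr(comp, "index")
  emb <- if (mds == "full") classical_mds(rdm, 2)
         else classical_mds(validate_rdm(rdm_matrix(rdm)[kept, kept, drop = FALSE],
                                         items = rdm_items(rdm)[kept]), 2)
  cols <- node_colors(emb, endpoints)
  if (mds == "full") cols <- cols[kept, , drop = FALSE]
  layout <- with_seed(layout_seed,
                      igraph::layout_with_fr(comp, niter = layout_niter))
  comp <- igraph::set_vertex_attr(comp, "x", value = layout[, 1])
  comp <- igraph::set_vertex_attr(comp, "y", value = layout[, 2])
  comp <- igraph::set_vertex_attr(comp, "r", value = cols[, 1])
  comp <- igraph::set_vertex_attr(comp, "g", value = cols[, 2])
  comp <- igraph::set_vertex_attr(comp, "b", value = cols[, 3])
  comp <- igraph::set_vertex_attr(comp, "label",
                                  value = igraph::vertex_attr(comp, "name"))
  comp <- igraph::set_vertex_attr(comp, "in_cycle",
                                  value = kept %in% cycle$vertices)
  structure(list(graph = comp, epsilon = epsilon, feature = feature,
                 cycle = cycle, mds = mds, layout_seed = layout_seed,
                 layout_niter = layout_niter, endpoints = endpoints),
            class = "plrg")
}

#' @export
print.plrg <- function(x, ...) {
  cat(sprintf("PLRG at epsilon = %g: %d nodes, %d edges (%d on the representative cycle)\n",
              x$epsilon, igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(igraph::vertex_attr(x$graph, "in_cycle"))))
  invisible(x)
}

#' Render a PLRG
#'
#' Draws edges, MDS-colored nodes, and the representative cycle emphasized
#' with deeper (darkened) node colors and enlarged vertices.
#'
#' @param x A `"plrg"`.
#' @param vertex_size Base node size (cycle nodes are drawn 1.5x larger).
#' @param show_labels Draw item labels.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.plrg <- function(x, vertex_size = 6, show_labels = FALSE, ...) {
  g <- x$graph
  rgbm <- cbind(igraph::vertex_attr(g, "r"), igraph::vertex_attr(g, "g"),
                igraph::vertex_attr(g, "b"))
  in_cycle <- igraph::vertex_attr(g, "in_cycle")
  fill <- rgbm
  fill[in_cycle, ] <- fill[in_cycle, , drop = FALSE] * 0.65 # deeper color
  hex <- grDevices::rgb(fill[, 1], fill[, 2], fill[, 3], maxColorValue = 255)
  coords <- cbind(igraph::vertex_attr(g, "x"), igraph::vertex_attr(g, "y"))
  igraph::plot.igraph(
    g, layout = coords, vertex.color = hex,
    vertex.size = ifelse(in_cycle, 1.5 * vertex_size, vertex_size),
    vertex.frame.color = ifelse(in_cycle, "black", "grey40"),
    vertex.label = if (show_labels) igraph::vertex_attr(g, "label") else NA,
    ...)
  invisible(x)
}

#' Export a PLRG to GraphML or an image file
#'
#' GraphML carries node attributes `x`, `y`, `r`, `g`, `b`, `label`,
#' `in_cycle` and the edge attribute `dissimilarity`; `png`/`svg` render
#' the graph via [plot.plrg()].
#'
#' @param plrg A `"plrg"`.
#' @param path Output path.
#' @param format `"graphml"`, `"png"` or `"svg"`.
#' @param width,height Image size in pixels (png) or inches (svg).
#' @param ... Passed to [plot.plrg()] for image formats.
#' @return `path`, invisibly.
#' @export
export_plrg <- function(plrg, path, format = c("graphml", "png", "svg"),
                        width = 800, height = 800, ...) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(plrg$graph, path, format = "graphml")
  } else {
    if (format == "png") grDevices::png(path, width = width, height = height)
    else grDevices::svg(path, width = width / 100, height = height / 100)
    on.exit(grDevices::dev.off())
    plot(plrg, ...)
  }
  invisible(path)
}
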