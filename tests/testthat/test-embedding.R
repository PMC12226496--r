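test_that("classical MDS recovers Euclidean-realizable configurations exactly", {
  # collinear points: realizable in 1D, second coordinate numerically zero
  d3 <- validate_rdm(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3))
  emb <- classical_mds(d3)
  expect_lt(max(abs(as.matrix(dist(emb$coords)) - rdm_matrix(d3))), 1e-9)
  # non-metric RDM: negative eigenvalue in the top k, column zeroed + warning
  dnm <- validate_rdm(matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3))
  expect_warning(embnm <- classical_mds(dnm), "positive")
  expect_equal(unname(embnm$coords[, 2]), c(0, 0, 0))
  sq <- unit_square_rdm()
  emb2 <- classical_mds(sq)
  expect_lt(max(abs(as.matrix(dist(emb2$coords)) - rdm_matrix(sq))), 1e-9)
  set.seed(70)
  for (trial in 1:10) {
    pts <- matrix(runif(24), 12, 2)
    r <- rdm_from_points(pts)
    emb3 <- classical_mds(r)
    expect_lt(max(abs(as.matrix(dist(emb3$coords)) - rdm_matrix(r))), 1e-9)
  }
})

test_that("MDS embeddings are centered, eigen-ordered, and sign-fixed", {
  set.seed(71)
  r <- random_rdm(10)
  emb <- classical_mds(r)
  expect_lt(max(abs(colSums(emb$coords))), 1e-9)
  expect_true(all(diff(emb$eigenvalues) <= 1e-9))
  for (j in 1:2)
    expect_gt(emb$coords[which.max(abs(emb$coords[, j])), j], 0)
  expect_error(classical_mds(r, k = 10), class = "rta_validation_error")
})

test_that("Rips graph edges are the at-most-epsilon pairs and grow with epsilon", {
  sq <- unit_square_rdm()
  expect_equal(igraph::ecount(vr_graph(sq, 0)), 0)
  g1 <- vr_graph(sq, 1)
  expect_equal(igraph::ecount(g1), 4) # the 4-cycle of unit sides
  expect_equal(igraph::ecount(vr_graph(sq, sqrt(2))), 6) # complete graph
  eps_grid <- seq(0, sqrt(2), length.out = 8)
  counts <- sapply(eps_grid, function(e) igraph::ecount(vr_graph(sq, e)))
  expect_true(all(diff(counts) >= 0))
  expect_equal(sort(igraph::edge_attr(g1, "dissimilarity")), rep(1, 4))
})

test_that("loop_component isolates the cycle's component, matching union-find", {
  # circle plus a far outlier: the outlier is excluded at the loop birth scale
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- rbind(cbind(cos(th), sin(th)), c(30, 30))
  r <- rdm_from_points(pts)
  f <- build_vr_filtration(r, 1)
  pd <- compute_persistence(f)
  cyc <- representative_cycle(f, most_persistent_feature(pd, 1))
  g <- vr_graph(r, cyc$birth)
  comp <- loop_component(g, cyc)
  expect_equal(sort(igraph::vertex_attr(comp, "index")), 1:12)
  # independent union-find check of the component membership
  uf <- seq_len(13)
  find <- function(x) { while (uf[x] != x) x <- uf[x]; x }
  d <- rdm_matrix(r)
  for (i in 1:12) for (j in (i + 1):13)
    if (d[i, j] <= cyc$birth) uf[find(i)] <- find(j)
  members <- which(sapply(1:13, find) == find(1))
  expect_equal(sort(igraph::vertex_attr(comp, "index")), sort(members))
  # fully connected graph: the component is the whole graph
  gc <- vr_graph(r, max(r))
  expect_equal(igraph::vcount(loop_component(gc, cyc)), 13)
})

test_that("node colors blend the two axis scales channel-wise", {
  coords <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  cols <- node_colors(list(coords = coords) |> structure(class = "mds_embedding"))
  ep <- default_plrg_colors()
  expect_equal(unname(cols[3, ]), (ep$green + ep$orange) / 2) # top-right: brown
  expect_equal(unname(cols[1, ]), (ep$pink + ep$blue) / 2)    # bottom-left
  mid <- (ep$pink + ep$green + ep$blue + ep$orange) / 4
  expect_equal(unname(cols[5, ]), mid)
  # identical coordinates get identical colors
  cols2 <- node_colors(structure(list(coords = rbind(coords, c(1, 1))),
                                 class = "mds_embedding"))
  expect_equal(unname(cols2[3, ]), unname(cols2[6, ]))
  # degenerate vertical axis contributes its midpoint color uniformly
  flat <- structure(list(coords = cbind(c(0, 1, 2), 0)), class = "mds_embedding")
  cf <- node_colors(flat)
  vert_mid <- (ep$blue + ep$orange) / 2
  expect_equal(unname(cf[1, ]), (ep$pink + vert_mid) / 2)
  expect_equal(unname(cf[3, ]), (ep$green + vert_mid) / 2)
})

test_that("node colors are equivariant under item relabeling", {
  set.seed(72)
  pts <- matrix(runif(20), 10, 2)
  r <- rdm_from_points(pts)
  p <- sample(10)
  rp <- validate_rdm(rdm_matrix(r)[p, p])
  strip <- function(m) { attr(m, "hex") <- NULL; unname(m) }
  cols <- node_colors(classical_mds(r))
  colsp <- node_colors(classical_mds(rp))
  expect_equal(strip(colsp), strip(cols)[p, ], tolerance = 1e-8)
})

test_that("the PLRG of an even circle is a color-graded ring", {
  r <- even_circle_rdm(30)
  plrg <- build_plrg(r)
  g <- plrg$graph
  expect_equal(igraph::vcount(g), 30)
  expect_true(all(igraph::degree(g) == 2)) # a pure ring at loop birth
  expect_true(all(igraph::vertex_attr(g, "in_cycle")))
  # geometry and topology agree: colors of adjacent nodes are similar,
  # colors of antipodal nodes are not
  rgbm <- cbind(igraph::vertex_attr(g, "r"), igraph::vertex_attr(g, "g"),
                igraph::vertex_attr(g, "b"))
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  adj_dist <- mean(sqrt(rowSums((rgbm[ends[, 1], ] - rgbm[ends[, 2], ])^2)))
  anti <- cbind(1:15, 16:30)
  anti_dist <- mean(sqrt(rowSums((rgbm[anti[, 1], ] - rgbm[anti[, 2], ])^2)))
  expect_lt(adj_dist, anti_dist / 3)
})

test_that("a torus PLRG shows weaker geometry-topology agreement than a circle PLRG", {
  color_ratio <- function(plrg) {
    g <- plrg$graph
    rgbm <- cbind(igraph::vertex_attr(g, "r"), igraph::vertex_attr(g, "g"),
                  igraph::vertex_attr(g, "b"))
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    adj <- mean(sqrt(rowSums((rgbm[ends[, 1], ] - rgbm[ends[, 2], ])^2)))
    all_pairs <- t(combn(nrow(rgbm), 2))
    glob <- mean(sqrt(rowSums((rgbm[all_pairs[, 1], ] -
                                 rgbm[all_pairs[, 2], ])^2)))
    adj / glob
  }
  for (s in 1:3) {
    tor <- rdm_from_points(unclass(sample_torus(60, 2, 1, seed = s)))
    circ <- rdm_from_points(unclass(sample_circle(60, noise_sd = 0.05,
                                                  seed = s)))
    pt <- build_plrg(tor)
    pc <- build_plrg(circ)
    expect_gte(sum(igraph::vertex_attr(pt$graph, "in_cycle")), 3)
    # 2D MDS collapses the torus's minor loop, so adjacent nodes carry
    # less-coherent colors than on the planar circle
    expect_gt(color_ratio(pt), color_ratio(pc))
  }
})

test_that("PLRG layout and attributes are deterministic given the seed", {
  r <- even_circle_rdm(20)
  p1 <- build_plrg(r, layout_seed = 42)
  p2 <- build_plrg(r, layout_seed = 42)
  expect_identical(igraph::vertex_attr(p1$graph, "x"),
                   igraph::vertex_attr(p2$graph, "x"))
  p3 <- build_plrg(r, layout_seed = 1)
  expect_false(identical(igraph::vertex_attr(p1$graph, "x"),
                         igraph::vertex_attr(p3$graph, "x")))
})

test_that("PLRG export round trips GraphML and renders PNG", {
  r <- even_circle_rdm(16)
  plrg <- build_plrg(r)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_plrg(plrg, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(plrg$graph))
  expect_equal(igraph::ecount(back), igraph::ecount(plrg$graph))
  expect_equal(igraph::vertex_attr(back, "x"),
               igraph::vertex_attr(plrg$graph, "x"))
  expect_equal(as.logical(igraph::vertex_attr(back, "in_cycle")),
               igraph::vertex_attr(plrg$graph, "in_cycle"))
  expect_equal(igraph::edge_attr(back, "dissimilarity"),
               igraph::edge_attr(plrg$graph, "dissimilarity"))
  png_path <- withr::local_tempfile(fileext = ".png")
  export_plrg(plrg, png_path, "png")
  expect_true(file.exists(png_path))
  expect_gt(file.size(png_path), 0)
  expect_error(export_plrg(plrg, "x.foo", "foo"))
})

test_that("a PLRG needs a loop when epsilon comes from the diagram", {
  # a triangle's loop is born and filled at the same scale: no H1 feature
  expect_error(build_plrg(equilateral_rdm()), class = "rta_no_features")
})
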