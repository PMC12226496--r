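# Independent oracles used to validate the persistence and bottleneck
# implementations.  These are deliberately naive (rank computations and
# exhaustive enumeration) and share no code with the package internals.

# rank of a 0/1 matrix over the field with two elements
gf2_rank <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M %% 2
  r <- 0L
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j] == 1 & seq_len(nrow(M)) > r)
    if (length(piv) == 0) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    for (i in which(M[, j] == 1)) if (i != r) M[i, ] <- (M[i, ] + M[r, ]) %% 2
  }
  r
}

# Betti numbers (dims 0 and 1) of the Rips complex of d at scale eps,
# directly from boundary-matrix ranks: betti_k = n_k - rank d_k - rank d_{k+1}
betti_oracle <- function(d, eps) {
  n <- nrow(d)
  edges <- which(upper.tri(d) & d <= eps, arr.ind = TRUE)
  ne <- nrow(edges)
  tri <- t(combn(n, 3))
  tri_val <- apply(tri, 1, function(v) max(d[v[1], v[2]], d[v[1], v[3]],
                                           d[v[2], v[3]]))
  tri <- tri[tri_val <= eps, , drop = FALSE]
  nt <- nrow(tri)
  d1 <- matrix(0L, n, max(ne, 1))
  if (ne > 0)
    for (e in seq_len(ne)) d1[edges[e, ], e] <- 1L
  rank_d1 <- if (ne > 0) gf2_rank(d1) else 0L
  d2 <- matrix(0L, max(ne, 1), max(nt, 1))
  if (nt > 0) {
    edge_id <- function(i, j) which(edges[, 1] == min(i, j) &
                                      edges[, 2] == max(i, j))
    for (t in seq_len(nt)) {
      v <- tri[t, ]
      d2[c(edge_id(v[1], v[2]), edge_id(v[1], v[3]), edge_id(v[2], v[3])), t] <- 1L
    }
  }
  rank_d2 <- if (nt > 0) gf2_rank(d2) else 0L
  c(b0 = n - rank_d1, b1 = ne - rank_d1 - rank_d2)
}

# Betti numbers implied by a persistence diagram at scale eps: features
# alive on [birth, death), capped features alive through the cap radius
diagram_betti <- function(pd, eps, dim) {
  sum(pd$dimension == dim & pd$birth <= eps &
        (pd$death_capped | pd$death > eps))
}

# exhaustive-matching bottleneck distance for small diagrams
# (<= ~6 features per side): enumerate every partial injective matching
bottleneck_oracle <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  pers2 <- function(m) (m[, 2] - m[, 1]) / 2
  linf <- function(x, y) max(abs(x[1] - y[1]), abs(x[2] - y[2]))
  best <- Inf
  recurse <- function(i, used, cur) {
    if (cur >= best) return()
    if (i > n1) {
      rest <- if (n2 > 0) pers2(b)[!used] else numeric(0)
      tot <- max(c(cur, rest, 0))
      if (tot < best) best <<- tot
      return()
    }
    # feature i to the diagonal
    recurse(i + 1, used, max(cur, pers2(a)[i]))
    if (n2 > 0)
      for (j in which(!used)) {
        u <- used; u[j] <- TRUE
        recurse(i + 1, u, max(cur, linf(a[i, ], b[j, ])))
      }
  }
  recurse(1L, rep(FALSE, max(n2, 0)), 0)
  best
}

# random diagram as a (birth, death) matrix
random_diagram_matrix <- function(k, scale = 1) {
  if (k == 0) return(matrix(numeric(0), 0, 2))
  b <- runif(k, 0, scale)
  cbind(b, b + runif(k, 0, scale))
}

as_pd <- function(mat, dim = 1L, max_radius = NULL) {
  pd <- data.frame(dimension = rep(dim, nrow(mat)),
                   birth = mat[, 1], death = mat[, 2],
                   death_capped = rep(FALSE, nrow(mat)))
  attr(pd, "max_radius") <- max_radius
  class(pd) <- c("persistence_diagram", "data.frame")
  pd
}
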