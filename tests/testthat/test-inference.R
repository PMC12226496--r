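test_that("loss statistic equals a brute-force double loop and vanishes on identical groups", {
  set.seed(90)
  ga <- lapply(1:3, function(i) as_pd(random_diagram_matrix(3)))
  gb <- lapply(1:4, function(i) as_pd(random_diagram_matrix(2)))
  brute <- 0
  for (g in list(ga, gb))
    for (i in seq_along(g))
      for (j in seq_along(g))
        if (i < j) brute <- brute +
            bottleneck_distance(g[[i]], g[[j]], 1)$value
  expect_equal(loss_statistic(ga, gb, 1), brute, tolerance = 1e-12)
  same <- lapply(1:3, function(i) ga[[1]])
  expect_equal(loss_statistic(same, same, 1), 0)
  # a singleton group contributes no within-group variation
  expect_equal(loss_statistic(list(ga[[1]], ga[[1]]), list(gb[[1]]), 1), 0)
  expect_error(loss_statistic(list(), gb, 1), class = "rta_validation_error")
})

test_that("paired bootstrap shares index multisets, the joint cap, and is seed-reproducible", {
  set.seed(91)
  pts <- matrix(rnorm(60), 20, 3)
  t_rdm <- rdm_from_points(pts)
  m_rdm <- rdm_from_points(pts * 2)
  pb <- paired_bootstrap_diagrams(t_rdm, m_rdm, n_boot = 5, seed = 100)
  expect_equal(pb$cap, max(max(t_rdm), max(m_rdm)))
  for (p in pb$pairs) {
    expect_equal(attr(p$pd_t, "max_radius"), pb$cap)
    expect_equal(attr(p$pd_m, "max_radius"), pb$cap)
  }
  pb2 <- paired_bootstrap_diagrams(t_rdm, m_rdm, n_boot = 5, seed = 100)
  expect_identical(lapply(pb$pairs, `[[`, "indices"),
                   lapply(pb2$pairs, `[[`, "indices"))
  # index multisets differ across iterations (collision chance is negligible)
  expect_gt(length(unique(lapply(pb$pairs, `[[`, "indices"))), 1)
  expect_error(paired_bootstrap_diagrams(t_rdm, random_rdm(5), 5),
               class = "rta_validation_error")
})

test_that("identical target and model give zero distances and p = 1", {
  set.seed(92)
  t_rdm <- rdm_from_points(matrix(rnorm(45), 15, 3))
  pb <- paired_bootstrap_diagrams(t_rdm, t_rdm, n_boot = 6, seed = 7)
  for (p in pb$pairs)
    expect_equal(bottleneck_distance(p$pd_t, p$pd_m, 1)$value, 0)
  pt <- permutation_test(pb, n_perm = 50, dim = 1, seed = 8)
  expect_equal(pt$p_value, 1)
  expect_true(all(pt$perm_stats == pt$observed))
  expect_equal(distance_confidence_interval(pb, 1), c(0, 0))
})

test_that("the permutation p-value respects its formula bounds", {
  set.seed(93)
  pts <- matrix(rnorm(60), 20, 3)
  t_rdm <- rdm_from_points(pts)
  m_rdm <- rdm_from_points(pts + rnorm(60, sd = 0.3))
  pb <- paired_bootstrap_diagrams(t_rdm, m_rdm, n_boot = 8, seed = 9)
  pt <- permutation_test(pb, n_perm = 99, dim = 1, seed = 10)
  expect_gte(pt$p_value, 1 / 100)
  expect_lte(pt$p_value, 1)
  expect_equal(length(pt$perm_stats), 99)
  # identical seed, identical trace
  pt2 <- permutation_test(pb, n_perm = 99, dim = 1, seed = 10)
  expect_identical(pt$perm_stats, pt2$perm_stats)
})

test_that("confidence interval percentiles match direct computation", {
  set.seed(94)
  pts <- matrix(rnorm(54), 18, 3)
  t_rdm <- rdm_from_points(pts)
  m_rdm <- rdm_from_points(pts + rnorm(54, sd = 0.2))
  pb <- paired_bootstrap_diagrams(t_rdm, m_rdm, n_boot = 10, seed = 20)
  cross <- sapply(pb$pairs, function(p)
    bottleneck_distance(p$pd_t, p$pd_m, 1)$value)
  expect_equal(distance_confidence_interval(pb, 1),
               unname(quantile(cross, c(0.025, 0.975), type = 7)))
})

test_that("the permutation test is calibrated on independent diagram groups and powerful across topologies", {
  # groups built from independent replicates: the classical two-group
  # setting; rejection at the 0.1 level should sit near the nominal rate
  iid_pairs <- function(s, shape_b) {
    pairs <- lapply(1:12, function(b) {
      c1 <- rdm_from_points(unclass(sample_circle(30, noise_sd = 0.1,
                                                  seed = s * 1000 + b)))
      other <- if (shape_b == "circle")
        rdm_from_points(unclass(sample_circle(30, noise_sd = 0.1,
                                              seed = s * 1000 + 500 + b)))
      else
        rdm_from_points(unclass(sample_gaussian_clusters(
          30, rbind(c(0, 0)), sd = 0.5, seed = s * 1000 + 500 + b)))
      list(pd_t = rips_pd_fast(rdm_matrix(c1), 1),
           pd_m = rips_pd_fast(rdm_matrix(other), 1))
    })
    structure(list(pairs = pairs, n_boot = 12L, max_dim = 1L, cap = NA,
                   n = 30L, seed = NULL),
              class = "bootstrap_pairs")
  }
  rejections <- sum(sapply(1:15, function(s) {
    pt <- permutation_test(iid_pairs(s, "circle"), n_perm = 99, dim = 1,
                           seed = s)
    pt$p_value <= 0.1
  }))
  expect_lte(rejections, 4) # near-nominal under the null
  # distinct topologies (circle vs cluster): decisively rejected
  p_power <- sapply(1:5, function(s)
    permutation_test(iid_pairs(s + 100, "cluster"), n_perm = 99, dim = 1,
                     seed = s)$p_value)
  expect_true(all(p_power <= 0.05))
})

test_that("bootstrap thresholding distinguishes a clean circle from a cluster", {
  circ <- rdm_from_points(unclass(sample_circle(40, seed = 30)))
  bt <- bootstrap_threshold(circ, n_boot = 20, alpha = 0.1, seed = 31)
  expect_equal(sum(bt$significant$dimension == 1), 1)
  blob <- rdm_from_points(unclass(sample_gaussian_clusters(40, rbind(c(0, 0)),
                                                           sd = 1, seed = 32)))
  bt2 <- bootstrap_threshold(blob, n_boot = 20, alpha = 0.1, seed = 33)
  expect_equal(sum(bt2$significant$dimension == 1), 0)
  # significant features always sit above twice the band half-width
  pers <- bt$significant$death - bt$significant$birth
  expect_true(all(pers > 2 * bt$quantile_c[paste0("H", bt$significant$dimension)]))
})

test_that("the significant set grows as alpha increases", {
  circ <- rdm_from_points(unclass(sample_circle(30, noise_sd = 0.15, seed = 40)))
  bts <- lapply(c(0.05, 0.3, 0.9), function(a)
    bootstrap_threshold(circ, n_boot = 15, alpha = a, seed = 41))
  counts <- sapply(bts, function(b) nrow(b$significant))
  expect_true(all(diff(counts) >= 0))
  # quantile_c decreases toward the per-dimension minimum as alpha -> 1
  expect_true(all(bts[[3]]$quantile_c <= bts[[1]]$quantile_c))
  expect_error(bootstrap_threshold(circ, alpha = 1.5),
               class = "rta_validation_error")
})

test_that("adjudication ranks a same-topology model above a different-topology one", {
  target <- rdm_from_points(unclass(sample_circle(30, noise_sd = 0.05, seed = 50)))
  circle2 <- rdm_from_points(unclass(sample_circle(30, noise_sd = 0.05, seed = 51)))
  blob <- rdm_from_points(unclass(sample_gaussian_clusters(30, rbind(c(0, 0)),
                                                           sd = 0.5, seed = 52)))
  adj <- adjudicate(target, list(circle = circle2, blob = blob),
                    n_boot = 15, n_perm = 99, seed = 53)
  expect_lte(adj$p_values["blob", "H1"], adj$p_values["circle", "H1"])
  expect_true(all(adj$ci_lower <= adj$ci_upper, na.rm = TRUE))
  # identical model: p = 1, CI = (0, 0)
  adj_self <- adjudicate(target, list(self = target), n_boot = 8,
                         n_perm = 49, seed = 54)
  expect_equal(adj_self$p_values["self", "H1"], 1)
  expect_equal(unname(c(adj_self$ci_lower["self", "H1"],
                        adj_self$ci_upper["self", "H1"])), c(0, 0))
  # two identical models: neither ranks above the other
  adj_tie <- adjudicate(target, list(a = circle2, b = circle2),
                        n_boot = 8, n_perm = 49, seed = 55)
  expect_false(any(adj_tie$better$H1))
  expect_error(adjudicate(target, list()), class = "rta_validation_error")
})

test_that("adjudication results serialize to JSON and a flat table", {
  target <- rdm_from_points(unclass(sample_circle(20, noise_sd = 0.1, seed = 60)))
  model <- rdm_from_points(unclass(sample_circle(20, noise_sd = 0.1, seed = 61)))
  adj <- adjudicate(target, list(m = model), n_boot = 6, n_perm = 19, seed = 62)
  path <- withr::local_tempfile(fileext = ".json")
  write_adjudication(adj, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$models[[1]]$name, "m")
  expect_equal(parsed$models[[1]]$dimensions$H1$p_value,
               unname(adj$p_values["m", "H1"]))
  df <- as.data.frame(adj)
  expect_equal(nrow(df), 2) # one model x dims 0 and 1
  expect_true(all(c("model", "dimension", "p_value", "ci_lower") %in% names(df)))
})
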