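
# one bootstrap index multiset: resample with replacement, deduplicate
# (duplicated points only create zero-persistence features, which are
# dropped from diagrams anyway), redraw if fewer than 3 distinct items
resample_indices <- function(n) {
  repeat {
    idx <- sort(unique(sample.int(n, n, replace = TRUE)))
    if (length(idx) >= 3) return(idx)
    message("bootstrap resample had fewer than 3 distinct items; redrawn")
  }
}

#' Bootstrap significance thresholding of a persistence diagram
#'
#' Separates persistent (significant) features from noise features.  For
#' each bootstrap iteration the items are resampled with replacement, the
#' persistence diagram of the resampled sub-RDM is computed at the full
#' RDM's cap radius, and its per-dimension bottleneck distance to the full
#' diagram is recorded.  The `(1 - alpha)` empirical quantile of those
#' distances in each dimension gives a band half-width `c`; features with
#' persistence greater than `2 c` are declared significant.
#'
#' @param rdm An `"rdm"` object.
#' @param max_dim Highest homology dimension (default 1).
#' @param n_boot Bootstrap iterations (default 30, the usual minimum for
#'   stable quantiles at `alpha = 0.1`).
#' @param alpha Significance level in (0, 1); default 0.1.
#' @param seed Optional integer seed; the result is fully reproducible from
#'   it.
#' @param max_radius Cap radius; defaults to the maximum RDM entry.
#' @return A `"threshold_result"`: list with the full `diagram`, the
#'   per-dimension band `quantile_c`, the bootstrap `distances`
#'   (`n_boot` x dimensions), `significant` (the sub-diagram of significant
#'   features), `alpha`, `n_boot`, `seed`.
#' @export
bootstrap_threshold <- function(rdm, max_dim = 1, n_boot = 30, alpha = 0.1,
                                seed = NULL, max_radius = NULL) {
  rdm <- if (inherits(rdm, "rdm")) rdm else validate_rdm(rdm)
  if (!is_count(n_boot) || n_boot < 2)
    rta_stop("n_boot must be an integer >= 2", "rta_validation_error")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    rta_stop("alpha must lie strictly between 0 and 1", "rta_validation_error")
  d <- rdm_matrix(rdm)
  n <- nrow(d)
  max_radius <- max_radius %||% max(d)
  full <- rips_pd_fast(d, max_dim, max_radius)
  dims <- 0:max_dim
  full_mats <- lapply(dims, function(k) dim_matrix(full, k))
  distances <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- resample_indices(n)
      sub <- rips_pd_fast(d[idx, idx, drop = FALSE], max_dim, max_radius)
      vapply(seq_along(dims), function(j)
        bottleneck_value(dim_matrix(sub, dims[j]), full_mats[[j]]),
        numeric(1))
    }, numeric(length(dims))))
  })
  colnames(distances) <- paste0("H", dims)
  quantile_c <- apply(distances, 2, stats::quantile, probs = 1 - alpha,
                      type = 7, names = FALSE)
  pers <- full$death - full$birth
  sig <- pers > 2 * quantile_c[paste0("H", full$dimension)]
  structure(list(diagram = full, quantile_c = quantile_c,
                 distances = distances,
                 significant = full[sig, , drop = FALSE],
                 alpha = alpha, n_boot = as.integer(n_boot), seed = seed),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Bootstrap threshold (%d iterations, alpha = %g)\n",
              x$n_boot, x$alpha))
  for (nm in names(x$quantile_c))
    cat(sprintf("  %s: band half-width c = %g, %d/%d features significant\n",
                nm, x$quantile_c[nm],
                sum(x$significant$dimension == as.integer(sub("H", "", nm))),
                sum(x$diagram$dimension == as.integer(sub("H", "", nm)))))
  invisible(x)
}

#' Paired bootstrap persistence diagrams for two RDMs
#'
#' Draws `n_boot` shared item resamples and, for each, computes the
#' persistence diagrams of the corresponding target and model sub-RDMs.
#' Both diagrams of a pair use the same index multiset and a shared cap
#' radius equal to the joint maximum dissimilarity of the two RDMs, so that
#' capped deaths are comparable across the two groups.
#'
#' @param target,model `"rdm"` objects of identical size with item
#'   correspondence (row i of `target` is the same stimulus as row i of
#'   `model`).
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param max_dim Highest homology dimension (default 1).
#' @param seed Optional integer seed.
#' @return A `"bootstrap_pairs"` object: list with `pairs` (each containing
#'   `indices`, `pd_t`, `pd_m`), the shared `cap`, `max_dim`, `n`, `seed`.
#' @export
paired_bootstrap_diagrams <- function(target, model, n_boot, max_dim = 1,
                                      seed = NULL) {
  target <- if (inherits(target, "rdm")) target else validate_rdm(target)
  model <- if (inherits(model, "rdm")) model else validate_rdm(model)
  if (nrow(target) != nrow(model))
    rta_stop(sprintf("RDM sizes differ: %d vs %d", nrow(target), nrow(model)),
             "rta_validation_error")
  if (!is_count(n_boot) || n_boot < 2)
    rta_stop("n_boot must be an integer >= 2", "rta_validation_error")
  dt <- rdm_matrix(target)
  dm <- rdm_matrix(model)
  n <- nrow(dt)
  cap <- max(max(dt), max(dm)) # joint maximum dissimilarity
  pairs <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- resample_indices(n)
      list(indices = idx,
           pd_t = rips_pd_fast(dt[idx, idx, drop = FALSE], max_dim, cap),
           pd_m = rips_pd_fast(dm[idx, idx, drop = FALSE], max_dim, cap))
    })
  })
  structure(list(pairs = pairs, cap = cap, max_dim = as.integer(max_dim),
                 n = n, n_boot = as.integer(n_boot), seed = seed),
            class = "bootstrap_pairs")
}

#' @export
print.bootstrap_pairs <- function(x, ...) {
  cat(sprintf("Paired bootstrap diagrams: %d resamples of %d items (joint cap %g, max dim %d)\n",
              x$n_boot, x$n, x$cap, x$max_dim))
  invisible(x)
}

#' Within-group topological loss statistic
#'
#' The sum, over both groups, of all upper-triangle pairwise bottleneck
#' distances within the group: a topological analog of the within-group sum
#' of squared errors.  Low values mean each group's diagrams are mutually
#' similar.
#'
#' @param group_a,group_b Nonempty lists of `"persistence_diagram"` objects.
#' @param dim Homology dimension compared.
#' @return Nonnegative number.
#' @export
loss_statistic <- function(group_a, group_b, dim = 1) {
  if (length(group_a) == 0 || length(group_b) == 0)
    rta_stop("both groups must be nonempty", "rta_validation_error")
  within <- function(group) {
    mats <- lapply(group, dim_matrix, dim = dim)
    s <- 0
    m <- length(mats)
    if (m < 2) return(0)
    for (i in seq_len(m - 1))
      for (j in seq(i + 1, m))
        s <- s + bottleneck_value(mats[[i]], mats[[j]])
    s
  }
  within(group_a) + within(group_b)
}

# all pairwise bottleneck distances among the 2N diagrams
# [T_1..T_N, M_1..M_N]; each distance computed exactly once
pair_distance_matrix <- function(pairs, dim) {
  diagrams <- c(lapply(pairs$pairs, `[[`, "pd_t"),
                lapply(pairs$pairs, `[[`, "pd_m"))
  mats <- lapply(diagrams, dim_matrix, dim = dim)
  m <- length(mats)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1))
    for (j in seq(i + 1, m))
      D[i, j] <- D[j, i] <- bottleneck_value(mats[[i]], mats[[j]])
  D
}

upper_sum <- function(M) sum(M[upper.tri(M)])

#' Paired permutation test for a topological difference
#'
#' Tests whether the target and model representational spaces have
#' statistically distinct topologies.  The observed statistic is the
#' within-group loss ([loss_statistic()]) of the two groups of bootstrap
#' diagrams.  Each permutation independently swaps each pair's two diagrams
#' between the groups with probability 1/2 (the paired shuffle), and the
#' p-value is the +1-corrected frequency of permuted statistics less than
#' or equal to the observed one:
#' `p = (1 + #\{perm <= obs\}) / (1 + n_perm)`, so `p` is at least
#' `1 / (1 + n_perm)` and identical groups give `p = 1`.  All pairwise
#' bottleneck distances are computed once and cached.
#'
#' @param pairs A `"bootstrap_pairs"` object with at least 2 pairs.
#' @param n_perm Number of permutations (>= 1); default 1000.
#' @param dim Homology dimension tested (default 1).
#' @param seed Optional integer seed for the permutation draws.
#' @return A `"rta_permutation_test"`: list with `p_value`, `observed`,
#'   `perm_stats`, `dim`, `n_perm`, `seed`.
#' @export
permutation_test <- function(pairs, n_perm = 1000, dim = 1, seed = NULL) {
  if (!inherits(pairs, "bootstrap_pairs"))
    rta_stop("pairs must come from paired_bootstrap_diagrams()",
             "rta_validation_error")
  if (pairs$n_boot < 2)
    rta_stop("need at least 2 bootstrap pairs", "rta_validation_error")
  if (!is_count(n_perm) || n_perm < 1)
    rta_stop("n_perm must be an integer >= 1", "rta_validation_error")
  D <- pair_distance_matrix(pairs, dim)
  res <- permutation_test_from_matrix(D, pairs$n_boot, n_perm, seed)
  structure(c(res, list(dim = as.integer(dim), n_perm = as.integer(n_perm),
                        seed = seed)),
            class = "rta_permutation_test")
}

permutation_test_from_matrix <- function(D, n, n_perm, seed) {
  idx_t <- seq_len(n)
  idx_m <- n + idx_t
  observed <- upper_sum(D[idx_t, idx_t]) + upper_sum(D[idx_m, idx_m])
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      swap <- stats::runif(n) < 0.5
      a <- ifelse(swap, idx_m, idx_t)
      b <- ifelse(swap, idx_t, idx_m)
      upper_sum(D[a, a]) + upper_sum(D[b, b])
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats <= observed)) / (1 + n_perm)
  list(p_value = p, observed = observed, perm_stats = perm_stats)
}

#' @export
print.rta_permutation_test <- function(x, ...) {
  cat(sprintf("Paired topological permutation test (H%d): p = %g (observed loss %g, %d permutations)\n",
              x$dim, x$p_value, x$observed, x$n_perm))
  invisible(x)
}

#' Topological confidence interval for the target-model distance
#'
#' The 2.5% and 97.5% empirical percentiles (linear interpolation between
#' order statistics) of the within-pair bottleneck distances
#' `d(pd_t_b, pd_m_b)` across bootstrap resamples: a 95% confidence
#' interval for the topological distance between target and model.
#'
#' @param pairs A `"bootstrap_pairs"` object with at least 2 pairs.
#' @param dim Homology dimension (default 1).
#' @return Numeric `c(lower, upper)`.
#' @export
distance_confidence_interval <- function(pairs, dim = 1) {
  if (!inherits(pairs, "bootstrap_pairs"))
    rta_stop("pairs must come from paired_bootstrap_diagrams()",
             "rta_validation_error")
  if (pairs$n_boot < 2)
    rta_stop("need at least 2 bootstrap pairs", "rta_validation_error")
  cross <- vapply(pairs$pairs, function(p)
    bottleneck_value(dim_matrix(p$pd_t, dim), dim_matrix(p$pd_m, dim)),
    numeric(1))
  stats::quantile(cross, c(0.025, 0.975), type = 7, names = FALSE)
}

#' Adjudicate candidate model RDMs against a target RDM
#'
#' For every candidate model, runs the paired-bootstrap permutation test
#' ([permutation_test()]) and computes the 95% topological confidence
#' interval ([distance_confidence_interval()]) in every dimension up to
#' `max_dim`.  Among the models whose difference test is *not* significant
#' at the chosen threshold, model j ranks above model k in a dimension when
#' j's confidence interval lies entirely below k's.
#'
#' @param target An `"rdm"` object.
#' @param models Nonempty (optionally named) list of `"rdm"` objects, each
#'   the same size as `target` with item correspondence.
#' @param n_boot Bootstrap resamples per model (default 100).
#' @param n_perm Permutations per test (default 1000).
#' @param max_dim Highest homology dimension (default 1).
#' @param alpha Significance threshold for the difference test (default
#'   0.05).
#' @param bonferroni If `TRUE`, divide `alpha` by the number of models.
#' @param seed Optional master seed; every source of randomness derives
#'   from it, so identical seeds give identical results.
#' @return An `"rta_adjudication"`: per-model, per-dimension p-values,
#'   confidence intervals, observed statistics, and the better-model
#'   partial order (`better[[dim]][j, k]` is `TRUE` when model j is a
#'   better model of the target than model k).
#' @export
adjudicate <- function(target, models, n_boot = 100, n_perm = 1000,
                       max_dim = 1, alpha = 0.05, bonferroni = FALSE,
                       seed = NULL) {
  if (!is.list(models) || length(models) == 0)
    rta_stop("models must be a nonempty list of RDMs", "rta_validation_error")
  target <- if (inherits(target, "rdm")) target else validate_rdm(target)
  k <- length(models)
  model_names <- names(models) %||% paste0("model_", seq_len(k))
  model_names[model_names == ""] <- paste0("model_", which(model_names == ""))
  dims <- 0:max_dim
  seeds <- derive_seeds(seed, 2L * k)
  p_values <- matrix(NA_real_, k, length(dims),
                     dimnames = list(model_names, paste0("H", dims)))
  observed <- p_values
  ci_lower <- p_values
  ci_upper <- p_values
  for (i in seq_len(k)) {
    pairs <- paired_bootstrap_diagrams(target, models[[i]], n_boot,
                                       max_dim = max_dim,
                                       seed = seeds[[i]])
    for (j in seq_along(dims)) {
      D <- pair_distance_matrix(pairs, dims[j])
      res <- permutation_test_from_matrix(D, pairs$n_boot, n_perm,
                                          seeds[[k + i]])
      p_values[i, j] <- res$p_value
      observed[i, j] <- res$observed
      # within-pair distances sit on the cross-block diagonal of the cache
      cross <- D[cbind(seq_len(n_boot), n_boot + seq_len(n_boot))]
      ci <- stats::quantile(cross, c(0.025, 0.975), type = 7, names = FALSE)
      ci_lower[i, j] <- ci[1]
      ci_upper[i, j] <- ci[2]
    }
  }
  threshold <- alpha / (if (bonferroni) k else 1)
  better <- lapply(seq_along(dims), function(j) {
    ok <- p_values[, j] > threshold # not significantly different
    b <- outer(seq_len(k), seq_len(k), function(a, z)
      ok[a] & ok[z] & ci_upper[a, j] < ci_lower[z, j])
    diag(b) <- FALSE
    dimnames(b) <- list(model_names, model_names)
    b
  })
  names(better) <- paste0("H", dims)
  structure(list(models = model_names, p_values = p_values,
                 observed = observed, ci_lower = ci_lower,
                 ci_upper = ci_upper, better = better,
                 threshold = threshold,
                 params = list(n_boot = n_boot, n_perm = n_perm,
                               max_dim = max_dim, alpha = alpha,
                               bonferroni = bonferroni),
                 seed = seed),
            class = "rta_adjudication")
}

#' @export
print.rta_adjudication <- function(x, ...) {
  cat(sprintf("Topological model adjudication (%d models, n_boot %d, n_perm %d, threshold %g)\n",
              length(x$models), x$params$n_boot, x$params$n_perm, x$threshold))
  for (dm in colnames(x$p_values)) {
    cat(sprintf(" %s:\n", dm))
    for (m in x$models)
      cat(sprintf("  %-12s p = %-8.4g CI = [%g, %g]\n", m,
                  x$p_values[m, dm], x$ci_lower[m, dm], x$ci_upper[m, dm]))
  }
  invisible(x)
}

#' Flatten an adjudication result to a data frame
#' @param x An `"rta_adjudication"`.
#' @param row.names,optional,... Ignored (data frame method signature).
#' @return One row per model and dimension with p-value and CI bounds.
#' @export
as.data.frame.rta_adjudication <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  dims <- colnames(x$p_values)
  do.call(rbind, lapply(dims, function(dm)
    data.frame(model = x$models, dimension = as.integer(sub("H", "", dm)),
               p_value = x$p_values[, dm], observed = x$observed[, dm],
               ci_lower = x$ci_lower[, dm], ci_upper = x$ci_upper[, dm],
               row.names = NULL)))
}

#' Write an adjudication report as JSON
#'
#' Per-model, per-dimension p-values, confidence bounds, observed
#' statistics, plus the run parameters and seed.
#'
#' @param x An `"rta_adjudication"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjudication <- function(x, path) {
  dims <- colnames(x$p_values)
  models <- lapply(seq_along(x$models), function(i) {
    per_dim <- lapply(dims, function(dm)
      list(p_value = x$p_values[i, dm], observed = x$observed[i, dm],
           ci = c(x$ci_lower[i, dm], x$ci_upper[i, dm])))
    names(per_dim) <- dims
    list(name = x$models[i], dimensions = per_dim)
  })
  jsonlite::write_json(list(models = models, threshold = x$threshold,
                            params = x$params, seed = x$seed),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
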