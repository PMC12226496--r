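
new_point_cloud <- function(coords, generator) {
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  structure(coords, generator = generator,
            class = c("point_cloud", "matrix", "array"))
}

#' @export
print.point_cloud <- function(x, ...) {
  g <- attr(x, "generator")
  cat(sprintf("Point cloud: %d points in %dD (shape '%s')\n",
              nrow(x), ncol(x), g$shape %||% "unknown"))
  invisible(x)
}

#' Sample points from a torus
#'
#' Points on the surface `((sqrt(x^2 + y^2) - R)^2 + z^2 = r^2)`.  The
#' default `"angle_uniform"` method draws both the major and minor angle
#' uniformly on `[0, 2*pi)`, which oversamples the inner rim relative to
#' surface area; `"area_uniform"` applies rejection sampling on the minor
#' angle (acceptance proportional to `R + r*cos(theta)`) to obtain the
#' uniform surface measure.
#'
#' @param n Number of points.
#' @param R Major (center-to-tube) radius; must exceed `r`.
#' @param r Minor (tube) radius.
#' @param seed Optional integer seed; generators are pure functions of
#'   (parameters, seed).
#' @param method `"angle_uniform"` (default) or `"area_uniform"`.
#' @return A 3D `"point_cloud"` with a provenance record in
#'   `attr(, "generator")`.
#' @export
sample_torus <- function(n, R = 2, r = 1, seed = NULL,
                         method = c("angle_uniform", "area_uniform")) {
  method <- match.arg(method)
  if (!is_count(n) || n < 1)
    rta_stop("n must be a positive integer", "rta_validation_error")
  if (!(R > r && r > 0))
    rta_stop("need R > r > 0 (otherwise the torus self-intersects)",
             "rta_validation_error")
  coords <- with_seed(seed, {
    u <- stats::runif(n, 0, 2 * pi)
    v <- if (method == "angle_uniform") {
      stats::runif(n, 0, 2 * pi)
    } else {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- stats::runif(2 * n, 0, 2 * pi)
        keep <- stats::runif(2 * n) < (R + r * cos(cand)) / (R + r)
        out <- c(out, cand[keep])
      }
      out[seq_len(n)]
    }
    cbind((R + r * cos(v)) * cos(u), (R + r * cos(v)) * sin(u), r * sin(v))
  })
  new_point_cloud(coords, list(shape = "torus", n = n, R = R, r = r,
                               seed = seed, method = method))
}

#' Project a torus point cloud onto the annulus below it
#'
#' Drops the third coordinate.  Planar radii lie in `[R - r, R + r]`, so
#' the projected cloud fills an annulus: the minor loop of the torus is
#' collapsed while the major loop survives.
#'
#' @param cloud A 3D `"point_cloud"`.
#' @return A 2D `"point_cloud"`.
#' @export
project_to_annulus <- function(cloud) {
  if (ncol(cloud) != 3)
    rta_stop("annulus projection needs a 3D point cloud", "rta_validation_error")
  g <- attr(cloud, "generator") %||% list()
  g$shape <- paste0("annulus_projection_of_", g$shape %||% "cloud")
  new_point_cloud(unclass(cloud)[, 1:2, drop = FALSE], g)
}

#' Sample a (noisy) circle
#'
#' Uniform angles on a circle of the given radius plus isotropic Gaussian
#' jitter.
#'
#' @param n Number of points.
#' @param radius Circle radius.
#' @param noise_sd Standard deviation of the 2D Gaussian jitter (0 places
#'   points exactly on the circle).
#' @param seed Optional integer seed.
#' @return A 2D `"point_cloud"`.
#' @export
sample_circle <- function(n, radius = 1, noise_sd = 0, seed = NULL) {
  if (!is_count(n) || n < 1)
    rta_stop("n must be a positive integer", "rta_validation_error")
  if (radius <= 0) rta_stop("radius must be positive", "rta_validation_error")
  coords <- with_seed(seed, {
    theta <- stats::runif(n, 0, 2 * pi)
    radius * cbind(cos(theta), sin(theta)) +
      matrix(stats::rnorm(2 * n, sd = noise_sd), n, 2)
  })
  new_point_cloud(coords, list(shape = "circle", n = n, radius = radius,
                               noise_sd = noise_sd, seed = seed))
}

#' Sample Gaussian clusters
#'
#' @param counts Integer vector: points per cluster.
#' @param centers Matrix of cluster centers, one row per cluster.
#' @param sd Isotropic standard deviation (scalar, or one per cluster).
#' @param seed Optional integer seed.
#' @return A `"point_cloud"` with `ncol(centers)` coordinates.
#' @export
sample_gaussian_clusters <- function(counts, centers, sd = 1, seed = NULL) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (length(counts) != k)
    rta_stop("length(counts) must equal nrow(centers)", "rta_validation_error")
  sd <- rep_len(sd, k)
  coords <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(k), function(i) {
      jit <- matrix(stats::rnorm(counts[i] * ncol(centers), sd = sd[i]),
                    counts[i], ncol(centers))
      sweep(jit, 2, centers[i, ], `+`)
    }))
  })
  new_point_cloud(coords, list(shape = "gaussian_clusters", counts = counts,
                               sd = sd, seed = seed))
}

#' Sample a punctured Gaussian cluster
#'
#' An isotropic 2D Gaussian with every point closer than `hole_radius` to
#' the center rejected: a cluster whose covariance barely changes but whose
#' topology becomes an annulus.
#'
#' @param n Number of points.
#' @param sd Standard deviation of the Gaussian.
#' @param hole_radius Radius of the central hole.
#' @param seed Optional integer seed.
#' @return A 2D `"point_cloud"` with no point within `hole_radius` of the
#'   origin.
#' @export
sample_punctured_gaussian <- function(n, sd = 1, hole_radius = 0.5,
                                      seed = NULL) {
  if (!is_count(n) || n < 1)
    rta_stop("n must be a positive integer", "rta_validation_error")
  if (hole_radius < 0) rta_stop("hole_radius must be nonnegative",
                                "rta_validation_error")
  # P(|X| >= h) = exp(-h^2 / (2 sd^2)) for an isotropic 2D Gaussian
  accept_prob <- exp(-hole_radius^2 / (2 * sd^2))
  if (accept_prob < 1e-6)
    rta_stop(sprintf("hole_radius %g leaves acceptance probability %g; no support left",
                     hole_radius, accept_prob), "rta_validation_error")
  coords <- with_seed(seed, {
    out <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(out) < n) {
      tries <- tries + 1
      if (tries > 1000)
        rta_stop("rejection sampling failed to fill the punctured cluster",
                 "rta_sampling_error")
      cand <- matrix(stats::rnorm(2 * n, sd = sd), n, 2)
      keep <- sqrt(rowSums(cand^2)) >= hole_radius
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  })
  new_point_cloud(coords, list(shape = "punctured_gaussian", n = n, sd = sd,
                               hole_radius = hole_radius, seed = seed))
}

#' Torus-versus-annulus simulation: where second-order correlation fails
#'
#' Samples `n` points from a torus, projects them onto the annulus below,
#' builds the Euclidean RDM of both clouds, and returns their second-order
#' Spearman correlation.  The two representational spaces have different
#' topologies (two independent loops versus one), yet their RDMs correlate
#' near 1 -- the motivating failure case for purely geometric RDM
#' comparison that topological analysis resolves.
#'
#' @param n Number of points (default 1000).
#' @param R,r Torus radii (defaults 2 and 1).
#' @param seed Optional integer seed.
#' @param method Torus sampling measure, see [sample_torus()].
#' @return List with `spearman`, `torus_rdm`, `annulus_rdm`, and the torus
#'   `cloud`.
#' @export
torus_annulus_experiment <- function(n = 1000, R = 2, r = 1, seed = NULL,
                                     method = c("angle_uniform",
                                                "area_uniform")) {
  cloud <- sample_torus(n, R, r, seed = seed, method = match.arg(method))
  flat <- project_to_annulus(cloud)
  torus_rdm <- rdm_from_points(unclass(cloud))
  annulus_rdm <- rdm_from_points(unclass(flat))
  list(spearman = spearman_rdm_cor(torus_rdm, annulus_rdm),
       torus_rdm = torus_rdm, annulus_rdm = annulus_rdm, cloud = cloud)
}

#' Write a point cloud as CSV with a JSON provenance sidecar
#'
#' @param cloud A `"point_cloud"`.
#' @param path Output CSV path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  utils::write.csv(as.data.frame(unclass(cloud)), path, row.names = FALSE)
  g <- attr(cloud, "generator")
  if (!is.null(g))
    jsonlite::write_json(g, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}
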