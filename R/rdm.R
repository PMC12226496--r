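#' Validate (and construct) a representational dissimilarity matrix
#'
#' An RDM is a square symmetric matrix of nonnegative dissimilarities with a
#' zero diagonal and at least three items.  `validate_rdm()` checks these
#' invariants, repairs tiny floating-point asymmetry by averaging with the
#' transpose, and attaches item labels.
#'
#' @param candidate A square numeric matrix.
#' @param items Optional character vector of item labels.  Defaults to the
#'   matrix rownames, or `"1" ... "n"` when absent.
#' @param asym_tol Largest absolute asymmetry, `max(|d - t(d)|)`, that is
#'   repaired by symmetrization rather than rejected.  Asymmetry above
#'   `1e-12` but within `asym_tol` is symmetrized with a warning; larger
#'   asymmetry is a validation error.
#'
#' @return A matrix of class `"rdm"` with items as dimnames.
#'
#' @details Validation failures signal conditions of class
#'   `"rta_validation_error"` naming the first offending cell.
#'
#' @examples
#' d <- as.matrix(dist(matrix(rnorm(12), 4)))
#' r <- validate_rdm(d)
#' @export
validate_rdm <- function(candidate, items = NULL, asym_tol = 1e-8) {
  d <- candidate
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d))
    rta_stop("RDM candidate must be a numeric matrix", "rta_validation_error")
  n <- nrow(d)
  if (ncol(d) != n)
    rta_stop(sprintf("RDM must be square; got %d x %d", n, ncol(d)),
             "rta_validation_error")
  if (n < 3L)
    rta_stop("an RDM needs at least 3 items", "rta_validation_error")
  if (anyNA(d) || any(!is.finite(d)))
    rta_stop("RDM entries must be finite and non-missing", "rta_validation_error")
  neg <- which(d < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    rta_stop(sprintf("negative dissimilarity at [%d, %d]: %g",
                     neg[1, 1], neg[1, 2], d[neg[1, 1], neg[1, 2]]),
             "rta_validation_error")
  bad_diag <- which(abs(diag(d)) > 1e-12)
  if (length(bad_diag) > 0)
    rta_stop(sprintf("nonzero diagonal at [%d, %d]: %g",
                     bad_diag[1], bad_diag[1], d[bad_diag[1], bad_diag[1]]),
             "rta_validation_error")
  asym <- max(abs(d - t(d)))
  if (asym > asym_tol)
    rta_stop(sprintf("matrix is asymmetric (max |d - t(d)| = %g)", asym),
             "rta_validation_error")
  if (asym > 1e-12) {
    warning(sprintf("symmetrizing RDM (asymmetry %g within tolerance %g)",
                    asym, asym_tol))
    d <- (d + t(d)) / 2
  }
  diag(d) <- 0
  items <- items %||% rownames(candidate) %||% as.character(seq_len(n))
  if (length(items) != n)
    rta_stop("length of item labels must equal the number of rows",
             "rta_validation_error")
  dimnames(d) <- list(items, items)
  class(d) <- c("rdm", "matrix", "array")
  d
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM with %d items; dissimilarities in [%g, %g]\n",
              nrow(x), min(x), max(x[upper.tri(x)])))
  invisible(x)
}

#' Item labels of an RDM
#' @param rdm An `"rdm"` object.
#' @return Character vector of item labels.
#' @export
rdm_items <- function(rdm) rownames(rdm) %||% as.character(seq_len(nrow(rdm)))

# strip the class for plain matrix arithmetic
rdm_matrix <- function(rdm) {
  d <- unclass(rdm)
  attr(d, "class") <- NULL
  d
}

#' Transform a correlation similarity matrix into an RDM
#'
#' Converts a matrix of correlations \eqn{\rho} between response patterns
#' into a dissimilarity matrix.  The default `"linear"` mode uses
#' \eqn{2(1-\rho)}, a rescaled correlation distance whose entries lie in
#' \eqn{[0, 4]}; the `"sqrt"` mode uses \eqn{\sqrt{2(1-\rho)}}, which is the
#' standard metric embedding of correlation dissimilarity (it satisfies the
#' triangle inequality, being the Euclidean distance between standardized
#' patterns).
#'
#' @param similarity Square symmetric matrix of correlations with unit
#'   diagonal and entries in `[-1, 1]`.
#' @param mode `"linear"` for \eqn{2(1-\rho)} (default) or `"sqrt"` for
#'   \eqn{\sqrt{2(1-\rho)}}.
#' @param items Optional item labels.
#' @return An `"rdm"` object with zero diagonal.
#' @examples
#' s <- diag(3)
#' s[s == 0] <- 0.5
#' cor_to_rdm(s)          # off-diagonals 2 * (1 - 0.5) = 1
#' cor_to_rdm(s, "sqrt")  # off-diagonals 1
#' @export
cor_to_rdm <- function(similarity, mode = c("linear", "sqrt"), items = NULL) {
  mode <- match.arg(mode)
  s <- similarity
  if (inherits(s, "dist")) s <- as.matrix(s)
  if (!is.matrix(s) || !is.numeric(s) || nrow(s) != ncol(s))
    rta_stop("similarity must be a square numeric matrix", "rta_validation_error")
  if (max(abs(s - t(s))) > 1e-8)
    rta_stop("similarity matrix is not symmetric", "rta_validation_error")
  if (any(abs(diag(s) - 1) > 1e-8))
    rta_stop("similarity diagonal must be 1 (self-correlation)",
             "rta_validation_error")
  out_of_range <- which(s < -1 - 1e-12 | s > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    i <- out_of_range[1, 1]; j <- out_of_range[1, 2]
    rta_stop(sprintf("correlation out of [-1, 1] at [%d, %d]: %g", i, j, s[i, j]),
             "rta_validation_error")
  }
  d <- 2 * (1 - s)
  d[d < 0] <- 0 # guard rounding at rho = 1
  if (mode == "sqrt") d <- sqrt(d)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  validate_rdm(d, items = items %||% rownames(s))
}

#' Build an RDM from a point cloud
#'
#' @param points Numeric matrix, one row per item.
#' @param metric `"euclidean"` for pairwise L2 distances, or `"correlation"`
#'   for [cor_to_rdm()] applied to the row-correlation matrix.
#' @param mode Transform mode passed to [cor_to_rdm()] when
#'   `metric = "correlation"`.
#' @param items Optional item labels.
#' @return An `"rdm"` object.
#' @examples
#' pts <- rbind(c(0, 0), c(3, 4), c(0, 1))
#' rdm_from_points(pts)["1", "2"] # 5: the 3-4-5 triangle
#' @export
rdm_from_points <- function(points, metric = c("euclidean", "correlation"),
                            mode = c("linear", "sqrt"), items = NULL) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    rta_stop("need at least 3 points", "rta_validation_error")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(points))
    dimnames(d) <- NULL
    return(validate_rdm(d, items = items %||% rownames(points)))
  }
  if (ncol(points) < 2L)
    rta_stop("correlation metric needs at least 2 coordinates per point",
             "rta_validation_error")
  sds <- apply(points, 1, stats::sd)
  if (any(sds == 0))
    rta_stop(sprintf("row %d is constant; correlation undefined",
                     which(sds == 0)[1]), "rta_validation_error")
  s <- stats::cor(t(points))
  cor_to_rdm(s, mode = match.arg(mode), items = items %||% rownames(points))
}

#' Second-order Spearman correlation between two RDMs
#'
#' The representational similarity analysis (RSA) baseline: Spearman rank
#' correlation over the `n(n-1)/2` lower-triangle entries of two RDMs with
#' identical item ordering.  Ties receive average ranks.
#'
#' @param a,b `"rdm"` objects (or square matrices) of identical size.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rdm_cor <- function(a, b) {
  a <- if (inherits(a, "rdm")) a else validate_rdm(a)
  b <- if (inherits(b, "rdm")) b else validate_rdm(b)
  if (nrow(a) != nrow(b))
    rta_stop(sprintf("RDM sizes differ: %d vs %d", nrow(a), nrow(b)),
             "rta_validation_error")
  x <- a[lower.tri(a)]
  y <- b[lower.tri(b)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    rta_stop("an RDM has constant off-diagonal entries; correlation undefined",
             "rta_undefined_correlation")
  stats::cor(x, y, method = "spearman")
}

#' Read an RDM from delimited text
#'
#' Accepts a square numeric block in CSV/TSV/whitespace-delimited form, with
#' an optional header row and leading label column.  Headerless files get
#' labels `"1" ... "n"`.
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) auto-detects tab, comma or
#'   whitespace from the first line.
#' @return An `"rdm"` object.
#' @export
read_rdm <- function(path, sep = NULL) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(c(0, which(nzchar(trimws(lines))))))]
  if (length(lines) == 0) rta_stop("empty RDM file", "rta_parse_error")
  if (is.null(sep)) {
    sep <- if (grepl("\t", lines[1])) "\t"
           else if (grepl(",", lines[1])) ","
           else "[[:space:]]+"
  }
  cells <- lapply(lines, function(l) {
    x <- strsplit(l, sep)[[1]]
    trimws(x)
  })
  widths <- lengths(cells)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    rta_stop(sprintf("ragged row at line %d: %d fields, expected %d",
                     bad, widths[bad], widths[1]), "rta_parse_error")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  header_row <- anyNA(num(cells[[1]][-1]))
  body <- if (header_row) cells[-1] else cells
  label_col <- length(body) > 0 && anyNA(num(vapply(body, `[`, "", 1)))
  items <- NULL
  if (header_row) {
    hdr <- cells[[1]]
    items <- if (widths[1] == length(body)) hdr else hdr[-1]
  }
  vals <- lapply(seq_along(body), function(i) {
    x <- body[[i]]
    if (label_col) x <- x[-1]
    v <- num(x)
    if (anyNA(v)) {
      line_no <- i + if (header_row) 1L else 0L
      rta_stop(sprintf("non-numeric cell at line %d: '%s'",
                       line_no, x[which(is.na(v))[1]]), "rta_parse_error")
    }
    v
  })
  if (label_col && is.null(items)) items <- vapply(body, `[`, "", 1)
  m <- do.call(rbind, vals)
  if (nrow(m) != ncol(m))
    rta_stop(sprintf("numeric block is %d rows x %d columns; RDM must be square",
                     nrow(m), ncol(m)), "rta_parse_error")
  validate_rdm(m, items = items)
}

#' Write an RDM as delimited text
#'
#' Writes a header row and leading label column; values keep 17 significant
#' digits so that a write/read round trip reproduces them to better than
#' `1e-12`.
#'
#' @param rdm An `"rdm"` object.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path, sep = ",") {
  rdm <- if (inherits(rdm, "rdm")) rdm else validate_rdm(rdm)
  items <- rdm_items(rdm)
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  lines <- c(paste(c("item", items), collapse = sep),
             vapply(seq_len(nrow(rdm)), function(i)
               paste(c(items[i], fmt(rdm[i, ])), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}
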