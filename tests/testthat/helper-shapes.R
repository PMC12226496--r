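# small geometric fixtures built in code

unit_square_rdm <- function() {
  rdm_from_points(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

equilateral_rdm <- function(s = 1) {
  validate_rdm(s * (1 - diag(3)))
}

even_circle_rdm <- function(k, radius = 1) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  rdm_from_points(radius * cbind(cos(th), sin(th)))
}

random_rdm <- function(n, scale = 1) {
  rdm_from_points(matrix(runif(n * 3, 0, scale), n, 3))
}
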