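`%||%` <- function(a, b) if (is.null(a)) b else a

# typed conditions so callers can distinguish validation failures from
# missing-feature lookups etc.
rta_stop <- function(msg, class = "rta_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rta_error")))
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream; seed = NULL uses the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# derive k reproducible sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, k)))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}
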