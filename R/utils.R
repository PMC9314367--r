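# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized", call. = FALSE)
  v / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run expr with a private RNG stream; global .Random.seed is restored on exit
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# djb2-style rolling hash over a deparsed object; stamps reports with a config id
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
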