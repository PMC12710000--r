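# Internal helpers: error conditions, RNG scoping, small vector utilities.

stop_with <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "rsaeval_error")))
}

stop_parse      <- function(msg, ...) stop_with("rsaeval_parse_error", msg, ...)
stop_validation <- function(msg, ...) stop_with("rsaeval_validation_error", msg, ...)
stop_parameter  <- function(msg, ...) stop_with("rsaeval_parameter_error", msg, ...)
stop_degenerate <- function(msg, ...) stop_with("rsaeval_degenerate_error", msg, ...)
stop_format     <- function(msg, ...) stop_with("rsaeval_format_error", msg, ...)
stop_undefined  <- function(msg, ...) stop_with("rsaeval_undefined_error", msg, ...)

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. `seed = NULL` uses the
# current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_parameter("seed must be a single finite number, got %s",
                   deparse(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop_degenerate("cannot normalize a zero vector")
  v / n
}

# Orthonormal basis completing unit vector t (columns t, u, v).
orthobasis <- function(t) {
  a <- if (abs(t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize(pracma_cross(a, t))
  v <- pracma_cross(t, u)
  cbind(t, u, v, deparse.level = 0L)
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
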