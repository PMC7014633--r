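# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL runs in the ambient RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Lexicographic comparison of two integer rank vectors (paths); a strict
# prefix sorts before its extensions.
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    d <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(d)) return(a[d[1L]] < b[d[1L]])
  }
  length(a) < length(b)
}

stop_vectorops <- function(..., class) {
  stop(structure(class = c(class, "vectorops_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_vectorops(name, " must be a single finite number",
                   class = "vectorops_validation_error")
  if (positive && x <= 0)
    stop_vectorops(name, " must be strictly positive",
                   class = "vectorops_validation_error")
  invisible(x)
}
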