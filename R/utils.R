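# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit so package functions never
#' perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Two independent polynomial rolling hashes of a string, mixed with a salt.
# Used to derive reproducible per-string RNG seeds; both hashes must collide
# before two distinct strings can share an embedding. Arithmetic stays below
# 2^31 via modular reduction at every step.
string_hashes <- function(text, salt = 0L) {
  mod <- 2147483629  # prime < 2^31
  codes <- utf8ToInt(text)
  h1 <- (salt %% mod + 17) %% mod
  h2 <- (salt %% mod + 911) %% mod
  for (c in codes) {
    h1 <- (h1 * 31 + c) %% mod
    h2 <- (h2 * 131 + c) %% mod
  }
  c(h1, h2)
}

# stable short hash of an arbitrary R object (used to fingerprint configs)
object_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- string_hashes(as.character(s), salt = 7L)
  sprintf("%08x%08x", h[1], h[2])
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
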