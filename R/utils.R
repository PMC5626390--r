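`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state on
#' exit, so seeded internals never perturb an enclosing simulation.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# derive a child seed below 2^31 from a master seed and a stage offset
child_seed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483647)

#' Canonical name of a treated-vs-reference contrast
#'
#' @param contrast character vector of length 2: `c(treated, reference)`.
#' @return A string of the form `"<treated>_vs_<reference>"`, the key under
#'   which precomputed p-value columns are stored.
#' @export
#' @examples
#' contrast_key(c("il15", "exvivo"))
contrast_key <- function(contrast) {
  stopifnot(is.character(contrast), length(contrast) == 2L)
  paste0(contrast[1L], "_vs_", contrast[2L])
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_input("'%s' must be a probability in [0, 1]", name)
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stop_input("'%s' must be a non-negative integer", name)
  }
  invisible(x)
}
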