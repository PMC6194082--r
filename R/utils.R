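# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards, so seeded operations never
#' perturb unrelated randomness. A `NULL` seed evaluates `code` as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic mapping so that every stochastic stage of a run receives its
#' own reproducible seed. Kept within the 32-bit signed integer range.
#'
#' @param master integer master seed.
#' @param offset small integer identifying the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(master, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(as.numeric(master)) * 7919 + as.numeric(offset)) %% 2147483587) + 1L
}

# consistent domain-error style: user-facing message, no call
stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("'%s' must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    stop_domain(sprintf("'%s' must be > %g", name, lower))
  }
  if (!strict_lower && x < lower) {
    stop_domain(sprintf("'%s' must be >= %g", name, lower))
  }
  if (x > upper) stop_domain(sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
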