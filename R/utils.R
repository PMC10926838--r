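# RNG plumbing: every stochastic entry point takes an integer seed and
# evaluates under it without clobbering the caller's RNG stream.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates \code{expr}, and restores
#' the previous state, so seeded package functions never perturb the caller's
#' random number stream. With \code{seed = NULL} the expression runs on the
#' current stream.
#'
#' @param seed Integer seed or \code{NULL}.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seed: one master seed spawns reproducible substreams
# regardless of evaluation order (kept below 2^31 - 1)
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
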