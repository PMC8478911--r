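#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# round half away from zero (classic pixel rounding, unlike R's round-half-even)
round_half_up <- function(x) floor(x + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_reefquad <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "reefquad_error")))
}
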