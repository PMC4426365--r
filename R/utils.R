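# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the Mersenne-Twister stream seeded at `seed`, then
#' restores the caller's RNG state, so simulations are bit-reproducible
#' without clobbering the session stream. A seed of 0 is valid.
#'
#' @param seed single non-negative integer.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported rate ranges use the
#' conventional half-up rule at a fixed number of decimals.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(0.305, 2)  # 0.31, where round() gives 0.30
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an epsilon scaled to x to defeat binary representation of .5
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# stop() with a class so tests can assert error categories
sdStop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
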