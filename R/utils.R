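# Internal helpers: classed conditions and seed derivation.

#' @noRd
tg_abort <- function(message, class) {
  stop(structure(
    class = c(class, "tggpp_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' @noRd
check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    tg_abort(sprintf("`%s` must be finite numeric, without NA.", name),
             "tggpp_error_invalid_input")
  }
  invisible(x)
}

# Derive a stream of child seeds from one master seed, all < 2^31.
# Deterministic and independent of the global RNG state.
#' @noRd
derive_seeds <- function(master, n) {
  a <- 1103515245; c <- 12345; m <- 2^31
  s <- as.numeric(master) %% m
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (a * s + c) %% m
    out[i] <- s
  }
  as.integer(out %% (m - 1)) + 1L
}

# Run `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so simulation calls do not clobber it.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2^31))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
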