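# internal helpers shared across the package

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's stream so simulation substreams do not perturb each other
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_infinite = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_infinite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "npbat_error_input")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(lower),
                  format(upper)),
          class = "npbat_error_input")
  }
  invisible(x)
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))

# draw substream seeds below 2^31 from the current stream
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)
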