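## Small internal helpers shared across modules.

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. All stochastic stages route their randomness
# through this so scenes, designs and ensembles are reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# One quantile convention for the whole package: linear interpolation
# (type 7), used by trimming, background subtraction and station processing.
lur_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

is_power_of_two <- function(n) {
  n == round(n) && n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
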