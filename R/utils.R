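#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG
# state. All exported stochastic functions route their draws through this.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
  } else {
    on.exit({
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# scalar checks used across the package
stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}

match_posture <- function(posture) {
  match.arg(posture, c("uncrossed", "crossed"))
}

match_side <- function(side) {
  match.arg(side, c("left", "right"))
}
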