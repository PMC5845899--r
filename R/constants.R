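# Attention instructions, triplet pattern versions and timbre morph distances
# used throughout the package. Order is meaningful: it defines the integer
# coding of the design factors in the hierarchical model.
ATTENTION_LEVELS <- c("bassoon", "cello", "aggregate")
TRIPLET_VERSIONS <- c("none", "upper", "lower", "crossing")
TIMBRE_LEVELS    <- c("maximum", "intermediate", "minimum")
RESPONSE_LEVELS  <- c("present", "absent", "missing")
OUTCOME_LEVELS   <- c("hit", "miss", "fa", "cr", "invalid")

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state. All generators in the package route their randomness
# through this helper so identical seeds give identical output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
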