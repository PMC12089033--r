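# Internal helpers: seed substreams and RNG hygiene.

# Named stage ids for substream derivation; keeping them fixed means a stage
# can be re-run in isolation and still see the draws it saw inside the full
# pipeline.
.mzn_stage <- c(input = 1L, calibrate = 2L, granular = 3L, stellate = 4L,
                networks = 5L, purkinje = 6L, nuclear = 7L, sweep = 8L)

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a (stage, index) pair onto a deterministic child
#' seed below 2^31, so that every stochastic stage of a run draws from its
#' own stream and stage order cannot change results.
#'
#' @param master Integer master seed.
#' @param stage Stage name (one of `"input"`, `"calibrate"`, `"granular"`,
#'   `"stellate"`, `"networks"`, `"purkinje"`, `"nuclear"`, `"sweep"`) or a
#'   small integer.
#' @param index Non-negative integer distinguishing units within a stage
#'   (e.g. the rank or field index).
#' @return A single integer seed.
#' @examples
#' mzn_substream(1, "input", 3)
#' @export
mzn_substream <- function(master, stage, index = 0L) {
  if (is.character(stage)) {
    stage <- .mzn_stage[[match.arg(stage, names(.mzn_stage))]]
  }
  m <- 2147483647
  s <- as.numeric(master) %% m
  # Two rounds of a multiplicative congruential mix; all intermediates stay
  # below 2^53 so double arithmetic is exact.
  s <- (s * 48271 + as.numeric(stage) * 8191) %% m
  s <- (s * 16807 + as.numeric(index) * 524287) %% m
  as.integer(s)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state
# afterwards so that package simulators do not perturb user-level draws.
# A NULL seed evaluates under the current RNG stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %s (got %s)",
                 name, min, deparse(x)), call. = FALSE)
  }
  as.integer(x)
}

.check_positive <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number (got %s)",
                 name, deparse(x)), call. = FALSE)
  }
  x
}
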