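# Internal helpers: seeded RNG scoping and deterministic sub-seed derivation.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. All stochastic entry points funnel through this.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a deterministic sub-seed for a pipeline stage
#'
#' Hashes a master seed together with a stage label into a reproducible
#' 31-bit sub-seed, so every stochastic stage of a run draws from an
#' independent, re-derivable stream.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return an integer in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, stage) {
  h <- as.numeric(as.integer(seed)) %% 2147483647
  for (k in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# distance-matrix validation used across modules
.checkDistanceMatrix <- function(d, name = "d") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(name, " must be square")
  if (max(abs(d - t(d))) > 1e-12) stop(name, " must be symmetric")
  if (any(diag(d) != 0)) stop(name, " must have a zero diagonal")
  if (any(d < 0)) stop(name, " must be non-negative")
  d
}

.relAbundance <- function(m) {
  # rows = samples; all-zero rows stay zero
  tot <- rowSums(m)
  sweep(m, 1, pmax(tot, 1), "/")
}

.asSampleMatrix <- function(x) {
  if (is(x, "MetacomExperiment")) sampleCounts(x) else as.matrix(x)
}
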