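# internal helpers shared across modules

# Counter-based substream seeding: one user-facing seed, a fixed offset per
# operation, so adding a generator never perturbs another generator's draws.
.op_offsets <- c(
  cohort = 11L, qpcr = 23L, depth = 37L, geno = 53L, pheno = 71L,
  pipeline = 97L
)

substream_seed <- function(seed, op) {
  stopifnot(op %in% names(.op_offsets))
  # keep derived seed well inside 32-bit integer range
  (as.integer(seed) %% 2000000L) * 1000L + .op_offsets[[op]]
}

with_substream <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, op))
  expr
}

# truncated normal by resampling; bounds are hard limits
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("mitocn_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
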