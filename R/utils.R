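# internal helpers shared across modules

# One root seed, independent named substreams per stage: substream seeds are
# drawn once from the root so adding a stage never perturbs the others.
substream_seeds <- function(seed, names) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# ISO-8601 local-clock formatting; timestamps are plain wall-clock times with
# no timezone arithmetic anywhere in the package.
format_iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_iso <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(gsub("T", " ", x), tz = "UTC")
}

hour_floor <- function(x) as.POSIXct(trunc(x, "hours"), tz = "UTC")

minute_floor <- function(x) as.POSIXct(trunc(x, "mins"), tz = "UTC")
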