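#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Symbol normalisation used by every reader: uppercase, strip surrounding
# whitespace. No alias mapping.
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

stop_if_duplicated <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0L) {
    stop(sprintf(
      "duplicate %s: %s", what,
      paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform draw from the integer range [lo, hi], safe for lo == hi
# (avoiding sample()'s scalar-argument surprise)
sample_int_range <- function(lo, hi, n) {
  vals <- seq.int(lo, hi)
  vals[sample.int(length(vals), n, replace = TRUE)]
}
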