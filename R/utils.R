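# Internal helpers shared across modules.

# Signal a classed warning so callers/tests can distinguish package warnings
# from incidental ones.
warn_antl <- function(msg, class = "antl_warning") {
  warning(warningCondition(msg, class = c(class, "antl_warning")))
}

stop_antl <- function(msg, class = "antl_error") {
  stop(errorCondition(msg, class = c(class, "antl_error")))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded subroutines do not perturb the global stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
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
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a base seed; stays within 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483629)
}

# Unique integer key per (row, col) on an h-row grid (column-major, like R
# matrix linear indices).
pix_key <- function(row, col, h) {
  (as.integer(col) - 1L) * as.integer(h) + as.integer(row)
}

# Row-major ordering key: sorts by row, then column. Used for deterministic
# tie-breaking.
rowmajor_key <- function(row, col, w) {
  (as.numeric(row) - 1) * as.numeric(w) + as.numeric(col)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == as.integer(x)
}
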