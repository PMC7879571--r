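# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for a named generator stream
#'
#' Each simulator draws from its own RNG stream, seeded by the master seed and
#' the stream name, so adding one generator never perturbs another's draws.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name.
#' @return An integer seed below 2^31.
#' @keywords internal
stream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  # small deterministic string hash, kept in 31-bit integer range
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1977326743
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under the RNG stream (seed, stream), restoring the caller's
# RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(expr)
}

# Stop unless all named columns are present.
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Lower Cholesky factor of a 2x2 covariance matrix, tolerating the PSD
# boundary (|r| = 1).
chol2x2 <- function(S) {
  l11 <- sqrt(S[1, 1])
  l21 <- if (l11 > 0) S[2, 1] / l11 else 0
  l22 <- sqrt(max(S[2, 2] - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2, 2)
}
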