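# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
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
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  expr
}

stop_value <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_value("`%s` must be a single number", name)
  if (x < lower || x > upper)
    stop_value("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

# Reflection (mirror, no edge duplication) index map from 1..n onto 1..n_out.
reflect_index <- function(n, n_out) {
  if (n == 1L) return(rep(1L, n_out))
  i <- 0:(n_out - 1L)
  period <- 2L * n - 2L
  m <- i %% period
  ifelse(m < n, m + 1L, 2L * n - 1L - m)
}

# Reflect-pad a matrix or H x W x C array to `nrow_out` x `ncol_out`.
reflect_pad <- function(x, nrow_out, ncol_out) {
  d <- dim(x)
  ri <- reflect_index(d[1L], nrow_out)
  ci <- reflect_index(d[2L], ncol_out)
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # argument order keeps dim()

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L

`%||%` <- function(a, b) if (is.null(a)) b else a
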