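# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage / per-dataset seed fan-out from a master seed.
# Stable under insertion of new stage names; result always in [1, 2^31 - 2].
derive_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 20011L
  as.integer((abs(as.numeric(seed)) %% 1e6 * 2011 + 104729 * h) %%
               2147483646) + 1L
}

assert_positive_int <- function(x, what, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else 1
  if (length(x) < 1 || any(!is.finite(x)) || any(x != round(x)) ||
      any(x < lo)) {
    stop(sprintf("`%s` must be %s integer(s)", what,
                 if (allow_zero) "non-negative" else "positive"),
         call. = FALSE)
  }
  invisible(x)
}

# Column-standardize a matrix to mean 0, sd 1 (sample sd).
standardize_cols <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  s <- sqrt(colSums(m^2) / (nrow(m) - 1))
  if (any(s == 0)) stop("cannot standardize a zero-variance column")
  sweep(m, 2, s, "/")
}

# Sign convention for component weights: the largest-magnitude entry of each
# column is positive. Makes the arbitrary ICA sign reproducible.
apply_sign_convention <- function(w) {
  for (j in seq_len(ncol(w))) {
    i <- which.max(abs(w[, j]))
    if (w[i, j] < 0) w[, j] <- -w[, j]
  }
  w
}
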