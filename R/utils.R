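#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded helpers do not perturb the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# circular delay: out[t] = x[t - k], indices wrapped. k may be negative
# (an advance). Used by both the generator and the lag scan so the planted
# and recovered lag share one convention.
circ_shift <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) x else c(x[(n - k + 1L):n], x[1:(n - k)])
}

# row skewness of a matrix (population moments)
row_skewness <- function(m) {
  mu <- rowMeans(m)
  cm <- m - mu
  s2 <- rowMeans(cm^2)
  rowMeans(cm^3) / (s2^1.5 + 1e-300)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
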