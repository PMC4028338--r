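# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower
  if (!ok) {
    stopf("'%s' must be a single %snumber >= %s", name,
          if (allow_inf) "" else "finite ", format(lower))
  }
  invisible(x)
}

# (1 - exp(-k * t)) / k with the k -> 0 limit handled.
phi_exp <- function(k, t) {
  if (k == 0) return(t)
  -expm1(-k * t) / k
}
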