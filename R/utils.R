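# Internal helpers: argument checking and convention-fallback logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_envdyn <- function(...) stop(sprintf(...), call. = FALSE)

warn_envdyn <- function(...) warning(sprintf(...), call. = FALSE)

# Convention fallbacks (degenerate pairs, capped components, loaded
# covariances) are reported through this hook so pipelines can log them
# without turning them into user-facing warnings.
log_envdyn <- function(...) {
  if (isTRUE(getOption("envdyn.verbose", FALSE)))
    message("[envdyn] ", sprintf(...))
  invisible(NULL)
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_envdyn("`%s` must be a numeric matrix", name)
  if (any(!is.finite(x)))
    stop_envdyn("`%s` contains non-finite values", name)
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower)
    stop_envdyn("`%s` must be a finite scalar >= %g", name, lower)
  invisible(x)
}

# Derive a stream of child seeds from one master seed, reproducibly and
# within the 32-bit integer range.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
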