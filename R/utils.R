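#' @keywords internal
"_PACKAGE"

# Parameter validation helpers. All user-facing constructors funnel through
# these so error messages are uniform.

abort_invalid <- function(msg) {
  stop(structure(
    class = c("autobilayer_invalid_parameter", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_invalid(sprintf("'%s' must not be NULL", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("'%s' must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    abort_invalid(sprintf("'%s' must be > %g (got %g)", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort_invalid(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  }
  if (x > upper) {
    abort_invalid(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  }
  invisible(x)
}

# Deterministic sub-seed derivation so that one user-supplied seed can drive
# several independent random draws without reusing the stream. Kept within
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2L)) {
    s <- (s * 48271) %% 2147483647
  }
  as.integer((s + as.double(k) * 2654435761) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}
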