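#' @keywords internal
"_PACKAGE"

# Shared internal helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mesoconn <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mesoconn_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mesoconn(name, " must be a single finite number", class = "invalid_spec")
  if (positive && x <= 0)
    stop_mesoconn(name, " must be positive", class = "invalid_spec")
  invisible(x)
}

# Upper-triangle (i < j) values of a square matrix, column-major order.
upper_tri_vec <- function(m) m[upper.tri(m)]

# Relabel module ids to 1..C in order of first appearance; ties in labels
# (any atomic type) are handled through match().
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}

# Deterministic sub-seed derivation from a master seed. Keeps results
# reproducible while letting stages draw independent streams. Values stay
# below 2^31 - 1 so they remain valid R integer seeds.
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` with the RNG seeded by `seed`, restoring the caller's RNG state
# afterwards so library code never clobbers a user's random stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
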