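# Classed conditions used across the package so callers (and the CLI) can map
# failure modes to exit codes without parsing messages.

abort_domain <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("axstab_domain_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_singular <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("axstab_singularity_error", "axstab_domain_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_format <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("axstab_format_error", "axstab_parse_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_parse <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("axstab_parse_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_usage <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("axstab_usage_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_io <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("axstab_io_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_domain("`seed` must be a single finite number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation so one pipeline seed governs many
# generator calls without correlated streams.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 7919L + as.integer(index) * 104729L) %% 2147483629L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
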