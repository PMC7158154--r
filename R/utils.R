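#' @keywords internal
"_PACKAGE"

## Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Structured condition helper: all package errors carry a subclass so callers
## (and the CLI) can dispatch on the failing stage.
bp_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "brickplot_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

bp_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "brickplot_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## Derive a stream-specific 32-bit seed from a master seed. Keeps every RNG
## consumer on its own reproducible stream.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
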