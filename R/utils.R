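# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state, then restore whatever state the
# caller had.  All user-facing randomness in the package funnels through this
# so that identical seeds give bit-identical results regardless of session
# history.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  force(code)
}

stop_rwenet <- function(msg, class, ...) {
  stop(structure(class = c(class, "rwenet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
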