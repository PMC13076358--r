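# RNG hygiene: package functions that take a `seed` argument set it locally
# and restore the caller's RNG state on exit.
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

# Euclidean distance between two coordinate rows
.edist <- function(a, b) sqrt(sum((a - b)^2))
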