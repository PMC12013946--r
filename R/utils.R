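# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Voxel-center physical coordinates (um) along one axis: n voxels, spacing d.
axis_coords <- function(n, d) (seq_len(n) - 0.5) * d

`%||%` <- function(a, b) if (is.null(a)) b else a
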