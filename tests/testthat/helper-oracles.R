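# Independent oracles used across tests.

# Brute-force 2D grayscale opening with the paraboloid structuring function
# b(dy, dx) = -(dy^2 + dx^2) / (2r) on the square support |dy|,|dx| <= r.
# Direct 2D min/max over all element offsets (no separability assumption) —
# the reference the production separable implementation must equal.
brute_opening <- function(plane, r) {
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  h <- (offs$dy^2 + offs$dx^2) / (2 * r)   # -b
  ny <- nrow(plane); nx <- ncol(plane)
  shift2 <- function(m, dy, dx, pad) {
    out <- matrix(pad, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy); xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys - dy, xs - dx] <- m[ys, xs]
    out
  }
  er <- matrix(Inf, ny, nx)
  for (i in seq_len(nrow(offs)))
    er <- pmin(er, shift2(plane, offs$dy[i], offs$dx[i], Inf) + h[i])
  di <- matrix(-Inf, ny, nx)
  for (i in seq_len(nrow(offs)))
    di <- pmax(di, shift2(er, -offs$dy[i], -offs$dx[i], -Inf) - h[i])
  di
}

# Exact two-sided rank-sum p-value for distinct observations, from full
# enumeration of the C(nx+ny, nx) equally likely rank assignments.
exact_ranksum_p <- function(nx, ny, W) {
  sums <- combn(nx + ny, nx, FUN = sum)
  min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
}

# A small noise-free two-channel nucleus, shared by several image tests.
quiet_sim <- function(seed = 1, ...) {
  generate_nucleus_stack(image_sim_params(noise_scale = 0, seed = seed, ...))
}
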