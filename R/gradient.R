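# Discrete gradient operators Dx, Dy: forward differences with replicate
# (Neumann) boundaries, and their literal matrix transposes. D^T D is then
# the standard 5-point Neumann Laplacian, and applying D then D^T to a
# constant image gives exactly zero.

grad_x <- function(v) {
  g <- v
  g[, -ncol(v)] <- v[, -1L] - v[, -ncol(v)]
  g[, ncol(v)] <- 0
  g
}

grad_y <- function(v) {
  g <- v
  g[-nrow(v), ] <- v[-1L, ] - v[-nrow(v), ]
  g[nrow(v), ] <- 0
  g
}

# Transposes: (Dx^T g)[, j] = g[, j-1] - g[, j], with the boundary columns
# carrying the one-sided terms (last column of g never contributes through
# Dx, so only its incoming difference survives).
grad_x_t <- function(g) {
  nc <- ncol(g)
  out <- matrix(0, nrow(g), nc)
  out[, 1L] <- -g[, 1L]
  if (nc > 2L) out[, 2:(nc - 1L)] <- g[, 1:(nc - 2L)] - g[, 2:(nc - 1L)]
  out[, nc] <- g[, nc - 1L]
  out
}

grad_y_t <- function(g) {
  nr <- nrow(g)
  out <- matrix(0, nr, ncol(g))
  out[1L, ] <- -g[1L, ]
  if (nr > 2L) out[2:(nr - 1L), ] <- g[1:(nr - 2L), ] - g[2:(nr - 1L), ]
  out[nr, ] <- g[nr - 1L, ]
  out
}
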