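# Internal helpers shared across modules.

# Round half away from zero (printed tables use this convention, unlike
# base round()'s round-half-even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Voxel-centre coordinate (mm) of 1-based index i at pitch p: (i - 0.5) * p.
voxel_centers <- function(n, pitch) (seq_len(n) - 0.5) * pitch

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Offsets (integer matrix, rows = dx,dy,dz) of a digital ball of radius r.
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Shift a 3-D array by integer offset (dx,dy,dz), padding with `fill`.
shift_array <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) {
      if (o >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- seq_len(d[k] - o) + o
    } else {
      if (-o >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] + o) - o
      dst[[k]] <- seq_len(d[k] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
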