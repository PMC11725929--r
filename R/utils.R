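# internal helpers

# Eq.-style hyperbolic saturation curve used by generator and calibration.
hyperbola <- function(po2, K, tauMax, tauFloor) {
  (tauMax - tauFloor) * (po2 / (K + po2)) + tauFloor
}

# k x k sliding-window sum (same size as input, truncated at the borders),
# via an integral image. Used for spatial photon pooling before fitting.
boxSum2D <- function(m, k) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(m)
  h <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  i1 <- pmax(seq_len(nr) - h - 1L, 0L) + 1L
  i2 <- pmin(seq_len(nr) + h, nr) + 1L
  j1 <- pmax(seq_len(nc) - h - 1L, 0L) + 1L
  j2 <- pmin(seq_len(nc) + h, nc) + 1L
  S[i2, j2] - S[i1, j2] - S[i2, j1] + S[i1, j1]
}

# derive a bounded child seed from a base seed and an index (stays < 2^31)
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 9973) %% 2147483629)
}
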