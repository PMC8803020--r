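# Independent brute-force spatial-domain oracles used to validate the
# FFT-based implementations. Deliberately direct (nested loops / explicit
# sums); only ever run on tiny grids.

conv_brute_1d <- function(a, k) {
  n <- length(a)
  m <- length(k)
  r <- (m - 1L) %/% 2L
  out <- numeric(n)
  for (x in seq_len(n)) {
    s <- 0
    for (i in -r:r) {
      xx <- x - i
      if (xx >= 1L && xx <= n) s <- s + a[xx] * k[i + r + 1L]
    }
    out[x] <- s
  }
  out
}

conv_brute_2d <- function(a, k) {
  d <- dim(a)
  dk <- dim(k)
  r <- (dk - 1L) %/% 2L
  out <- matrix(0, d[1], d[2])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    s <- 0
    for (i in -r[1]:r[1]) for (j in -r[2]:r[2]) {
      xx <- x - i; yy <- y - j
      if (xx >= 1L && xx <= d[1] && yy >= 1L && yy <= d[2])
        s <- s + a[xx, yy] * k[i + r[1] + 1L, j + r[2] + 1L]
    }
    out[x, y] <- s
  }
  out
}

conv_brute_3d <- function(a, k) {
  d <- dim(a)
  dk <- dim(k)
  r <- (dk - 1L) %/% 2L
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    s <- 0
    for (i in -r[1]:r[1]) for (j in -r[2]:r[2]) for (l in -r[3]:r[3]) {
      xx <- x - i; yy <- y - j; zz <- z - l
      if (xx >= 1L && xx <= d[1] && yy >= 1L && yy <= d[2] &&
          zz >= 1L && zz <= d[3])
        s <- s + a[xx, yy, zz] * k[i + r[1] + 1L, j + r[2] + 1L, l + r[3] + 1L]
    }
    out[x, y, z] <- s
  }
  out
}

# one Richardson-Lucy step evaluated with the brute-force convolutions
rl_step_brute_1d <- function(e, v, f, b) {
  den <- conv_brute_1d(e, f)
  den[den < 1e-12] <- 1
  e * conv_brute_1d(v / den, b)
}
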