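# Circular focal (moving-window) means via FFT convolution.
# Truncated windows at the edges: both the value field and an all-ones field
# are convolved with the disc mask, so each cell is divided by the number of
# in-grid cells its window actually covers.

fft_next_size <- function(n) {
  # next 5-smooth number >= n keeps fft fast
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

conv2_same <- function(x, kern) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- fft_next_size(nr + kr - 1L); pc <- fft_next_size(nc + kc - 1L)
  X <- matrix(0, pr, pc); X[1:nr, 1:nc] <- x
  K <- matrix(0, pr, pc); K[1:kr, 1:kc] <- kern
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L; c0 <- (kc - 1L) %/% 2L
  full[(r0 + 1L):(r0 + nr), (c0 + 1L):(c0 + nc)]
}

disc_mask <- function(radius_cells) {
  r <- floor(radius_cells)
  off <- -r:r
  d2 <- outer(off^2, off^2, "+")
  (d2 <= radius_cells^2) * 1
}

# mean over cells whose centres lie within radius_cells of each cell centre
focal_mean_mat <- function(values, radius_cells) {
  kern <- disc_mask(radius_cells)
  num <- conv2_same(values, kern)
  den <- conv2_same(matrix(1, nrow(values), ncol(values)), kern)
  num / pmax(den, .Machine$double.eps)
}
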