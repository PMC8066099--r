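# shared fixtures and independent oracles, built in code at test time

# small deterministic volume: smooth gradient + seeded noise, ellipsoid mask
tiny_volume <- function(n = 20, slices = 3, spacing = c(1, 1, 3), seed = 42) {
  withr::with_seed(seed, {
    ints <- array(0, c(n, n, slices))
    for (s in seq_len(slices))
      ints[, , s] <- outer(seq_len(n), seq_len(n), "+") * 2 +
        matrix(rnorm(n * n, sd = 3), n, n)
  })
  cx <- (seq_len(n) - (n + 1) / 2)
  mask2d <- outer(cx^2, cx^2, "+") <= (n / 3)^2
  mask <- array(rep(mask2d, slices), c(n, n, slices))
  volume_with_mask(ints + 100, spacing, mask)
}

# exhaustive pair-counting AUC (Mann-Whitney with the 1/2 tie convention)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# direct double-loop 2D convolution with edge replication (oracle for the
# FFT-based implementation; assumes a symmetric kernel)
direct_conv2d <- function(img, kernel) {
  kr <- (nrow(kernel) - 1) / 2
  kc <- (ncol(kernel) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      ii <- min(max(i + a, 1), nr)
      jj <- min(max(j + b, 1), nc)
      acc <- acc + img[ii, jj] * kernel[a + kr + 1, b + kc + 1]
    }
    out[i, j] <- acc
  }
  out
}

# single-slice volume wrapper around a matrix
slice_volume <- function(m, spacing = c(1, 1, 1), mask = NULL) {
  ints <- array(m, c(nrow(m), ncol(m), 1))
  if (is.null(mask)) mask <- array(TRUE, dim(ints))
  else mask <- array(mask, dim(ints))
  volume_with_mask(ints, spacing, mask)
}
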