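# Independent oracles used across the suite; all are brute-force scalar
# implementations kept free of the package's internal code paths.

# Dense forward pass as explicit per-node loops.
oracle_forward <- function(layer_sizes, theta, x, activation = "sigmoid") {
  act <- if (activation == "sigmoid") function(z) 1 / (1 + exp(-z)) else tanh
  pos <- 0
  a <- x
  for (l in seq_len(length(layer_sizes) - 1)) {
    n_in <- layer_sizes[l]
    n_out <- layer_sizes[l + 1]
    W <- matrix(theta[pos + seq_len(n_in * n_out)], n_in, n_out)
    pos <- pos + n_in * n_out
    b <- theta[pos + seq_len(n_out)]
    pos <- pos + n_out
    out <- numeric(n_out)
    for (j in seq_len(n_out)) {
      s <- b[j]
      for (i in seq_len(n_in)) s <- s + a[i] * W[i, j]
      out[j] <- act(s)
    }
    a <- out
  }
  a
}

# AUC as the Mann-Whitney pair statistic: P(pos > neg) + 0.5 P(pos == neg),
# by exhaustive pair enumeration.
oracle_auc <- function(values, positive) {
  vp <- values[positive]
  vn <- values[!positive]
  total <- 0
  for (p in vp) for (n in vn) total <- total + (p > n) + 0.5 * (p == n)
  total / (length(vp) * length(vn))
}

# Seeded random grayscale image.
random_image <- function(nr, nc = nr, max = 255) {
  matrix(runif(nr * nc, 0, max), nr, nc)
}

# A stack of constant-value slices.
const_stack <- function(value, n, side = 8, ...) {
  slice_stack(replicate(n, matrix(value, side, side), simplify = FALSE), ...)
}

# Linearly separable 2-D two-class dataset.
blob_dataset <- function(n = 100, sep = 3) {
  half <- n %/% 2
  X <- rbind(cbind(rnorm(half), rnorm(half)),
             cbind(rnorm(n - half) + sep, rnorm(n - half) + sep))
  pos <- rep(c(TRUE, FALSE), c(half, n - half))
  targets <- t(vapply(pos, function(p) if (p) c(1, 0) else c(0, 1), numeric(2)))
  structure(list(X = X, targets = targets, name = "blobs"),
            class = "ann_dataset")
}

blob_dataset_seeded <- function(n = 100, seed = 100) {
  set.seed(seed)
  blob_dataset(n)
}
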