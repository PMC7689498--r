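# Separable image resampling on plain matrices.
#
# Both resamplers are expressed as sparse-ish row/column weight matrices so
# that `out = Wr %*% img %*% t(Wc)`; this keeps them deterministic and easy
# to verify against brute-force per-pixel loops.

# Linear-interpolation weights mapping n_src pixels to n_dst, pixel-centre
# convention: centre of pixel i sits at i - 0.5 (1-based), edges clamped.
bilinear_weights <- function(n_src, n_dst) {
  W <- matrix(0, n_dst, n_src)
  pos <- ((seq_len(n_dst) - 0.5) * n_src / n_dst) - 0.5   # 0-based src position
  pos <- clamp(pos, 0, n_src - 1)
  lo <- floor(pos)
  frac <- pos - lo
  for (j in seq_len(n_dst)) {
    i <- lo[j] + 1
    if (frac[j] == 0 || i >= n_src) {
      W[j, min(i, n_src)] <- 1
    } else {
      W[j, i] <- 1 - frac[j]
      W[j, i + 1] <- frac[j]
    }
  }
  W
}

# Box-filter (area-average) weights: target cell j covers the source
# interval [ (j-1)*s, j*s ) with s = n_src/n_dst; each source pixel
# contributes its overlap fraction. Exact for arbitrary (non-integer) ratios.
area_weights <- function(n_src, n_dst) {
  W <- matrix(0, n_dst, n_src)
  s <- n_src / n_dst
  for (j in seq_len(n_dst)) {
    a <- (j - 1) * s
    b <- j * s
    i0 <- floor(a) + 1
    i1 <- ceiling(b)
    for (i in i0:min(i1, n_src)) {
      overlap <- min(b, i) - max(a, i - 1)
      if (overlap > 0) W[j, i] <- overlap / s
    }
  }
  W
}

resize_bilinear <- function(img, n_row, n_col = n_row) {
  bilinear_weights(nrow(img), n_row) %*% img %*% t(bilinear_weights(ncol(img), n_col))
}

resize_area <- function(img, n_row, n_col = n_row) {
  area_weights(nrow(img), n_row) %*% img %*% t(area_weights(ncol(img), n_col))
}
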