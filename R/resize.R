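# Minimal image resizing on plain matrices. Nearest-neighbour maps each
# target pixel center to the source pixel containing it (exact inverse of
# integer downsampling); bilinear interpolates at target pixel centers with
# edge clamping.

resize_nearest <- function(m, h, w) {
  m <- unclass(m)
  if (nrow(m) == h && ncol(m) == w) return(m)
  ri <- floor(((seq_len(h) - 0.5) * nrow(m)) / h) + 1
  ci <- floor(((seq_len(w) - 0.5) * ncol(m)) / w) + 1
  m[ri, ci, drop = FALSE]
}

resize_bilinear <- function(m, h, w) {
  m <- unclass(m)
  if (nrow(m) == h && ncol(m) == w) return(m)
  src_r <- (seq_len(h) - 0.5) * nrow(m) / h - 0.5
  src_c <- (seq_len(w) - 0.5) * ncol(m) / w - 0.5
  r0 <- pmin(pmax(floor(src_r), 0), nrow(m) - 1)
  c0 <- pmin(pmax(floor(src_c), 0), ncol(m) - 1)
  r1 <- pmin(r0 + 1, nrow(m) - 1)
  c1 <- pmin(c0 + 1, ncol(m) - 1)
  fr <- pmin(pmax(src_r - r0, 0), 1)
  fc <- pmin(pmax(src_c - c0, 0), 1)
  top <- m[r0 + 1, c0 + 1, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0 + 1, c1 + 1, drop = FALSE] * outer(1 - fr, fc)
  bot <- m[r1 + 1, c0 + 1, drop = FALSE] * outer(fr, 1 - fc) +
    m[r1 + 1, c1 + 1, drop = FALSE] * outer(fr, fc)
  top + bot
}
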