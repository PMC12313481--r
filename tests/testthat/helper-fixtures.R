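# Shared fixtures and independent oracles for the test suite.

# digital ball mask on an n^3 grid, radius in mm
ball_mask <- function(n = 24L, radius = 8, spacing = c(1, 1, 1),
                      center = NULL) {
  if (is.null(center)) center <- rep((n + 1) / 2, 3)
  x <- (seq_len(n) - center[1]) * spacing[1]
  y <- (seq_len(n) - center[2]) * spacing[2]
  z <- (seq_len(n) - center[3]) * spacing[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(as.integer(r2 <= radius^2), c(n, n, n))
}

# brute-force normalized Shannon entropy: explicit per-component loop in
# natural log, base-converted at the end (independent of the package path)
kh_oracle <- function(P, k = 3) {
  acc <- 0
  for (p in P) {
    if (p > 0) acc <- acc - p * log(p)
  }
  acc / log(k)
}

# brute-force AUC by exhaustive pair counting, ties counted 1/2
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force symmetric GLCM over the 13 3-D directions (distance 1) via
# explicit voxel loops — the independent oracle for glcm_matrix
glcm_oracle <- function(G, Ng) {
  d <- dim(G)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  M <- matrix(0, Ng, Ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    gi <- G[x, y, z]
    if (is.na(gi)) next
    for (k in seq_len(nrow(offs))) {
      xx <- x + offs[k, 1]; yy <- y + offs[k, 2]; zz <- z + offs[k, 3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
        next
      gj <- G[xx, yy, zz]
      if (!is.na(gj)) M[gi, gj] <- M[gi, gj] + 1
    }
  }
  M
}

# a small three-class phantom reused across tests
small_phantom <- function(noise_sd = 0, seed = 11L,
                          proportions = c(0.3, 0.3, 0.4)) {
  simulate_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L),
                                semi_axes = c(11, 10, 9),
                                class_proportions = proportions,
                                noise_sd = noise_sd, seed = seed))
}
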