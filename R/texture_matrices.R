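# Texture-matrix construction and features on discretized gray levels.
# Conventions: 3-D aggregation with the 13 unique direction offsets at
# distance 1; co-occurrence and run-length matrices are merged (summed)
# over directions before features are computed; gray levels are the bin
# indices 1..Ng from fixed-bin-width discretization.

eps_log <- 2.2e-16  # guard for 0*log(0) style terms

#' Discretize ROI intensities with a fixed bin width
#'
#' Bin index `floor((x - min)/bin_width) + 1`, anchored at the ROI minimum,
#' so adding a constant to the whole image leaves the discretized pattern
#' unchanged (bin edges travel with the data).
#'
#' @param vals numeric vector of ROI voxel intensities.
#' @param bin_width positive bin width (intensity units).
#' @return integer vector of gray levels 1..Ng, with attribute `Ng`.
#' @export
discretize_fixed_width <- function(vals, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  g <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  # guard the exact-maximum edge case is unnecessary with floor anchoring,
  # but a fully constant ROI still needs at least one level
  attr(g, "Ng") <- max(g)
  g
}

# gray-level volume: NA outside ROI, bin index inside
gray_volume <- function(vol, roi_idx, dims, bin_width) {
  g <- array(NA_integer_, dims)
  gl <- discretize_fixed_width(vol[roi_idx], bin_width)
  g[roi_idx] <- gl
  attr(g, "Ng") <- attr(gl, "Ng")
  g
}

# ---- GLCM ----------------------------------------------------------------

# symmetric co-occurrence matrix merged over the 13 unique 3-D directions
glcm_matrix <- function(G, Ng) {
  d <- dim(G)
  offs <- connectivity_offsets(26L, half = TRUE)
  counts <- numeric(Ng * Ng)
  roi <- which(!is.na(G))
  pos <- arrayInd(roi, d)
  gi <- G[roi]
  for (k in seq_len(nrow(offs))) {
    nb <- pos + matrix(offs[k, ], nrow(pos), 3, byrow = TRUE)
    okv <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
           nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- nb[okv, 1] + d[1] * (nb[okv, 2] - 1L) +
      d[1] * d[2] * (nb[okv, 3] - 1L)
    gj <- G[nb_lin]
    pair_ok <- !is.na(gj)
    a <- gi[okv][pair_ok]; b <- gj[pair_ok]
    if (!length(a)) next
    counts <- counts + tabulate(a + Ng * (b - 1L), nbins = Ng * Ng) +
      tabulate(b + Ng * (a - 1L), nbins = Ng * Ng)
  }
  matrix(counts, Ng, Ng)
}

glcm_features <- function(P) {
  Ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) P <- diag(1, Ng) / Ng else P <- P / tot
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sigx <- sqrt(sum((i - mux)^2 * P)); sigy <- sqrt(sum((j - muy)^2 * P))
  # diagonal (difference) and cross-diagonal (sum) distributions
  kd <- 0:(Ng - 1)
  pdiff <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * Ng)
  psum <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(kd * pdiff)
  HX <- -sum(px * log2(px + eps_log)); HY <- -sum(py * log2(py + eps_log))
  HXY <- max(0, -sum(P * log2(P + eps_log)))
  HXY1 <- -sum(P * log2(px[i] * py[j] + eps_log))
  HXY2 <- -sum(px[i] * py[j] * log2(px[i] * py[j] + eps_log))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  corr <- if (sigx * sigy > 0) (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1
  mcc <- if (Ng > 1) {
    Q <- matrix(0, Ng, Ng)
    nzx <- px > 0; nzy <- py > 0
    for (kk in which(nzy)) {
      w <- P[, kk] / py[kk]
      Q <- Q + outer(ifelse(nzx, P[, kk] / px, 0), w)
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  } else 1
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = max(0, -sum(pdiff * log2(pdiff + eps_log))),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / Ng^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum((P / pmax((i - j)^2, 1))[i != j]),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * psum),
    SumEntropy = max(0, -sum(psum * log2(psum + eps_log))),
    SumSquares = sum((i - mux)^2 * P))
}

# ---- GLRLM ---------------------------------------------------------------

# run-length matrix merged over 13 directions: R[g, l] = number of maximal
# runs of gray level g with length l
glrlm_matrix <- function(G, Ng) {
  d <- dim(G)
  roi <- which(!is.na(G))
  pos <- arrayInd(roi, d)
  g <- G[roi]
  offs <- connectivity_offsets(26L, half = TRUE)
  max_len <- max(d)
  R <- matrix(0, Ng, max_len)
  for (k in seq_len(nrow(offs))) {
    dvec <- offs[k, ]
    a <- which(dvec != 0)[1L]
    t <- pos[, a] * dvec[a]
    # line identifier: start-of-line coordinates
    l1 <- pos[, 1] - t * dvec[1]
    l2 <- pos[, 2] - t * dvec[2]
    l3 <- pos[, 3] - t * dvec[3]
    span <- max(d) * 3L
    key <- (l1 + span) + (2L * span) * ((l2 + span) +
             (2L * span) * (l3 + span))
    o <- order(key, t)
    kk <- key[o]; tt <- t[o]; gg <- g[o]
    n <- length(o)
    new_run <- c(TRUE, kk[-1] != kk[-n] | tt[-1] != tt[-n] + 1L |
                   gg[-1] != gg[-n])
    run_id <- cumsum(new_run)
    len <- tabulate(run_id)
    gray <- gg[new_run]
    R <- R + matrix(tabulate(gray + Ng * (pmin(len, max_len) - 1L),
                             nbins = Ng * max_len), Ng, max_len)
  }
  attr(R, "n_voxels") <- length(roi)
  attr(R, "n_directions") <- nrow(offs)
  R
}

glrlm_features <- function(R) {
  Ng <- nrow(R)
  lvl <- seq_len(Ng); len <- seq_len(ncol(R))
  Nr <- sum(R)
  Np <- attr(R, "n_voxels") * attr(R, "n_directions")
  p <- R / Nr
  rg <- rowSums(R); rl <- colSums(R)
  mu_g <- sum(lvl * rowSums(p)); mu_l <- sum(len * colSums(p))
  I2 <- outer(lvl^2, rep(1, ncol(R)))
  J2 <- outer(rep(1, Ng), len^2)
  c(ShortRunEmphasis = sum(R / J2) / Nr,
    LongRunEmphasis = sum(R * J2) / Nr,
    GrayLevelNonUniformity = sum(rg^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rg^2) / Nr^2,
    RunLengthNonUniformity = sum(rl^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / Nr^2,
    RunPercentage = Nr / Np,
    GrayLevelVariance = sum((outer(lvl, rep(1, ncol(R))) - mu_g)^2 * p),
    RunVariance = sum((outer(rep(1, Ng), len) - mu_l)^2 * p),
    RunEntropy = max(0, -sum(p * log2(p + eps_log))),
    LowGrayLevelRunEmphasis = sum(R / I2) / Nr,
    HighGrayLevelRunEmphasis = sum(R * I2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (I2 * J2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(R * I2 / J2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(R * J2 / I2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(R * I2 * J2) / Nr)
}

# ---- GLSZM ---------------------------------------------------------------

# size-zone matrix: zones are 26-connected components of constant gray level
glszm_matrix <- function(G, Ng) {
  d <- dim(G)
  roi <- which(!is.na(G))
  pos <- arrayInd(roi, d)
  g <- G[roi]
  key <- array(0L, d); key[roi] <- seq_along(roi)
  offs <- connectivity_offsets(26L, half = TRUE)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- pos + matrix(offs[k, ], nrow(pos), 3, byrow = TRUE)
    okv <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
           nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- nb[okv, 1] + d[1] * (nb[okv, 2] - 1L) +
      d[1] * d[2] * (nb[okv, 3] - 1L)
    nb_key <- key[nb_lin]
    same <- nb_key > 0L & G[nb_lin] == g[okv]
    same[is.na(same)] <- FALSE
    from <- c(from, which(okv)[same])
    to <- c(to, nb_key[same])
  }
  gr <- igraph::make_graph(rbind(from, to), n = length(roi), directed = FALSE)
  comp <- igraph::components(gr)$membership
  zone_size <- tabulate(comp)
  zone_gray <- g[match(seq_along(zone_size), comp)]
  max_size <- max(zone_size)
  Z <- matrix(tabulate(zone_gray + Ng * (zone_size - 1L),
                       nbins = Ng * max_size), Ng, max_size)
  attr(Z, "n_voxels") <- length(roi)
  Z
}

glszm_features <- function(Z) {
  Ng <- nrow(Z)
  lvl <- seq_len(Ng); sz <- seq_len(ncol(Z))
  Nz <- sum(Z)
  Np <- attr(Z, "n_voxels")
  p <- Z / Nz
  zg <- rowSums(Z); zs <- colSums(Z)
  mu_g <- sum(lvl * rowSums(p)); mu_s <- sum(sz * colSums(p))
  I2 <- outer(lvl^2, rep(1, ncol(Z)))
  J2 <- outer(rep(1, Ng), sz^2)
  c(SmallAreaEmphasis = sum(Z / J2) / Nz,
    LargeAreaEmphasis = sum(Z * J2) / Nz,
    GrayLevelNonUniformity = sum(zg^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(zg^2) / Nz^2,
    SizeZoneNonUniformity = sum(zs^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(zs^2) / Nz^2,
    ZonePercentage = Nz / Np,
    GrayLevelVariance = sum((outer(lvl, rep(1, ncol(Z))) - mu_g)^2 * p),
    ZoneVariance = sum((outer(rep(1, Ng), sz) - mu_s)^2 * p),
    ZoneEntropy = max(0, -sum(p * log2(p + eps_log))),
    LowGrayLevelZoneEmphasis = sum(Z / I2) / Nz,
    HighGrayLevelZoneEmphasis = sum(Z * I2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(Z / (I2 * J2)) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(Z * I2 / J2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(Z * J2 / I2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(Z * I2 * J2) / Nz)
}

# ---- GLDM ----------------------------------------------------------------

# dependence matrix: D[g, d] = voxels of gray g with dependence d, where
# dependence = 1 + number of 26-neighbours within the ROI whose gray level
# differs by at most alpha (default 0)
gldm_matrix <- function(G, Ng, alpha = 0L) {
  d <- dim(G)
  roi <- which(!is.na(G))
  pos <- arrayInd(roi, d)
  g <- G[roi]
  offs <- connectivity_offsets(26L, half = FALSE)
  dep <- rep(1L, length(roi))
  for (k in seq_len(nrow(offs))) {
    nb <- pos + matrix(offs[k, ], nrow(pos), 3, byrow = TRUE)
    okv <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
           nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- nb[okv, 1] + d[1] * (nb[okv, 2] - 1L) +
      d[1] * d[2] * (nb[okv, 3] - 1L)
    gj <- G[nb_lin]
    hit <- !is.na(gj) & abs(gj - g[okv]) <= alpha
    dep[which(okv)[hit]] <- dep[which(okv)[hit]] + 1L
  }
  max_dep <- max(dep)
  D <- matrix(tabulate(g + Ng * (dep - 1L), nbins = Ng * max_dep),
              Ng, max_dep)
  D
}

gldm_features <- function(D) {
  Ng <- nrow(D)
  lvl <- seq_len(Ng); dp <- seq_len(ncol(D))
  Nz <- sum(D)
  p <- D / Nz
  dg <- rowSums(D); dd <- colSums(D)
  mu_g <- sum(lvl * rowSums(p)); mu_d <- sum(dp * colSums(p))
  I2 <- outer(lvl^2, rep(1, ncol(D)))
  J2 <- outer(rep(1, Ng), dp^2)
  c(SmallDependenceEmphasis = sum(D / J2) / Nz,
    LargeDependenceEmphasis = sum(D * J2) / Nz,
    GrayLevelNonUniformity = sum(dg^2) / Nz,
    DependenceNonUniformity = sum(dd^2) / Nz,
    DependenceNonUniformityNormalized = sum(dd^2) / Nz^2,
    GrayLevelVariance = sum((outer(lvl, rep(1, ncol(D))) - mu_g)^2 * p),
    DependenceVariance = sum((outer(rep(1, Ng), dp) - mu_d)^2 * p),
    DependenceEntropy = max(0, -sum(p * log2(p + eps_log))),
    LowGrayLevelEmphasis = sum(D / I2) / Nz,
    HighGrayLevelEmphasis = sum(D * I2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(D / (I2 * J2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(D * I2 / J2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(D * J2 / I2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(D * I2 * J2) / Nz)
}
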