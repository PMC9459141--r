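# Independent brute-force reference implementations used as oracles. These
# deliberately use naive exhaustive loops, never the package's vectorized
# shift/circulant machinery.

# all 26 neighbor offsets
oracle_offsets26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

wrap1 <- function(i, n) ((i - 1) %% n) + 1

# circular correlation y[n] = sum_k h[k] x[wrap(n + k - 1)] along all 3 axes
oracle_wavelet_band <- function(vol, letters, filters) {
  d <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    h <- if (substr(letters, ax, ax) == "L") filters$lo else filters$hi
    src <- out
    out <- array(0, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      acc <- 0
      for (t in seq_along(h)) {
        idx <- c(i, j, k)
        idx[ax] <- wrap1(idx[ax] + t - 1, d[ax])
        acc <- acc + h[t] * src[idx[1], idx[2], idx[3]]
      }
      out[i, j, k] <- acc
    }
  }
  out
}

oracle_haar <- function() list(lo = c(1, 1) / sqrt(2),
                               hi = c(1, -1) / sqrt(2))

# exhaustive pair-enumeration GLCM over the 13 half-directions, symmetric
oracle_glcm <- function(levels, mask) {
  d <- dim(levels)
  ng <- max(levels[mask], na.rm = TRUE)
  offs <- oracle_offsets26()
  # half set: lexicographically positive
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  per_dir <- list()
  for (o in seq_len(nrow(offs))) {
    counts <- matrix(0, ng, ng)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (!mask[i, j, k] || !mask[ii, jj, kk]) next
      a <- levels[i, j, k]; b <- levels[ii, jj, kk]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
    if (sum(counts) > 0) per_dir[[length(per_dir) + 1]] <- counts / sum(counts)
  }
  feats <- sapply(per_dir, function(p) {
    lev <- seq_len(ng)
    px <- rowSums(p); py <- colSums(p)
    mux <- sum(lev * px); muy <- sum(lev * py)
    sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
    cp <- cs <- 0
    for (a in lev) for (b in lev) {
      cp <- cp + (a + b - mux - muy)^4 * p[a, b]
      cs <- cs + (a + b - mux - muy)^3 * p[a, b]
    }
    corr <- if (sx * sy == 0) 1 else {
      acc <- 0
      for (a in lev) for (b in lev) acc <- acc + a * b * p[a, b]
      (acc - mux * muy) / (sx * sy)
    }
    c(ClusterProminence = cp, ClusterShade = cs, Correlation = corr)
  })
  rowMeans(feats)
}

# BFS flood-fill zone labelling; returns data.frame(level, size)
oracle_zones <- function(levels, mask, connectivity = 26) {
  d <- dim(levels)
  offs <- oracle_offsets26()
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  seen <- array(FALSE, d)
  zones <- list()
  coords <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    start <- coords[r, ]
    if (seen[start[1], start[2], start[3]]) next
    lev <- levels[start[1], start[2], start[3]]
    queue <- list(start)
    seen[start[1], start[2], start[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        if (seen[nb[1], nb[2], nb[3]] || !mask[nb[1], nb[2], nb[3]]) next
        if (levels[nb[1], nb[2], nb[3]] != lev) next
        seen[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
    zones[[length(zones) + 1]] <- c(level = lev, size = size)
  }
  as.data.frame(do.call(rbind, zones))
}

oracle_glszm <- function(levels, mask, connectivity = 26) {
  z <- oracle_zones(levels, mask, connectivity)
  nz <- nrow(z)
  p_is <- table(z$level, z$size) / nz
  p_is <- p_is[p_is > 0]
  c(ZoneEntropy = -sum(p_is * log2(p_is)),
    GrayLevelNonUniformity = sum(table(z$level)^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(z$level^2 * z$size^2) / nz,
    SizeZoneNonUniformityNormalized = sum(table(z$size)^2) / nz^2,
    SmallAreaHighGrayLevelEmphasis = sum(z$level^2 / z$size^2) / nz)
}

oracle_gldm <- function(levels, mask, alpha = 0) {
  d <- dim(levels)
  offs <- oracle_offsets26()
  coords <- which(mask, arr.ind = TRUE)
  acc <- 0
  for (r in seq_len(nrow(coords))) {
    v <- coords[r, ]
    lev <- levels[v[1], v[2], v[3]]
    dep <- 1
    for (o in seq_len(nrow(offs))) {
      nb <- v + offs[o, ]
      if (any(nb < 1) || any(nb > d)) next
      if (!mask[nb[1], nb[2], nb[3]]) next
      if (abs(levels[nb[1], nb[2], nb[3]] - lev) <= alpha) dep <- dep + 1
    }
    acc <- acc + dep^2 / lev^2
  }
  acc / nrow(coords)
}

oracle_skewness <- function(x) {
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) return(0)
  mean((x - mu)^3) / m2^1.5
}

# concordant-pair AUC (ties half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (n in neg) {
    acc <- acc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}

# random small masked grid guaranteed to contain adjacent masked voxels
random_grid <- function(seed, max_extent = 5, n_levels = 6) {
  set.seed(seed)
  d <- sample(3:max_extent, 3, replace = TRUE)
  vol <- array(runif(prod(d), 0, 60), d)
  if (seed %% 2 == 0) {
    mask <- array(TRUE, d)
  } else {
    mask <- array(runif(prod(d)) < 0.8, d)
    mask[1:2, 1, 1] <- TRUE
  }
  list(vol = vol, mask = mask, dim = d)
}
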