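# Independent brute-force oracles for the texture families. Written as
# naive elementwise loops straight from the definitions, deliberately
# sharing no code with the package implementation.

oracle_offsets <- list(`0` = c(0, 1), `45` = c(1, 1),
                       `90` = c(1, 0), `135` = c(1, -1))

# GLCM: enumerate every in-mask pixel pair at each offset, count both
# orderings (symmetrization), normalize, compute the five features.
oracle_glcm <- function(lv, n_levels, angles = c(0, 45, 90, 135)) {
  nr <- nrow(lv); nc <- ncol(lv)
  per_angle <- list()
  for (a in as.character(angles)) {
    off <- oracle_offsets[[a]]
    C <- matrix(0, n_levels, n_levels)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      v1 <- lv[i, j]; v2 <- lv[i2, j2]
      if (is.na(v1) || is.na(v2)) next
      C[v1 + 1, v2 + 1] <- C[v1 + 1, v2 + 1] + 1
      C[v2 + 1, v1 + 1] <- C[v2 + 1, v1 + 1] + 1
    }
    if (sum(C) == 0) next
    p <- C / sum(C)
    contrast <- 0; energy <- 0; homog <- 0; entropy <- 0; xy <- 0
    mi <- 0; mj <- 0
    for (u in seq_len(n_levels)) for (v in seq_len(n_levels)) {
      pij <- p[u, v]
      contrast <- contrast + pij * (u - v)^2
      energy <- energy + pij^2
      homog <- homog + pij / (1 + (u - v)^2)
      if (pij > 0) entropy <- entropy - pij * log2(pij)
      mi <- mi + (u - 1) * pij
      mj <- mj + (v - 1) * pij
      xy <- xy + (u - 1) * (v - 1) * pij
    }
    vi <- 0; vj <- 0
    for (u in seq_len(n_levels)) {
      vi <- vi + (u - 1 - mi)^2 * sum(p[u, ])
      vj <- vj + (u - 1 - mj)^2 * sum(p[, u])
    }
    corr <- if (vi <= 0 || vj <= 0) 0 else (xy - mi * mj) / sqrt(vi * vj)
    per_angle[[a]] <- c(contrast = contrast, correlation = corr,
                        energy = energy, homogeneity = homog,
                        entropy = entropy)
  }
  Reduce(`+`, per_angle) / length(per_angle)
}

# GLRL: walk every line of every direction, splitting runs at NA (mask
# boundary), count maximal runs into a matrix, compute the 11 features.
oracle_glrl <- function(lv, n_levels, directions = c(0, 45, 90, 135)) {
  nr <- nrow(lv); nc <- ncol(lv)
  n_pixels <- sum(!is.na(lv))
  starts_for <- function(off) {
    s <- list()
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ip <- i - off[1]; jp <- j - off[2]
      inside <- ip >= 1 && ip <= nr && jp >= 1 && jp <= nc
      if (!inside) s[[length(s) + 1]] <- c(i, j)
    }
    s
  }
  per_dir <- list()
  for (a in as.character(directions)) {
    off <- oracle_offsets[[a]]
    P <- matrix(0, n_levels, max(nr, nc))
    for (st in starts_for(off)) {
      i <- st[1]; j <- st[2]
      cur <- NA; len <- 0
      while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
        v <- lv[i, j]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1
        } else {
          if (!is.na(cur)) P[cur + 1, len] <- P[cur + 1, len] + 1
          cur <- v; len <- 1
        }
        i <- i + off[1]; j <- j + off[2]
      }
      if (!is.na(cur)) P[cur + 1, len] <- P[cur + 1, len] + 1
    }
    Nr <- sum(P)
    f <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0, RP = 0, LGRE = 0, HGRE = 0,
           SRLGE = 0, SRHGE = 0, LRLGE = 0, LRHGE = 0)
    for (g in seq_len(nrow(P))) for (l in seq_len(ncol(P))) {
      pij <- P[g, l]
      if (pij == 0) next
      f["SRE"] <- f["SRE"] + pij / l^2
      f["LRE"] <- f["LRE"] + pij * l^2
      f["LGRE"] <- f["LGRE"] + pij / g^2
      f["HGRE"] <- f["HGRE"] + pij * g^2
      f["SRLGE"] <- f["SRLGE"] + pij / (g^2 * l^2)
      f["SRHGE"] <- f["SRHGE"] + pij * g^2 / l^2
      f["LRLGE"] <- f["LRLGE"] + pij * l^2 / g^2
      f["LRHGE"] <- f["LRHGE"] + pij * g^2 * l^2
    }
    for (g in seq_len(nrow(P))) f["GLN"] <- f["GLN"] + sum(P[g, ])^2
    for (l in seq_len(ncol(P))) f["RLN"] <- f["RLN"] + sum(P[, l])^2
    f <- f / Nr
    f["RP"] <- Nr / n_pixels
    per_dir[[a]] <- f
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

# GLGM: per-voxel central-difference gradient magnitude at voxels whose
# four neighbours are in-mask; population moments of the magnitudes.
oracle_glgm <- function(x, mask, spacing = c(1, 1)) {
  nr <- nrow(x); nc <- ncol(x)
  g <- c()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i <= 1 || i >= nr || j <= 1 || j >= nc) next
    if (!mask[i, j] || !mask[i - 1, j] || !mask[i + 1, j] ||
        !mask[i, j - 1] || !mask[i, j + 1]) next
    gr <- (x[i + 1, j] - x[i - 1, j]) / (2 * spacing[1])
    gc <- (x[i, j + 1] - x[i, j - 1]) / (2 * spacing[2])
    g <- c(g, sqrt(gr^2 + gc^2))
  }
  if (!length(g)) return(NULL)
  m <- mean(g); m2 <- mean((g - m)^2)
  c(MGR = m, VGR = m2,
    skewness = if (m2 == 0) 0 else mean((g - m)^3) / m2^1.5,
    kurtosis = if (m2 == 0) 0 else mean((g - m)^4) / m2^2)
}

# Laws: direct 3x3 cross-correlation of the mean-centred ROI with each
# outer-product kernel, at voxels with full 3x3 in-mask support.
oracle_laws <- function(x, mask) {
  base <- list(L3 = c(1, 2, 1), E3 = c(-1, 0, 1), S3 = c(-1, 2, -1))
  nr <- nrow(x); nc <- ncol(x)
  xm <- x - mean(x[mask])
  out <- c()
  for (a in names(base)) for (b in names(base)) {
    resp <- c()
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (i <= 1 || i >= nr || j <= 1 || j >= nc) next
      ok <- TRUE
      for (u in -1:1) for (v in -1:1) if (!mask[i + u, j + v]) ok <- FALSE
      if (!ok) next
      acc <- 0
      for (u in -1:1) for (v in -1:1)
        acc <- acc + base[[b]][u + 2] * base[[a]][v + 2] * xm[i + u, j + v]
      resp <- c(resp, abs(acc))
    }
    if (!length(resp)) return(NULL)
    out[paste0(a, b)] <- mean(resp)
  }
  out
}

# Maximum pairwise in-plane distance between voxel centres, exhaustively.
oracle_diameter <- function(mask, spacing) {
  best <- 0
  for (z in seq_len(dim(mask)[3])) {
    idx <- which(mask[, , z], arr.ind = TRUE)
    if (nrow(idx) < 2) next
    for (a in seq_len(nrow(idx) - 1)) for (b in seq.int(a + 1, nrow(idx))) {
      d <- sqrt(((idx[a, 1] - idx[b, 1]) * spacing[1])^2 +
                ((idx[a, 2] - idx[b, 2]) * spacing[2])^2)
      best <- max(best, d)
    }
  }
  best
}

# Random masked test image: levels in 0..(n_levels-1), mask with a guaranteed
# minimum of in-mask pixels.
random_level_image <- function(nr, nc, n_levels, p_mask = 0.85) {
  lv <- matrix(sample.int(n_levels, nr * nc, replace = TRUE) - 1L, nr, nc)
  repeat {
    mask <- matrix(stats::runif(nr * nc) < p_mask, nr, nc)
    if (sum(mask) >= max(4, 0.3 * nr * nc)) break
  }
  lv[!mask] <- NA_integer_
  list(levels = lv, mask = mask)
}

tiny_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(32L, 32L, 3L), voxel_size_mm = c(1, 1, 3),
         energies_keV = c(40, 60, 80), nodule_axes_mm = c(6, 10)),
    list(...))
  do.call(phantom_config, args)
}
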