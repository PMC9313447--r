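# Naive reference implementations of the radiomics features: plain nested
# loops and base-R primitives, no vectorized shortcuts shared with the
# package implementation. Used as the independent oracle for the
# feature-equivalence tests.

oracle_discretize <- function(x, mode = "fixed-bin-count", value = 32) {
  n <- length(x)
  bins <- integer(n)
  if (mode == "fixed-bin-count") {
    nb <- as.integer(value)
    mn <- min(x); mx <- max(x)
    if (mx <= mn) return(structure(rep(1L, n), nlevels = nb))
    w <- (mx - mn) / nb
    for (i in seq_len(n)) {
      b <- 1L + as.integer(floor((x[i] - mn) / w))
      bins[i] <- min(b, nb)
    }
    structure(bins, nlevels = nb)
  } else {
    w <- value
    shift <- floor(min(x) / w)
    for (i in seq_len(n)) bins[i] <- as.integer(floor(x[i] / w) - shift) + 1L
    structure(bins, nlevels = max(bins))
  }
}

oracle_first_order <- function(x, disc_mode = "fixed-bin-count", disc_value = 32,
                               spacing = c(1, 1, 1)) {
  n <- length(x)
  voxvol <- prod(spacing)
  bins <- oracle_discretize(x, disc_mode, disc_value)
  p <- as.numeric(table(factor(bins, levels = seq_len(attr(bins, "nlevels"))))) / n
  p <- p[p > 0]
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  q <- unname(quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), type = 7))
  robust <- x[x >= q[1] & x <= q[5]]
  c(
    "10Percentile" = q[1],
    "90Percentile" = q[5],
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    InterquartileRange = q[4] - q[2],
    Kurtosis = if (m2 > 0) (sum((x - m)^4) / n) / m2^2 else 0,
    Maximum = max(x),
    MeanAbsoluteDeviation = sum(abs(x - m)) / n,
    Mean = m,
    Median = q[3],
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation =
      if (length(robust) > 0) sum(abs(robust - mean(robust))) / length(robust) else 0,
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) (sum((x - m)^3) / n) / m2^1.5 else 0,
    TotalEnergy = voxvol * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2
  )
}

# ---- GLCM ------------------------------------------------------------------

oracle_glcm_matrix <- function(binvol, dir, nlevels, symmetric = TRUE) {
  d <- dim(binvol)
  cnt <- matrix(0, nlevels, nlevels)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    b1 <- binvol[x, y, z]
    if (b1 == 0) next
    x2 <- x + dir[1]; y2 <- y + dir[2]; z2 <- z + dir[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    b2 <- binvol[x2, y2, z2]
    if (b2 == 0) next
    cnt[b1, b2] <- cnt[b1, b2] + 1
    if (symmetric) cnt[b2, b1] <- cnt[b2, b1] + 1
  }
  cnt
}

oracle_glcm_features_one <- function(cnt, ng) {
  p <- cnt / sum(cnt)
  px <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + p[i, j]
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  psum <- rep(0, 2 * ng - 1)
  pdiff <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  lg <- function(v) ifelse(v > 0, log2(v), 0)
  autoc <- prom <- shade <- tend <- contrast <- jenergy <- jentropy <- 0
  idm <- idmn <- idf <- idn <- invvar <- sumsq <- hxy1 <- hxy2 <- 0
  maxp <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    spread <- i + j - 2 * mu
    dd <- i - j
    if (pij > 0) {
      autoc <- autoc + pij * i * j
      prom <- prom + pij * spread^4
      shade <- shade + pij * spread^3
      tend <- tend + pij * spread^2
      contrast <- contrast + pij * dd^2
      jenergy <- jenergy + pij^2
      jentropy <- jentropy - pij * log2(pij)
      idm <- idm + pij / (1 + dd^2)
      idmn <- idmn + pij / (1 + dd^2 / ng^2)
      idf <- idf + pij / (1 + abs(dd))
      idn <- idn + pij / (1 + abs(dd) / ng)
      if (i != j) invvar <- invvar + pij / dd^2
      maxp <- max(maxp, pij)
      sumsq <- sumsq + pij * (i - mu)^2
      hxy1 <- hxy1 - pij * lg(px[i] * px[j])
    }
    if (px[i] * px[j] > 0) hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])
  }
  hx <- 0
  for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  davg <- 0
  for (k in 1:ng) davg <- davg + (k - 1) * pdiff[k]
  dent <- dvar <- 0
  for (k in 1:ng) {
    if (pdiff[k] > 0) dent <- dent - pdiff[k] * log2(pdiff[k])
    dvar <- dvar + pdiff[k] * (k - 1 - davg)^2
  }
  sent <- 0
  for (k in seq_along(psum)) if (psum[k] > 0) sent <- sent - psum[k] * log2(psum[k])
  imc2 <- 1 - exp(-2 * (hxy2 - jentropy))
  imc2 <- min(sqrt(max(imc2, 0)), 1)
  c(
    Autocorrelation = autoc, JointAverage = mu, ClusterProminence = prom,
    ClusterShade = shade, ClusterTendency = tend, Contrast = contrast,
    Correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    DifferenceAverage = davg, DifferenceEntropy = dent, DifferenceVariance = dvar,
    JointEnergy = jenergy, JointEntropy = jentropy,
    Imc1 = if (hx > 0) (jentropy - hxy1) / hx else 0,
    Imc2 = imc2, Idm = idm, Idmn = idmn, Id = idf, Idn = idn,
    InverseVariance = invvar, MaximumProbability = maxp,
    SumEntropy = sent, SumSquares = sumsq
  )
}

oracle_glcm <- function(volume, mask, disc_mode = "fixed-bin-count",
                        disc_value = 32, distance = 1, symmetric = TRUE) {
  idx <- which(mask != 0)
  bins <- oracle_discretize(volume[idx], disc_mode, disc_value)
  ng <- attr(bins, "nlevels")
  binvol <- array(0L, dim(volume))
  binvol[idx] <- bins
  dirs <- htradiomics::glcm_directions(distance)
  acc <- NULL
  nd <- 0
  for (k in seq_len(nrow(dirs))) {
    cnt <- oracle_glcm_matrix(binvol, dirs[k, ], ng, symmetric)
    if (sum(cnt) == 0) next
    f <- oracle_glcm_features_one(cnt, ng)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# ---- shape -----------------------------------------------------------------

# same constants as the implementation: these are definition parameters of
# the feature (Gaussian anti-aliasing sigma/radius, iso level), not tuning
ORACLE_SIGMA <- 0.8
ORACLE_RADIUS <- 3L
ORACLE_LEVEL <- 0.5

oracle_smooth <- function(f) {
  w <- exp(-0.5 * (0:ORACLE_RADIUS)^2 / ORACLE_SIGMA^2)
  w <- w / (w[1] + 2 * sum(w[-1]))
  d <- dim(f)
  for (ax in 1:3) {
    out <- array(0, d)
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      pos <- c(x, y, z)
      acc <- w[1] * f[x, y, z]
      for (k in 1:ORACLE_RADIUS) {
        lo <- pos; lo[ax] <- lo[ax] - k
        hi <- pos; hi[ax] <- hi[ax] + k
        if (lo[ax] >= 1) acc <- acc + w[k + 1] * f[lo[1], lo[2], lo[3]]
        if (hi[ax] <= d[ax]) acc <- acc + w[k + 1] * f[hi[1], hi[2], hi[3]]
      }
      out[x, y, z] <- acc
    }
    f <- out
  }
  f
}

# Kuhn 6-tetrahedra decomposition (corner offsets per tetrahedron)
ORACLE_TETS <- list(
  rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1)),
  rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(1,1,1)),
  rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,1,1)),
  rbind(c(0,0,0), c(0,1,0), c(0,1,1), c(1,1,1)),
  rbind(c(0,0,0), c(0,0,1), c(1,0,1), c(1,1,1)),
  rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(1,1,1))
)

oracle_mesh <- function(mask, spacing) {
  pad <- ORACLE_RADIUS + 1L
  d0 <- dim(mask)
  d <- d0 + 2L * pad
  m <- array(0, d)
  m[(pad + 1):(pad + d0[1]), (pad + 1):(pad + d0[2]), (pad + 1):(pad + d0[3])] <-
    mask * 1
  f <- oracle_smooth(m)
  if (max(f[m == 1]) <= ORACLE_LEVEL) {
    return(oracle_voxel_mesh(m, spacing))
  }
  area <- 0; vol6 <- 0
  verts <- list()
  interp <- function(p1, v1, p2, v2) p1 + (ORACLE_LEVEL - v1) / (v2 - v1) * (p2 - p1)
  emit <- function(a, b, c, ref) {
    pa <- a * spacing; pb <- b * spacing; pc <- c * spacing; pr <- ref * spacing
    nrm <- c(
      (pb[2] - pa[2]) * (pc[3] - pa[3]) - (pb[3] - pa[3]) * (pc[2] - pa[2]),
      (pb[3] - pa[3]) * (pc[1] - pa[1]) - (pb[1] - pa[1]) * (pc[3] - pa[3]),
      (pb[1] - pa[1]) * (pc[2] - pa[2]) - (pb[2] - pa[2]) * (pc[1] - pa[1])
    )
    cen <- (pa + pb + pc) / 3
    if (sum(nrm * (cen - pr)) < 0) { tmp <- pb; pb <- pc; pc <- tmp; nrm <- -nrm }
    area <<- area + sqrt(sum(nrm^2)) / 2
    vol6 <<- vol6 + pa[1] * (pb[2] * pc[3] - pb[3] * pc[2]) -
                    pa[2] * (pb[1] * pc[3] - pb[3] * pc[1]) +
                    pa[3] * (pb[1] * pc[2] - pb[2] * pc[1])
    verts[[length(verts) + 1]] <<- a
    verts[[length(verts) + 1]] <<- b
    verts[[length(verts) + 1]] <<- c
  }
  for (z in seq_len(d[3] - 1)) for (y in seq_len(d[2] - 1)) for (x in seq_len(d[1] - 1)) {
    cv <- f[x:(x + 1), y:(y + 1), z:(z + 1)]
    if (all(cv > ORACLE_LEVEL) || all(cv <= ORACLE_LEVEL)) next
    for (tet in ORACLE_TETS) {
      pts <- sweep(tet, 2, c(x, y, z) - 1, "+")
      vals <- numeric(4)
      for (c4 in 1:4) vals[c4] <- cv[tet[c4, 1] + 1, tet[c4, 2] + 1, tet[c4, 3] + 1]
      ins <- which(vals > ORACLE_LEVEL)
      outs <- which(vals <= ORACLE_LEVEL)
      if (length(ins) == 0 || length(ins) == 4) next
      ref <- colMeans(pts[ins, , drop = FALSE])
      if (length(ins) == 1) {
        i <- ins[1]
        emit(interp(pts[i, ], vals[i], pts[outs[1], ], vals[outs[1]]),
             interp(pts[i, ], vals[i], pts[outs[2], ], vals[outs[2]]),
             interp(pts[i, ], vals[i], pts[outs[3], ], vals[outs[3]]), ref)
      } else if (length(ins) == 3) {
        o <- outs[1]
        emit(interp(pts[ins[1], ], vals[ins[1]], pts[o, ], vals[o]),
             interp(pts[ins[2], ], vals[ins[2]], pts[o, ], vals[o]),
             interp(pts[ins[3], ], vals[ins[3]], pts[o, ], vals[o]), ref)
      } else {
        a <- interp(pts[ins[1], ], vals[ins[1]], pts[outs[1], ], vals[outs[1]])
        b <- interp(pts[ins[1], ], vals[ins[1]], pts[outs[2], ], vals[outs[2]])
        cc <- interp(pts[ins[2], ], vals[ins[2]], pts[outs[2], ], vals[outs[2]])
        dd <- interp(pts[ins[2], ], vals[ins[2]], pts[outs[1], ], vals[outs[1]])
        emit(a, b, cc, ref)
        emit(a, cc, dd, ref)
      }
    }
  }
  vmat <- unique(do.call(rbind, verts))
  list(area = area, volume = abs(vol6) / 6,
       vertices = sweep(vmat, 2, spacing, "*"))
}

oracle_voxel_mesh <- function(m, spacing) {
  d <- dim(m)
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2])
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  area <- 0
  verts <- list()
  count <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (m[x, y, z] == 0) next
    count <- count + 1
    surface <- FALSE
    for (k in 1:6) {
      q <- c(x, y, z) + nb[k, ]
      inside <- all(q >= 1) && all(q <= d) && m[q[1], q[2], q[3]] == 1
      if (!inside) { area <- area + face[ceiling(k / 2)]; surface <- TRUE }
    }
    if (surface) {
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        verts[[length(verts) + 1]] <- c(x + dx - 0.5, y + dy - 0.5, z + dz - 0.5)
      }
    }
  }
  vmat <- unique(do.call(rbind, verts))
  list(area = area, volume = count * prod(spacing),
       vertices = sweep(vmat, 2, spacing, "*"))
}

oracle_shape <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(idx)
  coords <- sweep(idx - 1, 2, spacing, "*")
  cc <- sweep(coords, 2, colMeans(coords), "-")
  cov <- crossprod(cc) / n
  ev <- sort(pmax(eigen(cov, symmetric = TRUE)$values, 0), decreasing = TRUE)
  mesh <- oracle_mesh(mask, spacing)
  v <- mesh$vertices
  maxd <- function(wdims) {
    best <- 0
    if (nrow(v) >= 2) {
      for (i in seq_len(nrow(v) - 1)) for (j in (i + 1):nrow(v)) {
        dd <- sum((v[i, wdims] - v[j, wdims])^2)
        if (dd > best) best <- dd
      }
    }
    sqrt(best)
  }
  vol <- mesh$volume
  area <- mesh$area
  c(
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    LeastAxisLength = 4 * sqrt(ev[3]),
    MajorAxisLength = 4 * sqrt(ev[1]),
    Maximum2DDiameterColumn = maxd(2:3),
    Maximum2DDiameterRow = maxd(c(1, 3)),
    Maximum2DDiameterSlice = maxd(1:2),
    Maximum3DDiameter = maxd(1:3),
    MeshVolume = vol,
    MinorAxisLength = 4 * sqrt(ev[2]),
    Sphericity = if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else 0,
    SurfaceArea = area,
    SurfaceVolumeRatio = if (vol > 0) area / vol else 0,
    VoxelVolume = n * prod(spacing)
  )
}
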