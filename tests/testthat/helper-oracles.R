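# Independent brute-force oracles used to validate the fast kernels.

# shift-based grayscale morphology on a (z, y, x) array, spherical SE,
# dilation padded with -Inf / erosion with +Inf (out-of-bounds ignored)
oracle_morph <- function(a, r, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(a)
  out <- array(if (op == "dilate") -Inf else Inf, d)
  cmp <- if (op == "dilate") pmax else pmin
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    if (dz^2 + dy^2 + dx^2 > r^2) next
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    out[zs - dz, ys - dy, xs - dx] <-
      cmp(out[zs - dz, ys - dy, xs - dx], a[zs, ys, xs])
  }
  out[!is.finite(out)] <- 0
  out
}

oracle_close <- function(a, r) oracle_morph(oracle_morph(a, r, "dilate"), r, "erode")

# 3D flood fill oracle: zero voxels 6-connected to the border
# (frontier-at-a-time breadth-first expansion, fully vectorized)
oracle_exterior_mask <- function(a) {
  d <- dim(a)
  ext <- array(FALSE, d)
  frontier <- which(a == 0 &
    (slice.index(a, 1) %in% c(1, d[1]) | slice.index(a, 2) %in% c(1, d[2]) |
       slice.index(a, 3) %in% c(1, d[3])))
  ext[frontier] <- TRUE
  while (length(frontier)) {
    idx <- frontier - 1L
    k <- idx %% d[1]
    j <- (idx %/% d[1]) %% d[2]
    i <- idx %/% (d[1] * d[2])
    nb <- c(frontier[k < d[1] - 1] + 1L, frontier[k > 0] - 1L,
            frontier[j < d[2] - 1] + d[1], frontier[j > 0] - d[1],
            frontier[i < d[3] - 1] + d[1] * d[2],
            frontier[i > 0] - d[1] * d[2])
    nb <- unique(nb[a[nb] == 0 & !ext[nb]])
    ext[nb] <- TRUE
    frontier <- nb
  }
  ext
}

# separable Gaussian blur oracle (reflect boundary, 4-sigma truncation)
oracle_blur <- function(a, sigma) {
  rad <- max(1, ceiling(4 * sigma))
  ker <- exp(-0.5 * (-rad:rad)^2 / sigma^2)
  ker <- ker / sum(ker)
  reflect <- function(p, len) {
    while (any(p < 1 | p > len)) {
      p <- ifelse(p < 1, 1 - p, p)
      p <- ifelse(p > len, 2 * len + 1 - p, p)
    }
    p
  }
  conv_axis <- function(x, axis) {
    d <- dim(x)
    out <- array(0, d)
    for (t in -rad:rad) {
      idx <- reflect(seq_len(d[axis]) + t, d[axis])
      shifted <- switch(axis, x[idx, , , drop = FALSE],
                        x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
      out <- out + ker[t + rad + 1] * shifted
    }
    out
  }
  b <- conv_axis(conv_axis(conv_axis(a * 1.0, 1), 2), 3)
  array(pmin(255, pmax(0, round(b))), dim(a))
}

# union-find connected components of a triangle mesh (vertex labels)
oracle_components <- function(faces, nv) {
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(faces))) {
    a <- find(faces[i, 1]); b <- find(faces[i, 2]); c_ <- find(faces[i, 3])
    parent[b] <- a
    parent[c_] <- find(a)
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  match(roots, unique(roots))
}

# exact point-to-triangle distance (pure R; Ericson's algorithm)
oracle_point_tri_dist <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c_
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c_)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c_ - b)))^2)))
  }
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

# all-pairs vertex-to-surface distance oracle
oracle_surface_dist <- function(points, mesh) {
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    min(vapply(seq_len(nrow(mesh$faces)), function(f) {
      oracle_point_tri_dist(p, mesh$vertices[mesh$faces[f, 1], ],
                            mesh$vertices[mesh$faces[f, 2], ],
                            mesh$vertices[mesh$faces[f, 3], ])
    }, numeric(1)))
  }, numeric(1))
}

oracle_hausdorff <- function(a, b) {
  max(max(oracle_surface_dist(a$vertices, b)),
      max(oracle_surface_dist(b$vertices, a)))
}
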