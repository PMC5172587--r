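#' Mesh primitives: box, icosphere, capped cylinder
#'
#' Simple closed test meshes in micrometre coordinates with outward
#' normals; used throughout the examples, vignette and test suite.
#'
#' @param dx,dy,dz box edge lengths in um.
#' @param origin corner (box) or center (sphere/cylinder), length-3.
#' @return a closed [surface_mesh].
#' @export
box_mesh <- function(dx, dy, dz, origin = c(0, 0, 0)) {
  v <- cbind(
    c(0, dx, dx, 0, 0, dx, dx, 0),
    c(0, 0, dy, dy, 0, 0, dy, dy),
    c(0, 0, 0, 0, dz, dz, dz, dz))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),          # bottom (z = 0), outward -z
    c(5, 6, 7), c(5, 7, 8),          # top
    c(1, 2, 6), c(1, 6, 5),          # y = 0
    c(3, 4, 8), c(3, 8, 7),          # y = dy
    c(2, 3, 7), c(2, 7, 6),          # x = dx
    c(4, 1, 5), c(4, 5, 8))          # x = 0
  surface_mesh(v, f)
}

#' @rdname box_mesh
#' @param radius sphere radius in um.
#' @param subdiv icosahedron subdivision level (>= 0).
#' @param center sphere center.
#' @export
icosphere <- function(radius = 1, subdiv = 2L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[k]])) return(mid_cache[[k]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  surface_mesh(sweep(v * radius, 2, center, "+"), f)
}

#' @rdname box_mesh
#' @param length cylinder length in um (axis along z).
#' @param n_theta angular resolution.
#' @param n_len axial segments.
#' @param capped close the ends with triangle fans.
#' @export
cylinder_mesh <- function(radius = 10, length = 100, n_theta = 32L,
                          n_len = 16L, center = c(0, 0, 0), capped = TRUE) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(-length / 2, length / 2, length.out = n_len + 1L)
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(th), radius * sin(th), z)))
  f <- matrix(0L, 0, 3)
  for (iz in seq_len(n_len)) {
    base0 <- (iz - 1L) * n_theta
    base1 <- iz * n_theta
    for (it in seq_len(n_theta)) {
      itn <- if (it == n_theta) 1L else it + 1L
      f <- rbind(f,
                 c(base0 + it, base0 + itn, base1 + it),
                 c(base0 + itn, base1 + itn, base1 + it))
    }
  }
  if (capped) {
    cb <- nrow(v) + 1L
    ct <- nrow(v) + 2L
    v <- rbind(v, c(0, 0, -length / 2), c(0, 0, length / 2))
    topb <- n_len * n_theta
    for (it in seq_len(n_theta)) {
      itn <- if (it == n_theta) 1L else it + 1L
      f <- rbind(f, c(cb, itn, it), c(ct, topb + it, topb + itn))
    }
  }
  surface_mesh(sweep(v, 2, center, "+"), f)
}
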