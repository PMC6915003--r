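# Independent test oracles, deliberately implemented differently from the
# package code paths they check.

# Brute-force exact line integral of a pixel image along one ray, by
# clipping the ray against every pixel's x/y slabs (Liang-Barsky style,
# vectorized over all pixels at once).  The ray at angle `theta`, offset
# `s`, is p(t) = s*(cos, sin) + t*(-sin, cos); the grid is centered.
oracleRayIntegral <- function(v, sp, theta, s) {
  nx <- nrow(v); ny <- ncol(v)
  xmin <- -nx * sp[1] / 2; ymin <- -ny * sp[2] / 2
  px <- s * cos(theta); py <- s * sin(theta)
  ux <- -sin(theta); uy <- cos(theta)
  xb <- xmin + (0:nx) * sp[1]
  yb <- ymin + (0:ny) * sp[2]
  bigT <- 1e9
  # axis-parallel tie-break: on-boundary rays belong to the upper cell
  # (+1e-9 mm bias), matching the compiled projector's convention
  if (abs(ux) < 1e-12) {
    inx <- px + 1e-9 >= xb[-length(xb)] & px + 1e-9 < xb[-1]
    tx0 <- ifelse(inx, -bigT, bigT); tx1 <- ifelse(inx, bigT, -bigT)
  } else {
    ta <- (xb[-length(xb)] - px) / ux; tb <- (xb[-1] - px) / ux
    tx0 <- pmin(ta, tb); tx1 <- pmax(ta, tb)
  }
  if (abs(uy) < 1e-12) {
    iny <- py + 1e-9 >= yb[-length(yb)] & py + 1e-9 < yb[-1]
    ty0 <- ifelse(iny, -bigT, bigT); ty1 <- ifelse(iny, bigT, -bigT)
  } else {
    ta <- (yb[-length(yb)] - py) / uy; tb <- (yb[-1] - py) / uy
    ty0 <- pmin(ta, tb); ty1 <- pmax(ta, tb)
  }
  t0 <- outer(tx0, ty0, pmax)
  t1 <- outer(tx1, ty1, pmin)
  lens <- pmax(t1 - t0, 0)
  sum(lens * v)
}

oracleSinogram <- function(img, geom) {
  v <- acval::values(img); sp <- acval::spacing(img)
  out <- matrix(0, length(geom@angles), length(geom@sCenters))
  for (a in seq_along(geom@angles))
    for (b in seq_along(geom@sCenters))
      out[a, b] <- oracleRayIntegral(v, sp, geom@angles[a],
                                     geom@sCenters[b])
  out
}

# Brute-force count of voxel centers inside a circle, by explicit loop.
oracleDiskCount <- function(n, sp, centerMm, radiusMm) {
  org <- -(n - 1) / 2 * sp
  cnt <- 0L
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) {
    x <- org[1] + (i - 1) * sp[1]
    y <- org[2] + (j - 1) * sp[2]
    if ((x - centerMm[1])^2 + (y - centerMm[2])^2 <= radiusMm^2)
      cnt <- cnt + 1L
  }
  cnt
}

# Small grids shared across tests.
smallGrid <- function(n = 64L, sp = 4.8) acval::imageGrid(n, sp)
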