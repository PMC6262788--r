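# Internal numerical helpers: separable convolution, Gaussian blur,
# in-plane rotation by inverse mapping.

# 1D Gaussian kernel, sigma in pixels, truncated at 4 sigma, sum 1
gauss_kernel <- function(sigma_px, truncate = 4) {
  if (sigma_px <= 1e-8) return(1)
  r <- max(1L, ceiling(truncate * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# convolve the rows (dim 1) of a matrix with kernel k, zero padding
conv_dim1 <- function(m, k) {
  if (length(k) == 1) return(m * k)
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
  }
  out
}

# separable 2D convolution, zero padding; kx along dim 1, ky along dim 2
sep_conv2 <- function(m, kx, ky) {
  m <- conv_dim1(m, kx)
  t(conv_dim1(t(m), ky))
}

# separable 3D Gaussian blur of array [x, y, z]; sigma_um scalar, spacing um
gauss_blur3 <- function(a, sigma_um, spacing) {
  if (sigma_um <= 1e-8) return(a)
  d <- dim(a)
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_um / spacing[ax])
    if (length(k) == 1) next
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    dim(b) <- c(db[1], db[2] * db[3])
    b <- conv_dim1(b, k)
    dim(b) <- db
    a <- aperm(b, order(perm))
  }
  a
}

# Rotate one xy plane by angle (degrees, +x towards +y) about the plane
# centre, physical (um) geometry; bilinear or nearest-neighbour sampling.
# Returns a matrix of the same dimensions; outside samples are `fill`.
rotate_plane_map <- function(nx, ny, sx, sy, angle_deg) {
  th <- angle_deg * pi / 180
  cx <- nx * sx / 2
  cy <- ny * sy / 2
  gx <- px_center(seq_len(nx), sx) - cx
  gy <- px_center(seq_len(ny), sy) - cy
  X <- matrix(gx, nx, ny)
  Y <- matrix(gy, nx, ny, byrow = TRUE)
  # inverse rotation of output coordinates into the source plane
  xs <- cos(th) * X + sin(th) * Y + cx
  ys <- -sin(th) * X + cos(th) * Y + cy
  list(ix = xs / sx + 0.5, iy = ys / sy + 0.5)  # fractional 1-based indices
}

sample_bilinear <- function(m, ix, iy, fill = 0) {
  nx <- nrow(m); ny <- ncol(m)
  x0 <- floor(ix); y0 <- floor(iy)
  fx <- ix - x0;  fy <- iy - y0
  out <- matrix(fill, nrow(ix), ncol(ix))
  get <- function(xi, yi) {
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
    v <- matrix(fill, nrow(xi), ncol(xi))
    v[ok] <- m[cbind(xi[ok], yi[ok])]
    v
  }
  v00 <- get(x0, y0);     v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  out
}

sample_nearest <- function(m, ix, iy, fill = 0L) {
  nx <- nrow(m); ny <- ncol(m)
  xi <- round(ix); yi <- round(iy)
  ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  out <- matrix(fill, nrow(ix), ncol(ix))
  out[ok] <- m[cbind(xi[ok], yi[ok])]
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

log_msg <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}
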