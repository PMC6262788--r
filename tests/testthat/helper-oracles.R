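# Independent brute-force oracles and small fixture builders.

# Exhaustive chord search over boundary-pixel pairs, written independently
# of the package's compiled implementation: plain R, vectorized only over
# the off-mask pixels of each candidate segment's bounding box.
oracle_chord <- function(mask, sx, sz, center_deg, halfwidth_deg) {
  nx <- nrow(mask); nz <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  is_b <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    i == 1 || i == nx || j == 1 || j == nz ||
      !mask[i - 1, j] || !mask[i + 1, j] ||
      !mask[i, j - 1] || !mask[i, j + 1]
  }, logical(1))
  bp <- idx[is_b, , drop = FALSE]
  off <- !mask
  ang_diff <- function(a, b) {
    d <- a - b + 90
    d <- d - 180 * floor(d / 180)
    d - 90
  }
  best <- NULL
  nb <- nrow(bp)
  for (a in seq_len(nb)) for (b in a:nb) {
    x1 <- unname(bp[a, 1]); z1 <- unname(bp[a, 2])
    x2 <- unname(bp[b, 1]); z2 <- unname(bp[b, 2])
    if (x2 < x1 || (x2 == x1 && z2 < z1)) {
      tmp <- c(x1, z1); x1 <- x2; z1 <- z2; x2 <- tmp[1]; z2 <- tmp[2]
    }
    dxu <- (x2 - x1) * sx; dzu <- (z2 - z1) * sz
    if (dzu < 0 || (dzu == 0 && dxu < 0)) { dxu <- -dxu; dzu <- -dzu }
    ang <- atan2(dxu, dzu) * 180 / pi
    dev <- abs(ang_diff(ang, center_deg))
    if (dev > halfwidth_deg + 1e-7) next
    len <- sqrt(dxu^2 + dzu^2)
    if (!is.null(best)) {
      if (len < best$len) next
      if (len == best$len) {
        better <- dev < best$dev ||
          (dev == best$dev &&
             !identical(order_pairs(c(x1, z1, x2, z2), best$ep), 2L))
        if (!better) next
      }
    }
    # off-mask pixels in the segment's bounding box
    bxs <- min(x1, x2):max(x1, x2)
    bzs <- min(z1, z2):max(z1, z2)
    sub_off <- which(off[bxs, bzs, drop = FALSE], arr.ind = TRUE)
    blocked <- FALSE
    if (nrow(sub_off)) {
      px <- bxs[sub_off[, 1]]; pz <- bzs[sub_off[, 2]]
      blocked <- any(oracle_seg_box(x1, z1, x2, z2, px, pz))
    }
    if (blocked) next
    best <- list(len = len, dev = dev, ang = ang, ep = c(x1, z1, x2, z2))
  }
  best
}

# lexicographic comparison; returns 1 if a < b, 2 if a >= b
order_pairs <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(1L)
    if (a[k] > b[k]) return(2L)
  }
  2L
}

# closed segment (pixel centres) vs closed unit cells at (px, pz); vectorized
oracle_seg_box <- function(x1, z1, x2, z2, px, pz) {
  dx <- x2 - x1; dz <- z2 - z1
  # four slab constraints; p is scalar per constraint, q vectorized
  r <- list(rep(0, length(px)), rep(1, length(px)))
  ps <- c(-dx, dx, -dz, dz)
  qs <- list(x1 - (px - 0.5), (px + 0.5) - x1,
             z1 - (pz - 0.5), (pz + 0.5) - z1)
  for (k in 1:4) {
    p <- ps[k]; q <- qs[[k]]
    if (p == 0) {
      r[[2]][q < 0] <- -Inf
    } else {
      t <- q / p
      if (p < 0) r[[1]] <- pmax(r[[1]], t) else r[[2]] <- pmin(r[[2]], t)
    }
  }
  r[[1]] <= r[[2]] + 1e-12
}

# random 8-connected blob mask (random walk dilated), at most nmax x nmax
random_blob_mask <- function(nmax = 40, steps = 40) {
  m <- matrix(FALSE, nmax, nmax)
  x <- sample.int(nmax - 10, 1) + 5
  z <- sample.int(nmax - 10, 1) + 5
  for (s in seq_len(steps)) {
    m[x, z] <- TRUE
    if (stats::runif(1) < 0.5)
      m[max(1, x - 1):min(nmax, x + 1), z] <- TRUE
    x <- min(nmax, max(1, x + sample(c(-1, 0, 1), 1)))
    z <- min(nmax, max(1, z + sample(c(-1, 0, 1), 1)))
  }
  # keep the largest 8-connected component for a well-defined mask
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  if (max(lab) > 1) {
    counts <- tabulate(lab[lab > 0])
    m <- lab == which.max(counts)
  }
  m
}

# ellipse mask with semi-axes (a_um, b_um) on pixel grid (sx, sz)
ellipse_mask <- function(a_um, b_um, sx, sz, pad = 3) {
  nx <- ceiling(2 * a_um / sx) + 2 * pad
  nz <- ceiling(2 * b_um / sz) + 2 * pad
  cx <- nx * sx / 2; cz <- nz * sz / 2
  xs <- ((1:nx) - 0.5) * sx
  zs <- ((1:nz) - 0.5) * sz
  outer(xs, zs, function(x, z) ((x - cx) / a_um)^2 + ((z - cz) / b_um)^2 <= 1)
}

# minimal total cost of an assignment by explicit permutation search
oracle_lap_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# small epithelium used by unit tests (seconds, not minutes)
small_epithelium <- function(...) {
  epithelium_params(n_cells_per_side = 2, cell_length = 18,
                    cell_depth_z = 8, focal_depth = 60, ...)
}

# Welch's t computed longhand, as an independent reference
oracle_welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# smooth separable test stack for rotation round-trip checks
gauss_smooth_fixture <- function(nx, ny, nz) {
  xs <- seq(-2, 2, length.out = nx)
  ys <- seq(-2, 2, length.out = ny)
  pl <- outer(xs, ys, function(a, b) exp(-(a^2 + b^2) / 2))
  array(rep(pl, nz), c(nx, ny, nz))
}

# nearest-neighbour rotation of a logical mask about its centre
rotate_mask <- function(m, angle_deg) {
  lab <- array(as.integer(m), c(dim(m), 1L))
  r <- rotate_stack_xy(cell_labels(lab, c(0.2, 0.2, 1)), angle_deg)
  r$labels[, , 1] == 1L
}

# centre a small mask inside an n x n canvas
embed_mask <- function(m, n) {
  out <- matrix(FALSE, n, n)
  ox <- (n - nrow(m)) %/% 2
  oz <- (n - ncol(m)) %/% 2
  out[ox + seq_len(nrow(m)), oz + seq_len(ncol(m))] <- m
  out
}
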