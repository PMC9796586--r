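# 3D array utilities shared by the phantom, masking and smoothing code.
# Volumes are plain numeric 3D arrays; an optional "voxel_size" attribute
# (mm triple) is carried through I/O.

shift3 <- function(a, s, fill = 0) {
  # translate a 3D array by integer offsets s = c(dx, dy, dz); out-of-range
  # positions take `fill`
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    k <- s[ax]
    if (abs(k) >= d[ax]) return(out)
    if (k >= 0) {
      dst[[ax]] <- (1 + k):d[ax]; src[[ax]] <- 1:(d[ax] - k)
    } else {
      dst[[ax]] <- 1:(d[ax] + k); src[[ax]] <- (1 - k):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

.cross_offsets <- rbind(c(0, 0, 0),
                        c(1, 0, 0), c(-1, 0, 0),
                        c(0, 1, 0), c(0, -1, 0),
                        c(0, 0, 1), c(0, 0, -1))

dilate3 <- function(m) {
  # binary dilation with the 6-connected cross structuring element
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(.cross_offsets)))
    out <- out | shift3(m, .cross_offsets[i, ], fill = FALSE)
  out
}

erode3 <- function(m) {
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(.cross_offsets)))
    out <- out & shift3(m, .cross_offsets[i, ], fill = FALSE)
  out
}

fill_holes3 <- function(m) {
  # fill background components not connected to the array border
  bg <- !m
  reach <- bg
  reach[2:(dim(m)[1] - 1), 2:(dim(m)[2] - 1), 2:(dim(m)[3] - 1)] <- FALSE
  repeat {
    grown <- dilate3(reach) & bg
    if (all(grown == reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

smooth_weighted <- function(vol, mask, wx = 1, wy = 1, wz = 1) {
  # separable weighted smoothing restricted to `mask`: the kernel is
  # renormalized over in-mask neighbors so constants are preserved and no
  # signal bleeds across the mask boundary.  Outside the mask the result is 0.
  num <- vol * mask
  den <- mask * 1
  axis_pass <- function(num, den, w, ax) {
    if (length(w) == 1) return(list(num, den))
    r <- (length(w) - 1) / 2
    n2 <- array(0, dim(num)); d2 <- array(0, dim(den))
    for (j in seq_along(w)) {
      s <- c(0, 0, 0); s[ax] <- j - r - 1
      n2 <- n2 + w[j] * shift3(num, s)
      d2 <- d2 + w[j] * shift3(den, s)
    }
    list(n2, d2)
  }
  p <- axis_pass(num, den, wx, 1)
  p <- axis_pass(p[[1]], p[[2]], wy, 2)
  p <- axis_pass(p[[1]], p[[2]], wz, 3)
  out <- array(0, dim(vol))
  ok <- mask & p[[2]] > 0
  out[ok] <- p[[1]][ok] / p[[2]][ok]
  out
}

same_grid <- function(a, b) identical(dim(a), dim(b))

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
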