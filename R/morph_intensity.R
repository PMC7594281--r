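## Size, shape and intensity-distribution features. Conventions: row-major
## 0/1 masks whose pixels are unit squares of size spacing[1] x spacing[2]
## mm; distances are measured between pixel centers; population (not
## sample) moments throughout.

# boundary pixels: in-mask pixels with a 4-neighbor outside the mask (or on
# the image edge); returned as an n x 2 matrix of (row, col) indices.
.boundary_pixels <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(m & !inner, arr.ind = TRUE)
}

#' Maximum Feret diameter of a mask
#'
#' The largest pairwise distance between boundary pixel centers, in mm —
#' the "longest tumor diameter". The maximum over all pixel pairs is
#' attained on the convex hull of the boundary points, which is used to
#' keep the search small; this is exactly equivalent to the exhaustive
#' pairwise search.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param spacing Pixel spacing in mm, length-2 `(row, col)` or a scalar.
#' @return Feret diameter in mm (0 for a single-pixel mask).
#' @export
feret_diameter <- function(mask, spacing = c(1, 1)) {
  m <- .stopifnot_mask(mask)
  spacing <- rep(as.numeric(spacing), length.out = 2)
  bp <- .boundary_pixels(m)
  pts <- cbind(bp[, 1] * spacing[1], bp[, 2] * spacing[2])
  if (nrow(pts) == 1) return(0)
  if (nrow(pts) > 3) {
    h <- chull(pts)
    pts <- pts[h, , drop = FALSE]
  }
  d <- dist(pts)
  max(d)
}

# outer boundary contour of a mask as a closed polygon in mm (marching
# squares at level 0.5 on the zero-padded mask); the longest contour is the
# outer boundary.
.outer_contour <- function(mask, spacing = c(1, 1)) {
  m <- mask != 0
  spacing <- rep(as.numeric(spacing), length.out = 2)
  pad <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m * 1
  cl <- grDevices::contourLines(
    x = (seq_len(nrow(pad)) - 1) * spacing[1],
    y = (seq_len(ncol(pad)) - 1) * spacing[2],
    z = pad, levels = 0.5)
  if (length(cl) == 0) stop("mask has no boundary contour")
  len <- vapply(cl, function(cc) {
    xs <- c(cc$x, cc$x[1]); ys <- c(cc$y, cc$y[1])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1))
  list(contour = cl[[which.max(len)]], length = max(len))
}

# convex area in pixels: number of grid pixels whose centers lie inside the
# convex hull of the mask pixel centers (the "convex image" of regionprops
# conventions). The mask is a subset of the hull fill, so solidity <= 1.
.convex_area_px <- function(mask) {
  px <- which(mask != 0, arr.ind = TRUE)
  h <- chull(px)
  if (length(h) <= 2) return(sum(mask != 0))  # collinear mask
  hull <- px[h, , drop = FALSE]
  hull <- rbind(hull, hull[1, ])
  eps <- 1e-9
  total <- 0L
  for (r in seq(min(px[, 1]), max(px[, 1]))) {
    xs <- numeric(0)
    for (k in seq_len(nrow(hull) - 1)) {
      y1 <- hull[k, 1]; y2 <- hull[k + 1, 1]
      x1 <- hull[k, 2]; x2 <- hull[k + 1, 2]
      if (y1 == y2) {
        if (y1 == r) xs <- c(xs, x1, x2)
      } else if (r >= min(y1, y2) && r <= max(y1, y2)) {
        xs <- c(xs, x1 + (r - y1) / (y2 - y1) * (x2 - x1))
      }
    }
    if (length(xs) == 0) next
    total <- total + max(0L, floor(max(xs) + eps) - ceiling(min(xs) - eps) + 1L)
  }
  total
}

# second central moments of the mask in mm^2 with the 1/12 pixel-square
# correction; returns eigenvalues (descending).
.moment_eigen <- function(mask, spacing = c(1, 1)) {
  m <- mask != 0
  spacing <- rep(as.numeric(spacing), length.out = 2)
  px <- which(m, arr.ind = TRUE)
  r <- px[, 1] * spacing[1]
  c_ <- px[, 2] * spacing[2]
  uxx <- .pop_var(r) + spacing[1]^2 / 12
  uyy <- .pop_var(c_) + spacing[2]^2 / 12
  uxy <- mean((r - mean(r)) * (c_ - mean(c_)))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  c((uxx + uyy + common) / 2, (uxx + uyy - common) / 2)
}

#' Size features of a tumor mask
#'
#' Six mm-valued size descriptors: area (pixel count times pixel area),
#' perimeter (outer boundary contour length), longest diameter (maximum
#' Feret diameter between boundary pixel centers), equivalent circular
#' diameter `2*sqrt(area/pi)`, and the major/minor axis lengths of the
#' ellipse with the same second central moments as the mask.
#'
#' @param mask Logical (or 0/1) matrix, non-empty.
#' @param spacing Pixel spacing in mm, length-2 `(row, col)` or scalar.
#' @return Named numeric vector of 6 features (names `size.*`).
#' @export
size_features <- function(mask, spacing = c(1, 1)) {
  m <- .stopifnot_mask(mask)
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (any(spacing <= 0)) stop("spacing must be positive")
  area <- sum(m) * spacing[1] * spacing[2]
  per <- .outer_contour(m, spacing)$length
  eig <- .moment_eigen(m, spacing)
  out <- c(area,
           per,
           feret_diameter(m, spacing),
           2 * sqrt(area / pi),
           4 * sqrt(eig[1]),
           4 * sqrt(eig[2]))
  names(out) <- .size_names
  out
}

#' Shape features of a tumor mask
#'
#' Five dimensionless shape descriptors: eccentricity of the moment
#' ellipse, solidity (pixel count over the pixel count of the convex image,
#' i.e. the grid fill of the convex hull of pixel centers, so solidity is
#' always <= 1), extent (area over bounding-box area), circularity
#' `4*pi*area/perimeter^2`, and elongation (minor over major axis).
#'
#' @param mask Logical (or 0/1) matrix with at least 2 pixels.
#' @return Named numeric vector of 5 features (names `shape.*`).
#' @export
shape_features <- function(mask) {
  m <- .stopifnot_mask(mask)
  if (sum(m) < 2) stop("shape features undefined for a single-pixel mask")
  eig <- .moment_eigen(m, c(1, 1))
  ecc <- sqrt(max(0, 1 - eig[2] / eig[1]))
  elong <- sqrt(eig[2] / eig[1])

  px <- which(m, arr.ind = TRUE)
  bbox_area <- (diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1)
  area <- sum(m)
  per <- .outer_contour(m, c(1, 1))$length

  out <- c(ecc,
           area / .convex_area_px(m),
           area / bbox_area,
           4 * pi * area / per^2,
           elong)
  names(out) <- .shape_names
  out
}

#' Intensity-distribution features
#'
#' Fourteen first-order statistics of the raw masked intensities (no
#' normalization or filtering): mean, median, population variance, Fisher
#' skewness, Pearson kurtosis (normal = 3), minimum, maximum, range, 10th
#' and 90th percentiles, interquartile range, energy (sum of squares), and
#' entropy / uniformity of a 256-equal-width-bin histogram spanning
#' `[min, max]` of the masked values (entropy in bits; a constant input has
#' entropy 0 and uniformity 1).
#'
#' @param values Numeric vector of masked intensities (length >= 2).
#' @return Named numeric vector of 14 features (names `hist.*`).
#' @export
intensity_features <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2) stop("need at least 2 pixels")
  if (any(!is.finite(v))) stop("non-finite intensities")
  m2 <- .pop_var(v)
  mu <- mean(v)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  rng <- max(v) - min(v)
  if (rng > 0) {
    b <- pmin(255L, as.integer(floor((v - min(v)) / rng * 256))) + 1L
    p <- tabulate(b, nbins = 256L) / length(v)
  } else {
    p <- c(1, numeric(255))
  }
  qs <- quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  out <- c(mu, median(v), m2, skew, kurt, min(v), max(v), rng,
           qs[1], qs[4], qs[3] - qs[2], sum(v^2),
           -sum(.xlog2x(p)), sum(p^2))
  names(out) <- .hist_names
  out
}
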