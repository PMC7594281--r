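## Gray-level texture matrices (GLCM, GLRLM, GLSZM, NGTDM) and the 52
## image-domain texture features derived from them. Matrices are built from
## a quantized image (labels 1..L inside the mask, 0 outside) by compiled
## routines; feature formulas follow the classical Haralick / Galloway /
## Thibault / Amadasun-King definitions in their IBSI-consistent form.
## All logarithms are base 2 with the 0*log 0 = 0 convention.

# direction name -> (dr, dc) grid offset; rows grow downward so 45 deg is
# up-right, 135 deg up-left.
.glcm_directions <- list(
  "0"   = c(0L, 1L),
  "45"  = c(-1L, 1L),
  "90"  = c(-1L, 0L),
  "135" = c(-1L, -1L))

.ngtdm_eps <- 1e-6

.as_quantized <- function(q) {
  if (!inherits(q, "quantized_image")) stop("expected a quantized_image")
  q
}

#' Gray-level co-occurrence matrix
#'
#' Builds the symmetric, normalized co-occurrence matrix of gray-level
#' pairs at a 1-pixel offset in one of four directions (0, 45, 90, 135
#' degrees). Only pairs with both pixels inside the mask are counted; each
#' pair is counted in both orders so the matrix is symmetric, and it is
#' normalized to sum 1.
#'
#' @param q A `quantized_image` from [equal_probability_quantize()].
#' @param direction One of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @param offset Pixel offset (only 1 is supported).
#' @return A `texture_matrix` object (kind `"GLCM"`).
#' @export
compute_glcm <- function(q, direction = "0", offset = 1L) {
  q <- .as_quantized(q)
  if (offset != 1L) stop("only offset 1 is supported")
  direction <- as.character(direction)
  d <- .glcm_directions[[direction]]
  if (is.null(d)) stop("direction must be one of 0, 45, 90, 135")
  counts <- cpp_glcm_counts(q$labels, q$L, d[1], d[2])
  tot <- sum(counts)
  if (tot == 0)
    stop("no in-mask pixel pair in direction ", direction)
  structure(list(kind = "GLCM", matrix = counts / tot, L = q$L,
                 direction = direction),
            class = "texture_matrix")
}

#' GLCM features
#'
#' Computes the 21 co-occurrence features: autocorrelation, contrast,
#' correlation, cluster prominence, cluster shade, dissimilarity, energy,
#' entropy, homogeneity, inverse difference moment, maximum probability,
#' sum average, sum entropy, sum variance, difference entropy, difference
#' variance, the two information measures of correlation, inverse
#' difference (moment) normalized, and inverse variance. Correlation and
#' the information measures are defined as 0 when a marginal standard
#' deviation (or entropy) vanishes.
#'
#' @param m A `texture_matrix` of kind `"GLCM"`.
#' @return Named numeric vector of 21 features (names `glcm.*`).
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$kind == "GLCM")
  p <- m$matrix
  L <- m$L
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  lev <- seq_len(L)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  dif <- abs(i - j)

  # sum and difference distributions
  psum <- vapply(2:(2 * L), function(k) sum(p[(i + j) == k]), numeric(1))
  ks <- 2:(2 * L)
  pdif <- vapply(0:(L - 1), function(k) sum(p[dif == k]), numeric(1))
  kd <- 0:(L - 1)
  sa <- sum(ks * psum)
  da <- sum(kd * pdif)

  hxy <- -sum(.xlog2x(p))
  hx <- -sum(.xlog2x(px)); hy <- -sum(.xlog2x(py))
  pxy <- outer(px, py)
  pos <- p > 0 & pxy > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- -sum(.xlog2x(pxy))
  hmax <- max(hx, hy)

  corr <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  imc1 <- if (hmax > 0) (hxy - hxy1) / hmax else 0
  imc2 <- if (hmax > 0) sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))) else 0

  offd <- dif > 0
  out <- c(
    autocorrelation = sum(i * j * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    cluster_prominence = sum((i + j - mux - muy)^4 * p),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    dissimilarity = sum(dif * p),
    energy = sum(p^2),
    entropy = hxy,
    homogeneity = sum(p / (1 + dif)),
    idm = sum(p / (1 + (i - j)^2)),
    max_probability = max(p),
    sum_average = sa,
    sum_entropy = -sum(.xlog2x(psum)),
    sum_variance = sum((ks - sa)^2 * psum),
    difference_entropy = -sum(.xlog2x(pdif)),
    difference_variance = sum((kd - da)^2 * pdif),
    imc1 = imc1,
    imc2 = imc2,
    idn = sum(p / (1 + dif / L)),
    idmn = sum(p / (1 + (i - j)^2 / L^2)),
    inverse_variance = sum(p[offd] / (i - j)[offd]^2)
  )
  names(out) <- .glcm_names
  out
}

#' Gray-level run-length matrix
#'
#' Counts maximal collinear runs of equal-level in-mask pixels in one of
#' four directions. Entry (i, j) is the number of runs of gray level i and
#' length j; runs are broken by the mask boundary.
#'
#' @inheritParams compute_glcm
#' @return A `texture_matrix` (kind `"GLRLM"`) carrying the raw counts and
#'   the in-mask pixel count used by the run-percentage feature.
#' @export
compute_glrlm <- function(q, direction = "0") {
  q <- .as_quantized(q)
  direction <- as.character(direction)
  d <- .glcm_directions[[direction]]
  if (is.null(d)) stop("direction must be one of 0, 45, 90, 135")
  counts <- cpp_glrlm_counts(q$labels, q$L, d[1], d[2])
  if (sum(counts) == 0) stop("no run in direction ", direction)
  structure(list(kind = "GLRLM", matrix = counts, L = q$L,
                 direction = direction, n_pixels = sum(q$labels > 0)),
            class = "texture_matrix")
}

# Shared run-length / size-zone feature formulas: R is the count matrix
# (rows = gray level, cols = run length or zone size), np the in-mask pixel
# count. Returns the 13 classical features.
.rl_features <- function(R, np) {
  nr <- sum(R)
  p <- R / nr
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  j <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  mui <- sum(i * p); muj <- sum(j * p)
  c(sre = sum(p / j^2),
    lre = sum(p * j^2),
    gln = sum(rowSums(R)^2) / nr,
    rln = sum(colSums(R)^2) / nr,
    rp = nr / np,
    lgre = sum(p / i^2),
    hgre = sum(p * i^2),
    srlge = sum(p / (i^2 * j^2)),
    srhge = sum(p * i^2 / j^2),
    lrlge = sum(p * j^2 / i^2),
    lrhge = sum(p * i^2 * j^2),
    glv = sum(p * (i - mui)^2),
    rlv = sum(p * (j - muj)^2))
}

#' GLRLM features
#'
#' The 13 run-length features: short/long run emphasis, gray-level and
#' run-length non-uniformity, run percentage, low/high gray-level run
#' emphasis, the four joint emphases, and gray-level / run-length variance.
#'
#' @param m A `texture_matrix` of kind `"GLRLM"`.
#' @return Named numeric vector of 13 features (names `glrlm.*`).
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$kind == "GLRLM")
  out <- .rl_features(m$matrix, m$n_pixels)
  names(out) <- .glrlm_names
  out
}

#' Gray-level size-zone matrix
#'
#' Counts connected zones of equal-level in-mask pixels under
#' full-neighborhood (8-connected) adjacency. Entry (i, s) is the number of
#' zones of gray level i and size s pixels.
#'
#' @param q A `quantized_image`.
#' @return A `texture_matrix` (kind `"GLSZM"`).
#' @export
compute_glszm <- function(q) {
  q <- .as_quantized(q)
  z <- cpp_zones(q$labels)
  maxs <- max(z[, 2])
  counts <- matrix(0, q$L, maxs)
  for (k in seq_len(nrow(z))) {
    counts[z[k, 1], z[k, 2]] <- counts[z[k, 1], z[k, 2]] + 1
  }
  structure(list(kind = "GLSZM", matrix = counts, L = q$L,
                 direction = NA_character_, n_pixels = sum(q$labels > 0)),
            class = "texture_matrix")
}

#' GLSZM features
#'
#' The 13 size-zone features, analogous to the run-length family with zone
#' size replacing run length (small/large zone emphasis, non-uniformities,
#' zone percentage, gray-level emphases, joint emphases, variances).
#'
#' @param m A `texture_matrix` of kind `"GLSZM"`.
#' @return Named numeric vector of 13 features (names `glszm.*`).
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$kind == "GLSZM")
  out <- .rl_features(m$matrix, m$n_pixels)
  names(out) <- .glszm_names
  out
}

#' Neighborhood gray-tone difference matrix
#'
#' For each gray level i, accumulates over in-mask pixels of level i with at
#' least one in-mask 8-neighbor: the pixel count `n_i` and the sum `s_i` of
#' absolute differences between i and the mean level of the pixel's in-mask
#' neighbors.
#'
#' @param q A `quantized_image`.
#' @return A `texture_matrix` (kind `"NGTDM"`) with per-level vectors `n`
#'   and `s`.
#' @export
compute_ngtdm <- function(q) {
  q <- .as_quantized(q)
  parts <- cpp_ngtdm_parts(q$labels, q$L)
  structure(list(kind = "NGTDM", n = parts$n, s = parts$s, L = q$L,
                 direction = NA_character_),
            class = "texture_matrix")
}

#' NGTDM features
#'
#' Coarseness, contrast, busyness, complexity and strength
#' (Amadasun-King). Denominators that can vanish (coarseness, busyness,
#' strength) are guarded by epsilon = 1e-6; a single-occupied-level image
#' has contrast 0 by convention.
#'
#' @param m A `texture_matrix` of kind `"NGTDM"`.
#' @return Named numeric vector of 5 features (names `ngtdm.*`).
#' @export
ngtdm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$kind == "NGTDM")
  eps <- .ngtdm_eps
  n <- m$n; s <- m$s
  N <- sum(n)
  if (N == 0) stop("no pixel with an in-mask neighbor")
  p <- n / N
  lev <- seq_along(p)
  occ <- which(p > 0)
  ng <- length(occ)

  coarseness <- 1 / (eps + sum(p * s))

  contrast <- if (ng < 2) 0 else {
    pi <- p[occ]; li <- lev[occ]
    (sum(outer(pi, pi) * outer(li, li, "-")^2) / (ng * (ng - 1))) *
      (sum(s) / N)
  }

  busyness <- if (ng < 2) 0 else {
    ip <- lev[occ] * p[occ]
    denom <- sum(abs(outer(ip, ip, "-")))
    sum(p * s) / (eps + denom)
  }

  complexity <- if (ng < 2) 0 else {
    pi <- p[occ]; si <- s[occ]; li <- lev[occ]
    num <- abs(outer(li, li, "-")) *
      (outer(pi * si, pi * si, "+")) / (N * outer(pi, pi, "+"))
    sum(num)
  }

  strength <- if (ng < 2) 0 else {
    pi <- p[occ]; li <- lev[occ]
    sum(outer(pi, pi, "+") * outer(li, li, "-")^2) / (eps + sum(s))
  }

  out <- c(coarseness = coarseness, contrast = contrast, busyness = busyness,
           complexity = complexity, strength = strength)
  names(out) <- .ngtdm_names
  out
}

#' Aggregated image-domain texture features
#'
#' Computes the 52 texture features of a masked image: at each
#' discretization level of the sweep the four texture matrices are built,
#' features are computed per direction for GLCM and GLRLM and averaged over
#' the directions that contain at least one valid pair/run, then every
#' feature is averaged over the levels of the sweep.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical (or 0/1) matrix, same shape.
#' @param levels Integer vector of discretization level counts.
#' @return Named numeric vector of 52 features.
#' @export
aggregate_texture <- function(image, mask, levels = .default_levels) {
  sweep <- level_sweep(image, mask, levels)
  per_level <- vapply(sweep, texture_features_single_level,
                      numeric(length(texture_feature_names())))
  rowMeans(per_level)
}

#' Texture features at a single discretization
#'
#' The 52 texture features of one quantized image: direction-averaged GLCM
#' and GLRLM features plus GLSZM and NGTDM features. Used by
#' [aggregate_texture()] and by the discretization-stability study, which
#' needs per-level values before averaging.
#'
#' @param q A `quantized_image`.
#' @return Named numeric vector of 52 features.
#' @export
texture_features_single_level <- function(q) {
  dirs <- names(.glcm_directions)
  avg_dirs <- function(compute, extract) {
    vals <- list()
    for (d in dirs) {
      m <- tryCatch(compute(q, d), error = function(e) NULL)
      if (!is.null(m)) vals[[d]] <- extract(m)
    }
    if (length(vals) == 0) stop("no direction with a valid pair/run")
    rowMeans(do.call(cbind, vals))
  }
  c(avg_dirs(compute_glcm, glcm_features),
    avg_dirs(compute_glrlm, glrlm_features),
    glszm_features(compute_glszm(q)),
    ngtdm_features(compute_ngtdm(q)))
}
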