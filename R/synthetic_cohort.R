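## Synthetic two-class tumor phantom generator. Benign lesions are smaller,
## rounder and enhance near-uniformly; malignant lesions are larger, more
## lobulated and show a smooth spatially heterogeneous enhancement field
## crossed by bright septa-like line structures. Two observer masks per
## subject are produced by smooth radial boundary perturbation, and a
## per-vendor linear gain/offset emulates scanner-dependent intensity
## scaling. Everything is deterministic given the cohort seed: each subject
## draws from its own RNG stream derived from (seed, subject index).

#' Cohort specification for the phantom generator
#'
#' Bundles and validates the generator parameters. Defaults emulate the
#' study cohort: 40 benign / 41 malignant subjects, ~0.8 mm pixels,
#' malignant lesions larger (radius 15-25 mm vs 8-15 mm), more lobulated,
#' with a heterogeneous enhancement field and 3 septa.
#'
#' @param n_benign,n_malignant Subjects per class.
#' @param image_size Square image side in pixels (>= 32).
#' @param pixel_spacing_mm Isotropic pixel spacing in mm.
#' @param benign_radius_range,malignant_radius_range Lesion radius intervals
#'   in mm; the malignant midpoint must exceed the benign one.
#' @param lobulation_amplitude Named (benign, malignant) radial modulation
#'   amplitudes in `[0, 1)`.
#' @param n_lobes Named (benign, malignant) dominant lobe counts.
#' @param septa_count Named (benign, malignant) numbers of septa.
#' @param texture_noise_sd Named (benign, malignant) Gaussian intensity
#'   noise SDs.
#' @param field_amplitude Named (benign, malignant) SDs of the smooth
#'   heterogeneous enhancement field.
#' @param base_intensity Mean enhancement inside the lesion.
#' @param septa_brightness,septa_width_px Septa intensity boost and Gaussian
#'   cross-profile width.
#' @param observer_jitter_px Boundary perturbation SD (pixels) for the
#'   second observer's mask.
#' @param vendor_labels Data frame with columns `vendor`, `gain`, `offset`;
#'   vendors are assigned cyclically over subjects.
#' @param seed Integer cohort seed.
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_benign = 40L, n_malignant = 41L,
                        image_size = 96L, pixel_spacing_mm = 0.8,
                        benign_radius_range = c(8, 15),
                        malignant_radius_range = c(15, 25),
                        lobulation_amplitude = c(benign = 0.08, malignant = 0.35),
                        n_lobes = c(benign = 3L, malignant = 6L),
                        septa_count = c(benign = 0L, malignant = 3L),
                        texture_noise_sd = c(benign = 20, malignant = 20),
                        field_amplitude = c(benign = 0, malignant = 120),
                        base_intensity = 400,
                        septa_brightness = 150,
                        septa_width_px = 1.5,
                        observer_jitter_px = 1.5,
                        vendor_labels = data.frame(
                          vendor = c("siemens", "ge", "philips", "toshiba"),
                          gain = c(1.00, 1.15, 0.90, 1.05),
                          offset = c(0, 10, -5, 5)),
                        seed = 1L) {
  stopifnot(n_benign >= 0, n_malignant >= 0, image_size >= 32,
            pixel_spacing_mm > 0, observer_jitter_px >= 0,
            all(lobulation_amplitude >= 0), all(lobulation_amplitude < 1),
            all(c("vendor", "gain", "offset") %in% names(vendor_labels)))
  if (mean(malignant_radius_range) <= mean(benign_radius_range))
    stop("malignant radius interval midpoint must exceed the benign one")
  structure(list(
    n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
    image_size = as.integer(image_size),
    pixel_spacing_mm = pixel_spacing_mm,
    benign_radius_range = benign_radius_range,
    malignant_radius_range = malignant_radius_range,
    lobulation_amplitude = lobulation_amplitude,
    n_lobes = n_lobes, septa_count = septa_count,
    texture_noise_sd = texture_noise_sd,
    field_amplitude = field_amplitude,
    base_intensity = base_intensity,
    septa_brightness = septa_brightness,
    septa_width_px = septa_width_px,
    observer_jitter_px = observer_jitter_px,
    vendor_labels = vendor_labels,
    seed = as.integer(seed)), class = "cohort_spec")
}

# smooth periodic modulation profile: random low-order Fourier series over
# theta, normalized to max |f| = 1 (consumes the current RNG stream)
.radial_profile <- function(theta, n_lobes) {
  ks <- unique(pmax(2L, c(n_lobes - 1L, n_lobes, n_lobes + 1L)))
  w <- c(0.4, 1, 0.4)[seq_along(ks)] * stats::rnorm(length(ks), 1, 0.2)
  ph <- stats::runif(length(ks), 0, 2 * pi)
  f <- function(th) {
    out <- 0
    for (q in seq_along(ks)) out <- out + w[q] * sin(ks[q] * th + ph[q])
    out
  }
  grid <- seq(0, 2 * pi, length.out = 720)
  nrm <- max(abs(f(grid)))
  f(theta) / nrm
}

#' Generate a lobulated tumor mask
#'
#' Builds a binary mask whose boundary is the radial curve
#' `r(theta) = radius * (1 + amplitude * f(theta))` with `f` a normalized
#' random low-order sinusoid mixture dominated by `n_lobes` lobes;
#' `amplitude = 0` gives a circle. The construction is star-shaped, so the
#' mask is a single connected component. Consumes the current RNG stream.
#'
#' @param center `(row, col)` center in pixels.
#' @param radius_mm Mean radius in mm (> 0).
#' @param lobulation_amplitude Radial modulation amplitude in `[0, 1)`.
#' @param n_lobes Dominant lobe count.
#' @param spacing Pixel spacing in mm (isotropic scalar or length 2).
#' @param size Square image side in pixels.
#' @return Logical mask matrix. Errors if the mask would come within 2 px
#'   of the image border (shape features would be undefined).
#' @export
generate_mask <- function(center, radius_mm, lobulation_amplitude = 0,
                          n_lobes = 5L, spacing = 1, size = 96L) {
  stopifnot(radius_mm > 0, lobulation_amplitude >= 0, lobulation_amplitude < 1)
  spacing <- rep(as.numeric(spacing), length.out = 2)
  radius_px <- radius_mm / mean(spacing)
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  dr <- rows - center[1]
  dc <- cols - center[2]
  d <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  r_theta <- if (lobulation_amplitude > 0) {
    radius_px * (1 + lobulation_amplitude * .radial_profile(theta, n_lobes))
  } else {
    matrix(radius_px, size, size)
  }
  mask <- d <= r_theta
  if (!any(mask)) stop("empty mask")
  px <- which(mask, arr.ind = TRUE)
  if (min(px) <= 2 || max(px[, 1]) >= size - 1 || max(px[, 2]) >= size - 1)
    stop("mask touches the image border")
  mask
}

#' Perturb a mask boundary (second-observer emulation)
#'
#' Displaces the mask boundary by a smooth random radial field with
#' standard deviation `jitter_px` pixels; `jitter_px = 0` returns the input
#' unchanged. The mask's radial boundary profile around its centroid is
#' estimated in angular bins and the perturbed mask keeps the star-shaped
#' (hence connected) construction. Consumes the current RNG stream.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param jitter_px Non-negative boundary displacement SD in pixels.
#' @return Perturbed logical mask; errors if the perturbation empties the
#'   mask or pushes it into the image border.
#' @export
perturb_mask <- function(mask, jitter_px) {
  m <- .stopifnot_mask(mask)
  stopifnot(jitter_px >= 0)
  if (jitter_px == 0) return(m)
  px <- which(m, arr.ind = TRUE)
  ctr <- colMeans(px)
  nr <- nrow(m); nc <- ncol(m)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- rows - ctr[1]; dc <- cols - ctr[2]
  d <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)

  # radial boundary profile in angular bins, circularly interpolated
  nbin <- 72L
  bin <- pmin(nbin, 1L + as.integer(floor((theta + pi) / (2 * pi) * nbin)))
  rad <- rep(NA_real_, nbin)
  bin_mask <- bin[m]
  d_mask <- d[m]
  for (b in unique(bin_mask)) rad[b] <- max(d_mask[bin_mask == b])
  if (anyNA(rad)) {  # fill empty bins by nearest occupied bin (circular)
    occ <- which(!is.na(rad))
    for (b in which(is.na(rad))) {
      dd <- pmin(abs(occ - b), nbin - abs(occ - b))
      rad[b] <- rad[occ[which.min(dd)]]
    }
  }

  # smooth random radial displacement with SD jitter_px
  a <- stats::rnorm(3); bcoef <- stats::rnorm(3)
  g <- function(th) {
    out <- 0
    for (k in 1:3) out <- out + a[k] * cos(k * th) + bcoef[k] * sin(k * th)
    out
  }
  grid <- seq(0, 2 * pi, length.out = 720)
  delta <- function(th) jitter_px * g(th) / .pop_sd(g(grid))

  # circular linear interpolation of the bin profile
  centers <- (seq_len(nbin) - 0.5) / nbin * 2 * pi - pi
  interp_rad <- function(th) {
    pos <- (th + pi) / (2 * pi) * nbin - 0.5
    i0 <- floor(pos)
    w <- pos - i0
    idx0 <- ((as.integer(i0) %% nbin) + nbin) %% nbin + 1L
    idx1 <- (idx0 %% nbin) + 1L
    (1 - w) * rad[idx0] + w * rad[idx1]
  }

  out <- d <= interp_rad(theta) + delta(theta)
  if (!any(out)) stop("perturbation emptied the mask")
  opx <- which(out, arr.ind = TRUE)
  if (min(opx) <= 1 || max(opx[, 1]) >= nr || max(opx[, 2]) >= nc)
    stop("perturbed mask touches the image border")
  out
}

# smooth standardized random field over the grid (unit SD inside the mask)
.smooth_field <- function(nr, nc, mask, sigma = 6) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  hw <- as.integer(ceiling(3 * sigma))
  u <- (-hw):hw
  g <- as.complex(exp(-u^2 / (2 * sigma^2)))
  sm <- Re(cpp_sepconv_valid(.reflect_pad(z, hw), g, g))
  v <- sm[mask]
  (sm - mean(v)) / .pop_sd(v)
}

#' Generate the enhancement texture for a phantom
#'
#' Benign lesions get near-uniform enhancement plus Gaussian noise;
#' malignant lesions additionally get a smooth heterogeneous enhancement
#' field and bright anti-aliased septa-like line structures crossing the
#' lesion near its centroid. The vendor effect is a linear gain/offset on
#' the intensities; the background outside the mask is small positive
#' noise. Consumes the current RNG stream.
#'
#' @param mask Logical lesion mask.
#' @param class_label `"benign"` or `"malignant"`.
#' @param spec A `cohort_spec` providing intensity parameters.
#' @param gain,offset Vendor intensity scaling.
#' @return Numeric intensity matrix of the same shape as `mask`.
#' @export
generate_texture <- function(mask, class_label = c("benign", "malignant"),
                             spec = cohort_spec(), gain = 1, offset = 0) {
  m <- .stopifnot_mask(mask)
  class_label <- match.arg(class_label)
  nr <- nrow(m); nc <- ncol(m)
  img <- matrix(0, nr, nc)

  noise_sd <- spec$texture_noise_sd[[class_label]]
  famp <- spec$field_amplitude[[class_label]]
  img[m] <- spec$base_intensity

  if (famp > 0) img[m] <- img[m] + famp * .smooth_field(nr, nc, m)[m]

  nsep <- spec$septa_count[[class_label]]
  if (nsep > 0) {
    px <- which(m, arr.ind = TRUE)
    ctr <- colMeans(px)
    rad <- max(sqrt((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (k in seq_len(nsep)) {
      # line through a point near the centroid with random orientation
      p0 <- ctr + stats::rnorm(2, 0, 0.25 * rad)
      ang <- stats::runif(1, 0, pi)
      nvec <- c(-sin(ang), cos(ang))  # unit normal to the line
      dist_line <- abs((rows - p0[1]) * nvec[1] + (cols - p0[2]) * nvec[2])
      boost <- spec$septa_brightness *
        exp(-dist_line^2 / (2 * spec$septa_width_px^2))
      img[m] <- img[m] + boost[m]
    }
  }

  if (noise_sd > 0) img[m] <- img[m] + stats::rnorm(sum(m), 0, noise_sd)
  img[!m] <- abs(stats::rnorm(sum(!m), 0, 1)) + 0.5
  gain * img + offset
}

#' Generate a reproducible phantom cohort
#'
#' Produces `n_benign + n_malignant` phantom subjects (image, two observer
#' masks, class, vendor). Each subject uses its own RNG stream derived from
#' `(seed, subject index)`, so the cohort is bit-identical across runs with
#' the same spec and stable under subject reordering. Vendors are assigned
#' cyclically.
#'
#' @param spec A `cohort_spec`.
#' @return A `phantom_cohort`: list of `phantom_subject` objects, each with
#'   `image`, `mask_obs1`, `mask_obs2`, `class_label`, `vendor`,
#'   `pixel_spacing_mm`, `subject_id`; the spec is attached as an attribute.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_benign + spec$n_malignant
  classes <- rep(c("benign", "malignant"), c(spec$n_benign, spec$n_malignant))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  streams <- sample.int(.Machine$integer.max - 1L, n)
  vend <- spec$vendor_labels
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(streams[i])
    cl <- classes[i]
    rng_range <- if (cl == "benign") spec$benign_radius_range else spec$malignant_radius_range
    radius <- stats::runif(1, rng_range[1], rng_range[2])
    ctr <- spec$image_size / 2 + stats::runif(2, -3, 3)
    mask1 <- generate_mask(ctr, radius,
                           spec$lobulation_amplitude[[cl]],
                           spec$n_lobes[[cl]],
                           spec$pixel_spacing_mm, spec$image_size)
    mask2 <- perturb_mask(mask1, spec$observer_jitter_px)
    vrow <- vend[((i - 1L) %% nrow(vend)) + 1L, ]
    image <- generate_texture(mask1, cl, spec, vrow$gain, vrow$offset)
    subjects[[i]] <- structure(list(
      image = image, mask_obs1 = mask1, mask_obs2 = mask2,
      class_label = cl, vendor = as.character(vrow$vendor),
      pixel_spacing_mm = spec$pixel_spacing_mm,
      subject_id = sprintf("S%03d", i)), class = "phantom_subject")
  }
  structure(subjects, spec = spec, class = "phantom_cohort")
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b Logical (or 0/1) matrices of the same shape.
#' @return `2|A  B| / (|A| + |B|)`.
#' @export
dice_coefficient <- function(a, b) {
  a <- a != 0; b <- b != 0
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
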