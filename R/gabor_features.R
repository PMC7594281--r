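## Frequency-domain texture via a Gabor filter bank: 5 wavelengths in a
## sqrt(2) progression from 3 px, 6 orientations at 30-degree steps,
## 1-octave bandwidth, isotropic Gaussian envelope. Kernels are DC-corrected
## so a constant image gives (numerically) zero response. Because the
## envelope is isotropic, each complex kernel factorizes into two 1D complex
## kernels; filtering is a separable valid-mode convolution on a
## reflect-padded image.

# sigma of the Gaussian envelope for a given wavelength and octave bandwidth
.gabor_sigma <- function(wavelength, bandwidth = 1) {
  wavelength / pi * sqrt(log(2) / 2) * (2^bandwidth + 1) / (2^bandwidth - 1)
}

#' Build a Gabor filter bank
#'
#' Constructs `n_scales * n_orientations` complex Gabor kernels with
#' wavelengths `min_wavelength * sqrt(2)^(s-1)` (s = 1..n_scales),
#' orientations `k * pi / n_orientations` (k = 0..n_orientations-1), a
#' 1-octave Gaussian envelope truncated at 3 sigma, and DC correction
#' (a scaled envelope is subtracted so each kernel sums to zero).
#'
#' @param min_wavelength Smallest wavelength in pixels (>= 2).
#' @param n_scales Number of scales.
#' @param n_orientations Number of orientations.
#' @param bandwidth Half-response spatial-frequency bandwidth in octaves.
#' @return An object of class `gabor_bank`: list with `kernels` (list of
#'   complex matrices indexed `[[scale]][[orientation]]`), `wavelengths`,
#'   `orientations` (radians), `halfwidths`, and the 1D factor kernels used
#'   by the separable filtering path.
#' @export
build_gabor_bank <- function(min_wavelength = 3, n_scales = 5,
                             n_orientations = 6, bandwidth = 1) {
  if (min_wavelength < 2) stop("min_wavelength must be >= 2")
  lambdas <- min_wavelength * sqrt(2)^(seq_len(n_scales) - 1)
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  kernels <- vector("list", n_scales)
  factors <- vector("list", n_scales)
  hw <- integer(n_scales)
  for (s in seq_len(n_scales)) {
    sigma <- .gabor_sigma(lambdas[s], bandwidth)
    hw[s] <- as.integer(ceiling(3 * sigma))
    u <- (-hw[s]):hw[s]
    env1d <- exp(-u^2 / (2 * sigma^2))
    kernels[[s]] <- vector("list", n_orientations)
    factors[[s]] <- vector("list", n_orientations)
    for (k in seq_len(n_orientations)) {
      # x along columns, y along rows; wave vector (cos theta, sin theta)
      kc <- env1d * exp(1i * 2 * pi * u * cos(thetas[k]) / lambdas[s])
      kr <- env1d * exp(1i * 2 * pi * u * sin(thetas[k]) / lambdas[s])
      kern <- outer(kr, kc)  # rows = y, cols = x
      env2d <- outer(env1d, env1d)
      dc <- sum(kern) / sum(env2d)
      kern <- kern - dc * env2d
      kernels[[s]][[k]] <- kern
      # separable DC-corrected response: gabor response minus dc * envelope
      # response, both separable
      factors[[s]][[k]] <- list(kr = kr, kc = kc, dc = dc,
                                env = as.complex(env1d))
    }
  }
  structure(list(kernels = kernels, factors = factors,
                 wavelengths = lambdas, orientations = thetas,
                 halfwidths = hw, bandwidth = bandwidth),
            class = "gabor_bank")
}

# reflect-pad a matrix by hw pixels on every side
.reflect_pad <- function(x, hw) {
  nr <- nrow(x); nc <- ncol(x)
  if (hw >= nr || hw >= nc) stop("mask/image smaller than kernel support")
  ridx <- c(rev(seq_len(hw) + 1L), seq_len(nr), nr - seq_len(hw))
  cidx <- c(rev(seq_len(hw) + 1L), seq_len(nc), nc - seq_len(hw))
  x[ridx, cidx]
}

# magnitude of the DC-corrected Gabor response of an image for one
# (scale, orientation), reflect boundary handling; env_resp is the (real)
# envelope response shared by all orientations of the scale
.gabor_magnitude <- function(pad, fac, env_resp) {
  resp <- cpp_sepconv_valid(pad, fac$kr, fac$kc)
  Mod(resp - fac$dc * env_resp)
}

#' Gabor filter-bank features
#'
#' Convolves the image with each kernel of the bank (reflect padding),
#' takes the response magnitude, and for each scale averages the mean and
#' the (population) variance of the magnitudes over masked pixels across
#' the orientations: 5 scales x 2 statistics = 10 features.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical (or 0/1) matrix, same shape.
#' @param bank A `gabor_bank`; the default bank follows the pipeline
#'   settings (5 scales, 6 orientations, minimal wavelength 3).
#' @return Named numeric vector of 10 features (names `gabor.s<k>.mean`,
#'   `gabor.s<k>.var`).
#' @export
gabor_features <- function(image, mask, bank = build_gabor_bank()) {
  m <- .stopifnot_mask(mask)
  if (!identical(dim(image), dim(m))) stop("image and mask shapes differ")
  if (!inherits(bank, "gabor_bank")) stop("bank must be a gabor_bank")
  n_scales <- length(bank$wavelengths)
  out <- numeric(2 * n_scales)
  for (s in seq_len(n_scales)) {
    hw <- bank$halfwidths[s]
    pad <- .reflect_pad(image, hw)
    env <- bank$factors[[s]][[1]]$env
    env_resp <- cpp_sepconv_valid(pad, env, env)
    mu <- va <- numeric(length(bank$factors[[s]]))
    for (k in seq_along(bank$factors[[s]])) {
      mag <- .gabor_magnitude(pad, bank$factors[[s]][[k]], env_resp)
      vals <- mag[m]
      mu[k] <- mean(vals)
      va[k] <- .pop_var(vals)
    }
    out[2 * s - 1] <- mean(mu)
    out[2 * s] <- mean(va)
  }
  names(out) <- .gabor_names
  out
}
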