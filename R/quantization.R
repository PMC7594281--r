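#' Equal-probability gray-level quantization
#'
#' Discretizes the intensities inside a mask into `L` gray levels using
#' decision thresholds at the k/L-quantiles (k = 1..L-1) of the masked
#' intensity multiset, so that every level receives the same number of
#' pixels up to ties. Quantiles are order statistics (type 1, no
#' interpolation); bins are right-closed, i.e. a pixel is assigned level
#' `1 + #\{thresholds < value\}`. Equal intensities always map to the same
#' level, even when this unbalances the bins.
#'
#' @param image Numeric matrix of intensities.
#' @param mask Logical (or 0/1) matrix of the same shape; `TRUE` = tumor.
#' @param L Number of gray levels (>= 2).
#' @return An object of class `quantized_image`: list with `labels`
#'   (integer matrix, values 1..L inside the mask, 0 outside), `L`, and
#'   `constant` (flag set when the masked intensities are constant, in
#'   which case every pixel gets level 1 and a warning is issued).
#' @examples
#' img <- matrix(1:16, 4, 4)
#' q <- equal_probability_quantize(img, matrix(TRUE, 4, 4), 4)
#' table(q$labels)
#' @export
equal_probability_quantize <- function(image, mask, L) {
  m <- .stopifnot_mask(mask)
  if (!identical(dim(image), dim(m))) stop("image and mask shapes differ")
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  v <- image[m]
  if (any(!is.finite(v))) stop("non-finite intensities inside mask")
  if (length(v) < L) stop("mask has fewer pixels (", length(v),
                          ") than gray levels (", L, ")")
  labels <- matrix(0L, nrow(image), ncol(image))
  constant <- FALSE
  if (max(v) == min(v)) {
    constant <- TRUE
    warning("constant intensities inside mask: all pixels assigned level 1")
    labels[m] <- 1L
  } else {
    thr <- quantile(v, probs = seq_len(L - 1L) / L, type = 1, names = FALSE)
    lev <- rep(1L, length(v))
    for (t in thr) lev <- lev + (v > t)
    labels[m] <- lev
  }
  structure(list(labels = labels, L = L, constant = constant),
            class = "quantized_image")
}

#' Quantize an image at a sweep of gray-level counts
#'
#' Applies [equal_probability_quantize()] at each level count of the sweep
#' (ascending), returning one quantized image per level. The default sweep
#' is 8, 16, 24, 32, 40, 48 and 64 levels; texture features are later
#' averaged over the sweep.
#'
#' @inheritParams equal_probability_quantize
#' @param levels Integer vector of level counts.
#' @return Named list of `quantized_image` objects, one per level.
#' @export
level_sweep <- function(image, mask, levels = .default_levels) {
  levels <- sort(unique(as.integer(levels)))
  m <- .stopifnot_mask(mask)
  if (sum(m) < max(levels))
    stop("mask smaller than the largest level count")
  out <- lapply(levels, function(L) equal_probability_quantize(image, mask, L))
  names(out) <- paste0("L", levels)
  out
}
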