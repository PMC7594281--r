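# Shared fixtures: simple masks, label images and small feature tables,
# all built in code at test time.

disc_mask <- function(radius, size = 2 * radius + 9, center = NULL) {
  if (is.null(center)) center <- c(size, size) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  sqrt((rows - center[1])^2 + (cols - center[2])^2) <= radius
}

# wrap an integer label matrix (0 = outside mask) as a quantized image
as_quantized <- function(labels, L = max(labels)) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, L = as.integer(L), constant = FALSE),
            class = "quantized_image")
}

# random label image: every pixel in the mask gets a uniform level in 1..L
rand_labels <- function(nr, nc, L, mask = matrix(TRUE, nr, nc)) {
  lab <- matrix(0L, nr, nc)
  lab[mask] <- sample.int(L, sum(mask), replace = TRUE)
  lab
}

# two-class feature table with n subjects per class for classifier tests;
# informative features shift by delta in the malignant class
toy_table <- function(n_per_class, features, delta = rep(0, length(features))) {
  n <- 2 * n_per_class
  cls <- rep(c("benign", "malignant"), each = n_per_class)
  tab <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    observer = 1L, class_label = cls,
                    vendor = "siemens", stringsAsFactors = FALSE)
  for (k in seq_along(features)) {
    x <- rnorm(n)
    x[cls == "malignant"] <- x[cls == "malignant"] + delta[k]
    tab[[features[k]]] <- x
  }
  tab
}
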