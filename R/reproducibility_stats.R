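## Inter-observer agreement per feature (Pearson r, R^2 = r^2 for the
## simple linear regression, Spearman rho) and gray-level-discretization
## stability (coefficient of variation across the level sweep).

#' Pairwise agreement statistics for one feature
#'
#' Pearson correlation, coefficient of determination (the square of the
#' Pearson correlation, as in simple linear regression) and Spearman
#' rank-order correlation (Pearson on mid-ranks, ties averaged) between two
#' observers' paired measurements. Zero variance in either vector makes the
#' correlations undefined: the statistics are `NA` and the `defined` flag is
#' `FALSE` (such a feature is treated as non-reproducible downstream).
#'
#' @param values_obs1,values_obs2 Paired numeric vectors (n >= 3).
#' @return List with `r`, `r_squared`, `rho`, `defined`.
#' @export
pairwise_agreement <- function(values_obs1, values_obs2) {
  x <- as.numeric(values_obs1); y <- as.numeric(values_obs2)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (.pop_sd(x) == 0 || .pop_sd(y) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, rho = NA_real_,
                defined = FALSE))
  r <- cor(x, y)
  rho <- cor(rank(x), rank(y))
  list(r = r, r_squared = r^2, rho = rho, defined = TRUE)
}

#' Inter-observer reproducibility report
#'
#' Computes the agreement statistics of every feature between the two
#' observers of a feature table and flags features as reproducible when the
#' Pearson correlation strictly exceeds the threshold. Also summarizes each
#' feature family (mean, SD, range of each statistic).
#'
#' @param table Feature table with an `observer` column (values 1 and 2)
#'   and one row per (subject, observer).
#' @param r_threshold Reproducibility threshold on Pearson r (default 0.8).
#' @return Object of class `reproducibility_report`: list with `per_feature`
#'   (data.frame `feature, family, r, r_squared, rho, reproducible`) and
#'   `per_family` (data.frame of family summaries).
#' @export
reproducibility_report <- function(table, r_threshold = 0.8) {
  feats <- intersect(feature_names(), names(table))
  if (length(feats) == 0) stop("no feature columns in table")
  o1 <- table[table$observer == 1, , drop = FALSE]
  o2 <- table[table$observer == 2, , drop = FALSE]
  stopifnot(nrow(o1) == nrow(o2), nrow(o1) >= 3)
  o2 <- o2[match(o1$subject_id, o2$subject_id), , drop = FALSE]
  rows <- lapply(feats, function(f) {
    a <- pairwise_agreement(o1[[f]], o2[[f]])
    data.frame(feature = f, family = unname(feature_families(f)),
               r = a$r, r_squared = a$r_squared, rho = a$rho,
               reproducible = isTRUE(a$defined && a$r > r_threshold),
               stringsAsFactors = FALSE)
  })
  per_feature <- do.call(rbind, rows)
  fam_summary <- function(df) {
    summ <- function(v) c(mean = mean(v, na.rm = TRUE),
                          sd = sd(v, na.rm = TRUE),
                          min = suppressWarnings(min(v, na.rm = TRUE)),
                          max = suppressWarnings(max(v, na.rm = TRUE)))
    data.frame(family = df$family[1], n_features = nrow(df),
               n_reproducible = sum(df$reproducible),
               t(c(r = summ(df$r), r_squared = summ(df$r_squared),
                   rho = summ(df$rho))),
               stringsAsFactors = FALSE)
  }
  per_family <- do.call(rbind, lapply(split(per_feature,
                                            per_feature$family), fam_summary))
  structure(list(per_feature = per_feature, per_family = per_family,
                 r_threshold = r_threshold),
            class = "reproducibility_report")
}

#' Coefficient of variation across discretization levels
#'
#' `CV = 100 * SD / |mean|` (population SD) of a feature's values across
#' the gray-level sweep for one subject. A zero mean makes the CV
#' undefined (`NA`).
#'
#' @param per_level_values Numeric vector of one feature's values, one per
#'   discretization level (length >= 2).
#' @return CV in percent, or `NA` if the mean is zero.
#' @export
discretization_cv <- function(per_level_values) {
  v <- as.numeric(per_level_values)
  stopifnot(length(v) >= 2)
  if (any(!is.finite(v))) stop("non-finite values")
  mu <- mean(v)
  if (mu == 0) return(NA_real_)
  100 * .pop_sd(v) / abs(mu)
}

#' Band a CV value
#'
#' CV from 0 to 5% counts as an absence of variation, 5 to 25% as an
#' acceptable variation, and above 25% as unacceptable.
#'
#' @param cv_percent Numeric CV values in percent.
#' @return Character vector: `"none"`, `"acceptable"` or `"unacceptable"`
#'   (`NA` passes through).
#' @export
cv_band <- function(cv_percent) {
  out <- rep(NA_character_, length(cv_percent))
  ok <- !is.na(cv_percent)
  out[ok & cv_percent <= 5] <- "none"
  out[ok & cv_percent > 5 & cv_percent <= 25] <- "acceptable"
  out[ok & cv_percent > 25] <- "unacceptable"
  out
}

#' Gray-level discretization stability study
#'
#' Draws `n_per_group` subjects per class from a cohort, computes the 52
#' image-domain texture features at every discretization level of the
#' sweep (observer-1 mask), takes each subject's CV across levels per
#' feature, and reports the feature-wise mean CV over the sampled subjects
#' with its stability band.
#'
#' @param cohort A `phantom_cohort`.
#' @param n_per_group Subjects sampled per class (default 10).
#' @param levels Discretization level sweep.
#' @param seed Integer seed for the subject draw.
#' @return Object of class `cv_report`: data.frame `feature, family,
#'   cv_percent, band` plus the sampled subject ids as an attribute.
#' @export
cv_study <- function(cohort, n_per_group = 10, levels = .default_levels,
                     seed = 1L) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  cls <- vapply(cohort, function(s) s$class_label, character(1))
  idx_b <- which(cls == "benign"); idx_m <- which(cls == "malignant")
  if (length(idx_b) < n_per_group || length(idx_m) < n_per_group)
    stop("fewer than n_per_group subjects in a class")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  picked <- c(sample(idx_b, n_per_group), sample(idx_m, n_per_group))
  tf <- texture_feature_names()
  cvs <- vapply(picked, function(i) {
    s <- cohort[[i]]
    sweep <- level_sweep(s$image, s$mask_obs1, levels)
    per_level <- vapply(sweep, texture_features_single_level,
                        numeric(length(tf)))
    apply(per_level, 1, discretization_cv)
  }, numeric(length(tf)))
  mean_cv <- rowMeans(cvs)
  out <- data.frame(feature = tf, family = unname(feature_families(tf)),
                    cv_percent = mean_cv, band = cv_band(mean_cv),
                    stringsAsFactors = FALSE)
  structure(out, subjects = vapply(picked, function(i)
    cohort[[i]]$subject_id, character(1)), class = c("cv_report", "data.frame"))
}
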