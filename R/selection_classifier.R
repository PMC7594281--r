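## Feature filtering on relevancy (pooled two-sample t-test) and
## inter-observer reproducibility (Pearson r), z-score standardization,
## linear soft-margin SVM trained by sequential minimal optimization,
## stratified holdout, diagnostic metric panel with unclipped Wald 95% CIs,
## rank-statistic AUROC, and a per-feature vendor ANOVA with Bonferroni
## post-tests.

#' Selection and training configuration
#'
#' @param p_threshold Relevancy threshold: keep features with t-test
#'   p strictly below it (default 0.2).
#' @param r_threshold Reproducibility threshold: keep features with Pearson
#'   r strictly above it (default 0.8).
#' @param C Soft-margin box constraint (default 1).
#' @param train_fraction Training fraction of the stratified holdout
#'   (default 0.75).
#' @param seed Integer seed for the holdout split.
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 0.2, r_threshold = 0.8, C = 1,
                             train_fraction = 0.75, seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r_threshold > 0, r_threshold < 1, C > 0,
            train_fraction > 0, train_fraction < 1)
  structure(list(p_threshold = p_threshold, r_threshold = r_threshold,
                 C = C, train_fraction = train_fraction,
                 seed = as.integer(seed)), class = "selection_config")
}

#' Pooled two-sample t-test p-value
#'
#' Two-sided Student t-test with pooled variance. Degenerate case: zero
#' pooled variance gives p = 1 when the group means are equal and p = 0
#' otherwise.
#'
#' @param benign_values,malignant_values Numeric vectors (each n >= 2).
#' @return Two-sided p-value.
#' @export
two_sample_t_pvalue <- function(benign_values, malignant_values) {
  x <- as.numeric(benign_values); y <- as.numeric(malignant_values)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (any(!is.finite(c(x, y)))) stop("non-finite values")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df = n1 + n2 - 2)
}

#' Dual-criterion feature filter
#'
#' Keeps a feature iff its class-relevancy t-test p-value is strictly below
#' `p_threshold` AND its inter-observer Pearson r is strictly above
#' `r_threshold`. The t-test compares benign vs malignant values of the
#' observer-1 rows; the reproducibility r comes from the report. The result
#' preserves the table's feature order and is fully deterministic.
#'
#' @param table Feature table (rows per subject and observer).
#' @param repro_report A `reproducibility_report` covering the same
#'   features (error if any table feature is missing from it).
#' @param config A `selection_config`.
#' @return Character vector of selected feature names, with a `details`
#'   attribute (data.frame of p and r per feature).
#' @export
dual_filter <- function(table, repro_report, config = selection_config()) {
  stopifnot(inherits(repro_report, "reproducibility_report"))
  feats <- intersect(names(table), feature_names())
  if (length(feats) == 0) stop("no feature columns in table")
  missing <- setdiff(feats, repro_report$per_feature$feature)
  if (length(missing) > 0)
    stop("features missing from reproducibility report: ",
         paste(missing, collapse = ", "))
  o1 <- table[table$observer == 1, , drop = FALSE]
  benign <- o1[o1$class_label == "benign", , drop = FALSE]
  malignant <- o1[o1$class_label == "malignant", , drop = FALSE]
  p <- vapply(feats, function(f)
    two_sample_t_pvalue(benign[[f]], malignant[[f]]), numeric(1))
  r <- repro_report$per_feature$r[
    match(feats, repro_report$per_feature$feature)]
  keep <- !is.na(r) & p < config$p_threshold & r > config$r_threshold
  out <- feats[keep]
  attr(out, "details") <- data.frame(feature = feats, p_value = p,
                                     pearson_r = r, selected = keep,
                                     stringsAsFactors = FALSE)
  out
}

# Sequential minimal optimization for the linear soft-margin SVM dual.
# Deterministic maximal-violating-pair working-set selection; stops when the
# KKT violation gap m - M falls below tol. Returns alpha and bias.
.smo_solve <- function(K, y, C, tol = 1e-3, max_iter = 100000L) {
  n <- length(y)
  alpha <- numeric(n)
  G <- numeric(n)  # sum_k alpha_k y_k K[, k]
  for (it in seq_len(max_iter)) {
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    viol <- y - G  # -y_i * grad_i
    if (!any(up) || !any(lo)) break
    m <- max(viol[up]); M <- min(viol[lo])
    if (m - M <= tol) break
    i <- which(up)[which.max(viol[up])]
    j <- which(lo)[which.min(viol[lo])]
    Ei <- G[i] - y[i]; Ej <- G[j] - y[j]
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    aj_old <- alpha[j]; ai_old <- alpha[i]
    aj <- aj_old + y[j] * (Ei - Ej) / eta
    if (y[i] != y[j]) {
      L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
    }
    aj <- min(max(aj, L), H)
    ai <- ai_old + y[i] * y[j] * (aj_old - aj)
    dG <- y[i] * (ai - ai_old) * K[, i] + y[j] * (aj - aj_old) * K[, j]
    alpha[i] <- ai; alpha[j] <- aj
    G <- G + dG
  }
  viol <- y - G
  up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
  lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) mean(viol[free])
       else (max(viol[up]) + min(viol[lo])) / 2
  list(alpha = alpha, b = b)
}

#' Train a linear SVM by sequential minimal optimization
#'
#' Standardizes the selected features to zero mean and unit SD using the
#' training data only (constant features are dropped with a warning), then
#' solves the soft-margin dual with box constraint `C` by SMO (deterministic
#' maximal-KKT-violation pair selection, tolerance 1e-3). The decision value
#' is `f(x) = w . z(x) + b` on the standardized scale; `f > 0` predicts
#' malignant.
#'
#' @param train_table Feature table rows used for training (both classes
#'   present).
#' @param selected Character vector of feature names to use.
#' @param config A `selection_config` (provides `C`).
#' @param tol SMO stopping tolerance on the KKT violation gap.
#' @return A `model_bundle`: list with `selected_features`, `center`,
#'   `scale`, `w`, `b`.
#' @export
train_svm <- function(train_table, selected, config = selection_config(),
                      tol = 1e-3) {
  stopifnot(length(selected) >= 1,
            all(selected %in% names(train_table)))
  y <- ifelse(train_table$class_label == "malignant", 1, -1)
  if (length(unique(y)) < 2) stop("both classes must be present in training data")
  X <- as.matrix(train_table[, selected, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, .pop_sd)
  const <- scl == 0
  if (any(const)) {
    warning("dropping constant features: ",
            paste(selected[const], collapse = ", "))
    selected <- selected[!const]
    X <- X[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]
    if (length(selected) == 0) stop("all selected features constant")
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  K <- Z %*% t(Z)
  fit <- .smo_solve(K, y, config$C, tol)
  w <- as.numeric(t(Z) %*% (fit$alpha * y))
  structure(list(selected_features = selected, center = ctr, scale = scl,
                 w = w, b = fit$b, C = config$C),
            class = "model_bundle")
}

#' SVM decision values
#'
#' @param bundle A `model_bundle`.
#' @param table Feature table rows to score.
#' @return Numeric decision values; positive predicts malignant.
#' @export
decision_values <- function(bundle, table) {
  stopifnot(inherits(bundle, "model_bundle"),
            all(bundle$selected_features %in% names(table)))
  X <- as.matrix(table[, bundle$selected_features, drop = FALSE])
  Z <- sweep(sweep(X, 2, bundle$center), 2, bundle$scale, "/")
  as.numeric(Z %*% bundle$w + bundle$b)
}

#' Stratified holdout split
#'
#' Splits a per-subject table into train and test sets preserving the class
#' ratio: per class, `round(train_fraction * n)` subjects are drawn for
#' training (capped so that at least one test subject remains). Disjoint,
#' exhaustive and deterministic given the seed.
#'
#' @param table Per-subject table with a `class_label` column.
#' @param train_fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames.
#' @export
stratified_holdout <- function(table, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx_train <- integer(0)
  for (cl in unique(table$class_label)) {
    idx <- which(table$class_label == cl)
    if (length(idx) < 2) stop("class ", cl, " has fewer than 2 subjects")
    n_train <- min(round(train_fraction * length(idx)), length(idx) - 1L)
    n_train <- max(n_train, 1L)
    idx_train <- c(idx_train, sort(sample(idx, n_train)))
  }
  idx_train <- sort(idx_train)
  list(train = table[idx_train, , drop = FALSE],
       test = table[-idx_train, , drop = FALSE])
}

#' Diagnostic metric panel from confusion counts
#'
#' Sensitivity, specificity, PPV, NPV and accuracy in percent (malignant is
#' the positive class), each with an unclipped Wald 95% confidence interval
#' `p +/- 1.96 sqrt(p(1-p)/m)` where `m` is the denominator of the rate;
#' bounds may exceed 0-100%. A rate with a zero denominator is flagged
#' undefined rather than propagated as NaN.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Data frame with `metric`, `value`, `ci_low`, `ci_high` (percent)
#'   and `defined`.
#' @export
metric_panel <- function(tp, fp, tn, fn) {
  rate <- function(num, den) {
    if (den == 0) return(c(NA_real_, NA_real_, NA_real_))
    p <- num / den
    half <- 1.96 * sqrt(p * (1 - p) / den)
    100 * c(p, p - half, p + half)
  }
  vals <- rbind(
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    accuracy = rate(tp + tn, tp + fp + tn + fn))
  data.frame(metric = rownames(vals), value = vals[, 1],
             ci_low = vals[, 2], ci_high = vals[, 3],
             defined = !is.na(vals[, 1]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUROC of decision values against binary
#' labels; tied values count 1/2.
#'
#' @param decision Numeric decision values (higher = more malignant).
#' @param labels Class labels; `"malignant"` (or `TRUE`/1) is positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(decision, labels) {
  pos <- if (is.character(labels) || is.factor(labels))
    labels == "malignant" else labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC")
  r <- rank(decision)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained model on a test set
#'
#' Scores the test rows, thresholds the decision value at 0 (malignant
#' positive), and reports the confusion counts, the Wald-CI metric panel
#' and the AUROC.
#'
#' @param bundle A `model_bundle`.
#' @param test_table Test feature table (both classes present).
#' @return An `eval_report`: list with `confusion` (tp, fp, tn, fn),
#'   `metrics` (the panel), `auroc`, and the decision values.
#' @export
evaluate_model <- function(bundle, test_table) {
  stopifnot(nrow(test_table) >= 1)
  f <- decision_values(bundle, test_table)
  truth <- test_table$class_label == "malignant"
  pred <- f > 0
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  structure(list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 metrics = metric_panel(tp, fp, tn, fn),
                 auroc = auroc(f, test_table$class_label),
                 decision_values = f),
            class = "eval_report")
}

#' One-way vendor ANOVA with Bonferroni post-tests
#'
#' Tests a feature for vendor effects: one-way ANOVA F and p (equal-variance
#' form, so with two groups F equals the squared pooled t statistic),
#' followed by all pairwise pooled t-tests with p-values multiplied by the
#' number of pairs (capped at 1).
#'
#' @param feature_values Numeric vector.
#' @param vendor_labels Vendor label per value (at least 2 vendors, each
#'   with at least 2 values).
#' @return List with `F`, `p`, and `pairwise` (data.frame `vendor1,
#'   vendor2, p_bonferroni`).
#' @export
vendor_anova <- function(feature_values, vendor_labels) {
  v <- as.numeric(feature_values)
  g <- as.character(vendor_labels)
  stopifnot(length(v) == length(g))
  vendors <- unique(g)
  if (length(vendors) < 2) stop("need at least 2 vendors")
  if (any(table(g) < 2)) stop("each vendor needs at least 2 subjects")
  if (.pop_sd(v) == 0) {
    fit <- list(statistic = c(F = 0), p.value = 1)
  } else {
    ow <- oneway.test(v ~ factor(g), var.equal = TRUE)
    fit <- list(statistic = ow$statistic, p.value = ow$p.value)
    if (!is.finite(fit$statistic)) {  # zero within-group variance
      fit <- if (length(unique(tapply(v, g, mean))) == 1)
        list(statistic = c(F = 0), p.value = 1)
      else list(statistic = c(F = Inf), p.value = 0)
    }
  }
  pairs <- utils::combn(vendors, 2)
  n_pairs <- ncol(pairs)
  pw <- apply(pairs, 2, function(pr)
    min(1, n_pairs * two_sample_t_pvalue(v[g == pr[1]], v[g == pr[2]])))
  list(F = unname(fit$statistic), p = fit$p.value,
       pairwise = data.frame(vendor1 = pairs[1, ], vendor2 = pairs[2, ],
                             p_bonferroni = pw, stringsAsFactors = FALSE))
}

#' Serialize / restore a model bundle
#'
#' @param bundle A `model_bundle`.
#' @param path JSON path.
#' @export
write_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  jsonlite::write_json(unclass(bundle), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$center <- stats::setNames(as.numeric(x$center), x$selected_features)
  x$scale <- stats::setNames(as.numeric(x$scale), x$selected_features)
  structure(x, class = "model_bundle")
}
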