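test_that("pooled t-test matches stats::t.test and handles degeneracy", {
  set.seed(26)
  for (rep in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), mean = runif(1, 0, 2))
    expect_equal(two_sample_t_pvalue(x, y),
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(two_sample_t_pvalue(x, y), two_sample_t_pvalue(y, x))
  }
  expect_equal(two_sample_t_pvalue(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(two_sample_t_pvalue(c(1, 2, 3), c(11, 12, 13)), 0.001)
  expect_equal(two_sample_t_pvalue(c(2, 2), c(2, 2)), 1)
  expect_equal(two_sample_t_pvalue(c(2, 2), c(3, 3)), 0)
})

test_that("dual filter keeps exactly the relevant and reproducible features", {
  set.seed(27)
  feats <- feature_names()[1:40]
  informative <- feats[1:20]; noise_p <- feats[21:30]; noise_r <- feats[31:40]
  tab <- toy_table(30, feats,
                   delta = c(rep(3, 20), rep(0, 10), rep(3, 10)))
  # irrelevant features: identical class distributions by construction (the
  # malignant values mirror the benign ones), so p = 1 exactly
  for (f in noise_p)
    tab[[f]][tab$class_label == "malignant"] <-
      tab[[f]][tab$class_label == "benign"]
  # observer-2 rows: reproducible features copy observer 1, non-reproducible
  # ones are independent noise
  tab2 <- tab; tab2$observer <- 2L
  for (f in noise_r) tab2[[f]] <- rnorm(nrow(tab2))
  full <- rbind(tab, tab2)
  rep_ <- reproducibility_report(full)
  sel <- dual_filter(full, rep_, selection_config())
  expect_setequal(sel, informative)
  expect_equal(as.character(sel), informative)  # order preserved
  det <- attr(sel, "details")
  expect_true(all(det$p_value[det$feature %in% noise_p] >= 0.05))
})

test_that("filter thresholds are monotone", {
  set.seed(28)
  feats <- feature_names()[1:12]
  tab <- toy_table(25, feats, delta = runif(12, 0, 2))
  tab2 <- tab; tab2$observer <- 2L
  for (f in feats) tab2[[f]] <- tab2[[f]] + rnorm(nrow(tab2), 0, runif(1, 0, 1))
  full <- rbind(tab, tab2)
  rep_ <- reproducibility_report(full)
  base <- dual_filter(full, rep_, selection_config(p_threshold = 0.2,
                                                   r_threshold = 0.8))
  tighter_p <- dual_filter(full, rep_, selection_config(p_threshold = 0.05,
                                                        r_threshold = 0.8))
  tighter_r <- dual_filter(full, rep_, selection_config(p_threshold = 0.2,
                                                        r_threshold = 0.9))
  expect_true(all(tighter_p %in% base))
  expect_true(all(tighter_r %in% base))
})

test_that("the two-point problem has the analytic max-margin solution", {
  tab <- data.frame(subject_id = c("a", "b"), observer = 1L,
                    class_label = c("benign", "malignant"), vendor = "x",
                    f1 = c(-1, 1))
  b <- train_svm(tab, "f1")
  expect_equal(b$w, 1, tolerance = 1e-9)
  expect_equal(b$b, 0, tolerance = 1e-9)
  expect_equal(decision_values(b, tab), c(-1, 1), tolerance = 1e-9)
})

test_that("separable blobs are classified perfectly; duplicates share weight", {
  set.seed(29)
  feats <- c("f1", "f2")
  tab <- toy_table(15, feats, delta = c(6, 6))
  names(tab)[5:6] <- feats
  b <- train_svm(tab, feats, tol = 1e-8)
  pred <- decision_values(b, tab) > 0
  expect_equal(pred, tab$class_label == "malignant")
  # duplicated feature column: the unique optimum splits the weight equally
  # between the two copies and predicts the same labels
  tab$f3 <- tab$f1
  b2 <- train_svm(tab, c("f1", "f3", "f2"), tol = 1e-8)
  expect_equal(b2$w[1], b2$w[2], tolerance = 1e-6)
  expect_equal(decision_values(b2, tab) > 0, decision_values(b, tab) > 0)
})

test_that("decision values are invariant to affine feature rescaling", {
  set.seed(30)
  tab <- toy_table(20, c("f1", "f2"), delta = c(2, 1))
  names(tab)[5:6] <- c("f1", "f2")
  b1 <- train_svm(tab, c("f1", "f2"), tol = 1e-8)
  tab2 <- tab
  tab2$f1 <- 100 * tab2$f1 - 7
  tab2$f2 <- 0.01 * tab2$f2 + 3
  b2 <- train_svm(tab2, c("f1", "f2"), tol = 1e-8)
  expect_equal(decision_values(b2, tab2), decision_values(b1, tab),
               tolerance = 1e-6)
})

test_that("constant selected features are dropped with a warning", {
  tab <- toy_table(10, c("f1", "f2"), delta = c(4, 0))
  names(tab)[5:6] <- c("f1", "f2")
  tab$f2 <- 1
  expect_warning(b <- train_svm(tab, c("f1", "f2")), "constant")
  expect_equal(b$selected_features, "f1")
})

test_that("stratified holdout splits are exact, disjoint and seeded", {
  tab <- toy_table(40, "f1", 1)
  names(tab)[5] <- "f1"
  sp <- stratified_holdout(tab, 0.75, seed = 5)
  expect_equal(sum(sp$train$class_label == "benign"), 30)
  expect_equal(sum(sp$train$class_label == "malignant"), 30)
  expect_equal(nrow(sp$test), 20)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id), tab$subject_id)
  sp2 <- stratified_holdout(tab, 0.75, seed = 5)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  # 41 subjects at 0.75 -> 31 train / 10 test
  tab41 <- rbind(tab, tab[80, ])
  tab41$subject_id[81] <- "S999"; tab41$class_label[81] <- "malignant"
  sp3 <- stratified_holdout(tab41, 0.75, seed = 1)
  expect_equal(sum(sp3$train$class_label == "malignant"), 31)
})

test_that("the metric panel and its Wald intervals are exact", {
  p <- metric_panel(tp = 10, fp = 1, tn = 9, fn = 0)
  v <- setNames(p$value, p$metric)
  expect_equal(unname(v["sensitivity"]), 100)
  expect_equal(unname(v["specificity"]), 90)
  expect_equal(unname(v["ppv"]), 100 * 10 / 11, tolerance = 1e-12)
  expect_equal(unname(v["npv"]), 100)
  expect_equal(unname(v["accuracy"]), 95)
  # accuracy = (sens*P + spec*N)/(P+N)
  expect_equal(unname(v["accuracy"]),
               unname((v["sensitivity"] * 10 + v["specificity"] * 10) / 20))
  # zero denominator flagged, not NaN
  p2 <- metric_panel(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_false(p2$defined[p2$metric == "ppv"])
})

test_that("AUROC is the rank statistic with half credit for ties", {
  expect_equal(auroc(c(1, 2, 3, 4), c("benign", "benign", "malignant",
                                      "malignant")), 1)
  expect_equal(auroc(rep(0, 6), rep(c("benign", "malignant"), 3)), 0.5)
  expect_equal(auroc(c(3, 1, 2, 4), c("benign", "benign", "malignant",
                                      "malignant")), 0.75)
})

test_that("vendor ANOVA matches its algebraic identities", {
  x <- c(rnorm(5), rnorm(5))
  g2 <- rep(c("ge", "philips"), each = 5)
  va <- vendor_anova(x, g2)
  # two groups: F equals the squared pooled t statistic
  tt <- t.test(x[1:5], x[6:10], var.equal = TRUE)
  expect_equal(unname(va$F), unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(va$p, tt$p.value, tolerance = 1e-10)
  expect_equal(va$pairwise$p_bonferroni,
               min(1, two_sample_t_pvalue(x[1:5], x[6:10])))
  # identical groups: F = 0, p = 1
  same <- vendor_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(unname(same$F), 0)
  expect_equal(same$p, 1)
  # three vendors, one shifted by +10 SD: only its two pairs significant
  set.seed(33)
  x3 <- c(rnorm(10), rnorm(10), rnorm(10) + 10)
  g3 <- rep(c("ge", "philips", "siemens"), each = 10)
  va3 <- vendor_anova(x3, g3)
  pw <- va3$pairwise
  hit <- pw$p_bonferroni < 0.05
  expect_equal(sum(hit), 2)
  expect_true(all(grepl("siemens", paste(pw$vendor1, pw$vendor2))[hit]))
  expect_error(vendor_anova(x3, rep("ge", 30)), "2 vendors")
})

test_that("model bundles round-trip through JSON", {
  set.seed(34)
  tab <- toy_table(10, c("f1", "f2"), delta = c(3, 1))
  names(tab)[5:6] <- c("f1", "f2")
  b <- train_svm(tab, c("f1", "f2"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.json")
  write_model_bundle(b, path)
  b2 <- read_model_bundle(path)
  expect_equal(decision_values(b2, tab), decision_values(b, tab),
               tolerance = 1e-12)
})
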