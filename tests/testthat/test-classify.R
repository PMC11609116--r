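sep_features <- function(n_per_class = 10, d = 4, gap = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
  y <- rep(c("HC", "MDD"), each = n_per_class)
  structure(list(X = X, y = factor(y, levels = c("HC", "MDD")),
                 kind = "energy"), class = "feature_set")
}

test_that("feature assembly has the documented dimensions", {
  set.seed(2)
  cfg <- cohort_config(n_per_group = 3, seed = 2)
  coh <- generate_cohort(cfg, continuous = FALSE)
  analyses <- lapply(coh$truth, function(p)
    analyze_states(p$categories$fear$states, n_steps = 2000, seed = 1))
  labels <- vapply(coh$truth, `[[`, character(1), "group")
  fc <- build_features(analyses, labels, "connectivity")
  fe <- build_features(analyses, labels, "energy")
  expect_equal(ncol(fc$X), 21)           # C(C-1)/2 at C = 7
  expect_equal(ncol(fe$X), 132)          # 2^7 energies + 4 features
  expect_equal(nrow(fe$X), 6)
  # permuting participants permutes rows only
  perm <- c(3, 1, 2, 6, 4, 5)
  fe2 <- build_features(analyses[perm], labels[perm], "energy")
  expect_equal(fe2$X, fe$X[perm, ])
  expect_error(build_features(c(analyses[1], list(NULL), analyses[2:5]),
                              labels, "energy"), "missing participant")
})

test_that("classification metrics satisfy confusion-matrix identities", {
  truth <- factor(c("MDD", "MDD", "MDD", "HC", "HC", "HC", "HC"),
                  levels = c("HC", "MDD"))
  pred <- factor(c("MDD", "HC", "MDD", "HC", "MDD", "HC", "HC"),
                 levels = c("HC", "MDD"))
  m <- elscape:::classification_metrics(truth, pred)
  # TP=2 FN=1 FP=1 TN=3
  expect_equal(unname(m["Acc"]), 100 * 5 / 7)
  expect_equal(unname(m["Pre"]), 100 * 2 / 3)
  expect_equal(unname(m["Rec"]), 100 * 2 / 3)
  expect_equal(unname(m["Spec"]), 100 * 3 / 4)
  expect_equal(unname(m["F1"]), 2 * (2 / 3) * (2 / 3) / (4 / 3))
})

test_that("the SVM separates a wide-margin problem perfectly", {
  fs <- sep_features(gap = 8)
  rep <- loocv_classifier(fs, grid_C = c(1, 100), grid_gamma = c(0.01, 1),
                          inner_folds = 3, n_repeats = 2, seed = 3)
  expect_equal(unname(rep$mean["Acc"]), 100)
  expect_equal(unname(rep$mean["F1"]), 1)
})

test_that("label permutation stays at chance (no information leak)", {
  set.seed(5)
  fs <- sep_features(n_per_class = 12, gap = 0, seed = 5)  # pure noise
  rep <- loocv_classifier(fs, grid_C = c(0.1, 10), grid_gamma = c(0.05, 1),
                          inner_folds = 3, n_repeats = 1, seed = 5)
  # binomial 99% band around 0.5 at n = 24
  expect_lt(unname(rep$mean["Acc"]), 100 * (0.5 + 2.58 * sqrt(0.25 / 24)))
})

test_that("LOOCV is deterministic given the seed and flat mode is labelled", {
  fs <- sep_features(n_per_class = 8, gap = 2, seed = 6)
  r1 <- loocv_classifier(fs, grid_C = c(1), grid_gamma = c(0.1),
                         inner_folds = 3, n_repeats = 2, seed = 9)
  r2 <- loocv_classifier(fs, grid_C = c(1), grid_gamma = c(0.1),
                         inner_folds = 3, n_repeats = 2, seed = 9)
  expect_identical(r1$per_repeat, r2$per_repeat)
  rf <- loocv_classifier(fs, grid_C = c(1, 10), grid_gamma = c(0.1),
                         nested = FALSE)
  expect_equal(rf$protocol, "flat")
  expect_equal(unname(rf$sd), rep(0, 5))
})

test_that("constant feature columns are rescaled to zero with a warning", {
  Xtr <- cbind(c(1, 2, 3), c(5, 5, 5))
  expect_warning(sc <- elscape:::minmax_fit(Xtr), "constant feature")
  out <- elscape:::minmax_apply(Xtr, sc)
  expect_equal(out[, 2], rep(0, 3))
  expect_equal(range(out[, 1]), c(0, 1))
})

test_that("single-class training folds are refused", {
  X <- matrix(rnorm(10), 5, 2)
  y <- factor(rep("MDD", 5), levels = c("HC", "MDD"))
  expect_error(svm_rbf(X, y), "single class")
  fs <- structure(list(X = X, y = y, kind = "energy"), class = "feature_set")
  expect_error(loocv_classifier(fs), ">= 2 participants")
})

test_that("model comparison emits the full metric schema and a null model effect", {
  fake_report <- function(acc_rows) {
    pr <- t(vapply(acc_rows, function(a)
      c(Acc = a, Pre = a, Rec = a, Spec = a, F1 = a / 100), numeric(5)))
    structure(list(mean = colMeans(pr), sd = apply(pr, 2, sd),
                   per_repeat = pr, chosen = NULL, kind = "x",
                   protocol = "nested"), class = "classification_report")
  }
  rep1 <- fake_report(c(70, 74, 66))
  reports <- list(connectivity = list(fear = rep1, calm = rep1),
                  energy = list(fear = rep1, calm = rep1))
  cmp <- compare_models(reports)
  expect_setequal(
    setdiff(names(cmp$table), c("kind", "stimulus")),
    c("Acc", "Pre", "Rec", "Spec", "F1",
      "Acc_sd", "Pre_sd", "Rec_sd", "Spec_sd", "F1_sd"))
  # identical reports for both kinds: kind sum of squares is exactly zero
  p_kind <- cmp$anova$Acc$p[cmp$anova$Acc$effect == "kind"]
  expect_equal(p_kind, 1, tolerance = 1e-6)
})
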