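#' Assemble classifier feature vectors
#'
#' Two feature kinds per participant and stimulus: `"connectivity"` is the
#' upper triangle of the fitted couplings `J` (d = C(C-1)/2 = 21 at C = 7);
#' `"energy"` concatenates the 2^C state energies with the four landscape
#' features (number of LMs, mean LM-GM gap, basin-size SD, GM duration;
#' d = 132 at C = 7).  Column order is fixed: `J` in row-major upper
#' triangle / energies in state-code order, then the scalar features.
#' Min-max rescaling to [0, 1] is NOT applied here: it is fitted on each
#' training fold inside the cross-validation (see [loocv_classifier()]).
#'
#' @param analyses list of per-participant analysis results for one
#'   stimulus (elements of `cohort_features()$analyses[[stimulus]]`).
#' @param labels group labels, one per participant (`"MDD"`/`"HC"`).
#' @param kind `"connectivity"` or `"energy"`.
#' @return a `feature_set`: `X` (matrix `[participants x d]`), `y`
#'   (factor), `kind`.
#' @export
build_features <- function(analyses, labels, kind = c("connectivity", "energy")) {
  kind <- match.arg(kind)
  stopifnot(length(analyses) == length(labels))
  if (any(vapply(analyses, is.null, logical(1)))) {
    stop("missing participant analysis at position(s): ",
         paste(which(vapply(analyses, is.null, logical(1))), collapse = ", "))
  }
  rows <- lapply(analyses, function(a) {
    if (kind == "connectivity") {
      J <- a$model$J
      J[upper.tri(J)]
    } else {
      fe <- a$features
      c(a$model$E, fe$n_LM, fe$mean_gap, fe$basin_size_sd, fe$gm_duration)
    }
  })
  X <- do.call(rbind, rows)
  structure(list(X = X, y = factor(labels, levels = c("HC", "MDD")),
                 kind = kind), class = "feature_set")
}

# min-max scaling fitted on training rows; constant columns map to 0
minmax_fit <- function(Xtr) {
  rng <- apply(Xtr, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    warning("constant feature column(s) rescaled to 0: ",
            paste(which(span == 0), collapse = ", "))
  }
  list(min = rng[1, ], span = ifelse(span == 0, 1, span),
       zero = span == 0)
}
minmax_apply <- function(X, sc) {
  out <- sweep(sweep(X, 2, sc$min, `-`), 2, sc$span, `/`)
  out[, sc$zero] <- 0
  out
}

rbf_kernel <- function(D2, gamma) exp(-gamma * D2)

# squared Euclidean cross-distances
dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Radial-basis-kernel maximum-margin classifier
#'
#' Soft-margin SVM trained by sequential minimal optimization on the dual,
#' with class-balanced box constraints (`C_i = C * n / (2 n_class)`) and an
#' RBF kernel `exp(-gamma ||x - x'||^2)`.
#'
#' @param X training matrix (rows = samples).
#' @param y factor or +-1 labels (second factor level = positive class).
#' @param C soft-margin cost.
#' @param gamma RBF kernel width.
#' @param tol KKT tolerance (default 1e-3).
#' @param class_weight `"balanced"` (default) or `"none"`.
#' @return an `rbf_svm` with `alpha`, `b`, support information.
#' @export
svm_rbf <- function(X, y, C = 1, gamma = 1 / ncol(X), tol = 1e-3,
                    class_weight = "balanced") {
  yy <- if (is.factor(y)) ifelse(y == levels(y)[2], 1, -1) else as.numeric(y)
  if (length(unique(yy)) < 2) stop("training data contains a single class")
  n <- nrow(X)
  Cbox <- rep(C, n)
  if (identical(class_weight, "balanced")) {
    npos <- sum(yy > 0); nneg <- n - npos
    Cbox[yy > 0] <- C * n / (2 * npos)
    Cbox[yy < 0] <- C * n / (2 * nneg)
  }
  K <- rbf_kernel(dist2(X, X), gamma)
  fit <- cpp_smo(K, yy, Cbox, tol, 10000L)
  structure(list(X = X, y = yy, alpha = fit$alpha, b = fit$b,
                 gamma = gamma, C = C,
                 levels = if (is.factor(y)) levels(y) else c("-1", "1")),
            class = "rbf_svm")
}

#' @param object an `rbf_svm`.
#' @param newdata matrix of rows to classify.
#' @param ... unused.
#' @rdname svm_rbf
#' @export
predict.rbf_svm <- function(object, newdata, ...) {
  K <- rbf_kernel(dist2(newdata, object$X), object$gamma)
  f <- as.vector(K %*% (object$alpha * object$y)) + object$b
  factor(ifelse(f > 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}

# confusion-matrix metrics; positive class = second factor level ("MDD").
# Acc/Pre/Rec/Spec in percent, F1 in [0, 1].
classification_metrics <- function(truth, pred) {
  pos <- levels(truth)[2]
  tp <- sum(pred == pos & truth == pos)
  tn <- sum(pred != pos & truth != pos)
  fp <- sum(pred == pos & truth != pos)
  fn <- sum(pred != pos & truth == pos)
  acc <- (tp + tn) / length(truth)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  c(Acc = 100 * acc, Pre = 100 * pre, Rec = 100 * rec, Spec = 100 * spec,
    F1 = f1)
}

#' Leave-one-out cross-validated classification
#'
#' Outer leave-one-out over participants; on each training fold, min-max
#' rescaling is fitted on the training rows only and `(C, gamma)` are
#' chosen by grid search.  Two protocols:
#' \describe{
#'   \item{nested (default)}{the grid is scored by inner k-fold
#'     cross-validation on each outer training set - no information from
#'     the held-out participant reaches any fitting choice.}
#'   \item{flat}{one global grid search scored by leave-one-out over the
#'     whole set, reporting the best grid point's LOOCV metrics.  This is
#'     the literal single-grid-search-plus-LOOCV protocol; it leaks the
#'     held-out labels into hyperparameter choice and is provided for
#'     comparison, labelled as such.}
#' }
#' Metric spread (mean +- SD) comes from `n_repeats` repeated evaluations
#' with reshuffled inner-fold partitions (nested mode; the flat protocol is
#' deterministic and gets SD 0).
#'
#' @param features a `feature_set` from [build_features()].
#' @param grid_C,grid_gamma hyperparameter grids (defaults: powers of ten,
#'   `10^-8 .. 10^8`).
#' @param nested use the nested protocol (default `TRUE`).
#' @param inner_folds inner CV folds for the nested grid search.
#' @param n_repeats repeated evaluations for the SD (default 20).
#' @param seed integer seed.
#' @return a `classification_report`: `mean`, `sd` (named metric vectors:
#'   Acc, Pre, Rec, Spec in %, F1 in [0,1]), `per_repeat` (matrix),
#'   `chosen` (hyperparameters picked per outer fold, last repeat),
#'   `kind`, `protocol`.
#' @export
loocv_classifier <- function(features, grid_C = 10^seq(-8, 8, by = 1),
                             grid_gamma = 10^seq(-8, 8, by = 1),
                             nested = TRUE, inner_folds = 5,
                             n_repeats = 20, seed = 1L) {
  stopifnot(inherits(features, "feature_set"))
  X <- features$X; y <- features$y
  n <- nrow(X)
  if (min(table(y)) < 2) stop("need >= 2 participants per class")
  grid <- expand.grid(C = grid_C, gamma = grid_gamma,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  if (!nested) {
    # flat: global grid search scored by LOOCV (leaky, deterministic)
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      preds <- loo_predict(X, y, grid$C[g], grid$gamma[g])
      m <- classification_metrics(y, preds)
      if (is.null(best) || m["Acc"] > best$m["Acc"]) {
        best <- list(m = m, C = grid$C[g], gamma = grid$gamma[g])
      }
    }
    rep_mat <- matrix(best$m, nrow = 1,
                      dimnames = list(NULL, names(best$m)))
    return(structure(list(mean = best$m, sd = best$m * 0,
                          per_repeat = rep_mat,
                          chosen = data.frame(C = best$C, gamma = best$gamma),
                          kind = features$kind, protocol = "flat"),
                     class = "classification_report"))
  }
  per_repeat <- matrix(NA_real_, n_repeats, 5,
                       dimnames = list(NULL, c("Acc", "Pre", "Rec", "Spec", "F1")))
  chosen <- NULL
  for (rep_i in seq_len(n_repeats)) {
    preds <- factor(rep(levels(y)[1], n), levels = levels(y))
    chosen <- data.frame(C = numeric(n), gamma = numeric(n))
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
      folds <- balanced_folds(ytr, inner_folds)
      best <- NULL
      # squared distances on train-scaled features, shared across the grid
      sc <- minmax_fit(Xtr)
      Xs <- minmax_apply(Xtr, sc)
      for (g in seq_len(nrow(grid))) {
        acc <- inner_cv_accuracy(Xtr, ytr, folds, grid$C[g], grid$gamma[g])
        if (is.null(best) || acc > best$acc) {
          best <- list(acc = acc, C = grid$C[g], gamma = grid$gamma[g])
        }
      }
      fit <- svm_rbf(Xs, ytr, C = best$C, gamma = best$gamma)
      preds[i] <- predict(fit, minmax_apply(X[i, , drop = FALSE], sc))
      chosen$C[i] <- best$C; chosen$gamma[i] <- best$gamma
    }
    per_repeat[rep_i, ] <- classification_metrics(y, preds)
  }
  structure(list(mean = colMeans(per_repeat),
                 sd = apply(per_repeat, 2, stats::sd),
                 per_repeat = per_repeat, chosen = chosen,
                 kind = features$kind, protocol = "nested"),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification_report (", x$kind, ",", x$protocol, ")\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 2))
  invisible(x)
}

# LOO predictions at fixed hyperparameters, scaling fit per training fold
loo_predict <- function(X, y, C, gamma) {
  n <- nrow(X)
  preds <- factor(rep(levels(y)[1], n), levels = levels(y))
  for (i in seq_len(n)) {
    sc <- minmax_fit(X[-i, , drop = FALSE])
    fit <- suppressWarnings(
      svm_rbf(minmax_apply(X[-i, , drop = FALSE], sc), y[-i],
              C = C, gamma = gamma))
    preds[i] <- predict(fit, minmax_apply(X[i, , drop = FALSE], sc))
  }
  preds
}

# stratified fold assignment
balanced_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean held-out accuracy of k-fold CV at fixed hyperparameters
inner_cv_accuracy <- function(X, y, folds, C, gamma) {
  correct <- 0
  for (k in unique(folds)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) next
    sc <- minmax_fit(X[tr, , drop = FALSE])
    fit <- suppressWarnings(
      svm_rbf(minmax_apply(X[tr, , drop = FALSE], sc), y[tr],
              C = C, gamma = gamma))
    pr <- predict(fit, minmax_apply(X[!tr, , drop = FALSE], sc))
    correct <- correct + sum(pr == y[!tr])
  }
  correct / length(y)
}

#' Compare classification reports across feature kinds and stimuli
#'
#' Builds the comparison table (mean and SD of each metric per feature kind
#' and stimulus) and, when repeated evaluations are available, a two-way
#' ANOVA (kind, stimulus) per metric with Tukey post-hoc stimulus
#' contrasts.
#'
#' @param reports named nested list `reports[[kind]][[stimulus]]` of
#'   `classification_report`s sharing one fold structure.
#' @return list with `table` (long data frame) and `anova` (per-metric
#'   data frames, `NULL` when there are no repeats to test over).
#' @export
compare_models <- function(reports) {
  rows <- list(); long <- list()
  for (kind in names(reports)) {
    for (st in names(reports[[kind]])) {
      rp <- reports[[kind]][[st]]
      rows[[paste(kind, st)]] <- data.frame(
        kind = kind, stimulus = st, t(rp$mean),
        t(stats::setNames(rp$sd, paste0(names(rp$sd), "_sd"))))
      pr <- as.data.frame(rp$per_repeat)
      pr$kind <- kind; pr$stimulus <- st
      long[[paste(kind, st)]] <- pr
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  longd <- do.call(rbind, long)
  anovas <- NULL
  if (nrow(longd) > length(unique(longd$kind)) * length(unique(longd$stimulus))) {
    anovas <- list()
    for (m in c("Acc", "Pre", "Rec", "Spec", "F1")) {
      fit <- stats::aov(stats::reformulate(c("kind", "stimulus"), m),
                        data = longd)
      an <- summary(fit)[[1]]
      eff <- trimws(rownames(an))
      keep <- eff != "Residuals"
      anovas[[m]] <- data.frame(effect = eff[keep], df = an[keep, "Df"],
                                F = an[keep, "F value"],
                                p = an[keep, "Pr(>F)"])
    }
  }
  list(table = tab, anova = anovas)
}
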