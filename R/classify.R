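#' Build the samples x DMCs feature matrix for classification
#'
#' Features are methylation percentages at DMC positions, taken from CpG10
#' cells only (other cells are missing). Under `"complete_only"` all features
#' with any missing value are dropped; under `"impute_lt_10pct"` features
#' with less than 10% missing values are kept and completed by iterative
#' low-rank SVD reconstruction (rank chosen by internal cross-validation on
#' held-out observed cells, fixed seed), the rest dropped.
#'
#' @param matrix a [meth_count_matrix()].
#' @param dmcs data.frame `chrom, pos` of the selected sites.
#' @param policy `"complete_only"` or `"impute_lt_10pct"`.
#' @param cpg10 logical CpG10 mask for `matrix`.
#' @param max_missing maximal missing fraction for the impute policy
#'   (exclusive bound, default 0.10).
#' @param seed seed for the imputer.
#' @return numeric matrix samples x features (no missing cells), feature
#'   names `chrom:pos`; attribute `"dropped"` counts discarded features.
#' @export
prepare_features <- function(matrix, dmcs,
                             policy = c("complete_only", "impute_lt_10pct"),
                             cpg10 = coverage_filter(matrix),
                             max_missing = 0.10, seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(inherits(matrix, "MethCountMatrix"))
  key <- paste(matrix$sites$chrom, matrix$sites$pos)
  idx <- match(paste(dmcs$chrom, dmcs$pos), key)
  if (anyNA(idx)) stop("DMC positions absent from the matrix")
  pct <- meth_percent(matrix)
  pct[!cpg10] <- NA_real_
  X <- t(pct[idx, , drop = FALSE])
  colnames(X) <- paste0(dmcs$chrom, ":", dmcs$pos)
  rownames(X) <- matrix$samples
  miss <- colMeans(is.na(X))
  keep <- if (policy == "complete_only") miss == 0 else miss < max_missing
  dropped <- sum(!keep)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L) stop("no features survive the missing-value policy")
  if (policy == "impute_lt_10pct" && anyNA(X))
    X <- impute_low_rank(X, seed = seed)
  attr(X, "dropped") <- dropped
  X
}

#' Iterative low-rank SVD imputation
#'
#' Missing cells are initialized at column means and refined by alternating
#' truncated-SVD reconstruction until convergence. The rank is selected by
#' internal cross-validation: a random 10% of the observed cells are masked,
#' each candidate rank is scored by its reconstruction error on them, and the
#' best rank is used for the final fit.
#'
#' @param X numeric matrix with `NA`s.
#' @param max_rank largest candidate rank.
#' @param seed seed controlling the validation mask.
#' @param tol,max_iter convergence controls.
#' @return completed matrix; attribute `"rank"` records the chosen rank.
#' @export
impute_low_rank <- function(X, max_rank = min(5L, dim(X) - 1L), seed = 1L,
                            tol = 1e-6, max_iter = 200L) {
  obs <- !is.na(X)
  fit <- function(Xin, k) {
    miss <- is.na(Xin)
    if (!any(miss)) return(Xin)
    mu <- colMeans(Xin, na.rm = TRUE)
    Z <- Xin
    for (j in seq_len(ncol(Z))) Z[is.na(Z[, j]), j] <- mu[j]
    prev <- Z[miss]
    for (it in seq_len(max_iter)) {
      s <- svd(Z, nu = k, nv = k)
      rec <- s$u %*% (s$d[seq_len(k)] * t(s$v))
      Z[miss] <- rec[miss]
      if (sqrt(mean((Z[miss] - prev)^2)) < tol) break
      prev <- Z[miss]
    }
    Z
  }
  max_rank <- max(1L, min(max_rank, nrow(X) - 1L, ncol(X)))
  best_k <- 1L
  if (max_rank > 1L) {
    set.seed(derive_seed(seed, "impute_cv"))
    oi <- which(obs)
    hold <- sample(oi, max(1L, round(0.1 * length(oi))))
    Xcv <- X; Xcv[hold] <- NA
    obs_in <- !is.na(Xcv)
    errs <- vapply(seq_len(max_rank), function(k) {
      Z <- fit(Xcv, k)
      sqrt(mean((Z[hold] - X[hold])^2))
    }, numeric(1))
    best_k <- which.min(errs)
  }
  obs_in <- obs
  out <- fit(X, best_k)
  attr(out, "rank") <- best_k
  out
}

#' Stratified train/test split preserving class proportions
#'
#' Per class, the training side receives `round_half_up(train_frac * size)`
#' samples chosen uniformly at random; the remainder goes to the test side.
#' With classes of 57 and 43 at 2/3 this yields 38 + 29 = 67 training and
#' 19 + 14 = 33 testing samples. Sizes are seed-independent; contents are
#' seed-dependent.
#'
#' @param classes per-sample class labels (two classes, each >= 2 samples).
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list `train`, `test` of integer indices.
#' @export
stratified_split <- function(classes, train_frac = 2 / 3, seed = 1L) {
  classes <- as.character(classes)
  lev <- unique(classes)
  if (length(lev) != 2L) stop("exactly two classes are required")
  set.seed(derive_seed(seed, "split"))
  train <- integer()
  for (l in lev) {
    idx <- which(classes == l)
    n_tr <- floor(train_frac * length(idx) + 0.5)  # round half up
    if (n_tr < 1L || n_tr >= length(idx))
      stop("class '", l, "' would get an empty train or test side")
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(classes), train))
}

#' Train the Random-Forest fertility classifier
#'
#' 500 trees by default; the per-split candidate-feature count `mtry` is the
#' (floored) square root of the number of features. The positive class is
#' `fertile`.
#'
#' @param features numeric matrix samples x features, no missing cells.
#' @param labels class labels aligned with rows.
#' @param n_trees number of trees.
#' @param mtry `"sqrt"` or an integer.
#' @param seed integer seed for reproducibility.
#' @return a `randomForest` classifier.
#' @export
train_model <- function(features, labels, n_trees = 500L, mtry = "sqrt",
                        seed = 1L) {
  if (anyNA(features)) stop("features contain missing cells; prepare first")
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("labels contain a single class")
  m <- if (identical(mtry, "sqrt")) max(1L, floor(sqrt(ncol(features))))
       else as.integer(mtry)
  set.seed(derive_seed(seed, "rf"))
  randomForest::randomForest(x = features, y = labels, ntree = n_trees,
                             mtry = m)
}

#' ROC points and trapezoidal AUC from scores
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels actual labels.
#' @param positive the positive class.
#' @return list `roc` (data.frame `threshold, fpr, tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "fertile") {
  pos <- as.character(labels) == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    return(list(roc = data.frame(threshold = numeric(), fpr = numeric(),
                                 tpr = numeric()), auc = NA_real_))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  # trapezoidal integration over the ROC polygon
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a fitted classifier on a test set
#'
#' Confusion-derived metrics with `fertile` as the positive class:
#' sensitivity is the true-positive (fertile) rate, specificity the
#' true-negative (subfertile) rate; predicted class is positive when the
#' class probability reaches 0.5; AUC by trapezoidal integration of the ROC
#' built from class probabilities (undefined when the test set has a single
#' class).
#'
#' @param model classifier from [train_model()].
#' @param features test feature matrix.
#' @param labels actual test labels.
#' @param positive positive class label.
#' @param threshold probability cut for the predicted class.
#' @param strategy label stored in the report.
#' @return a `ModelReport` list: `accuracy, auc, sensitivity, specificity,
#'   roc, predictions, strategy`.
#' @export
evaluate <- function(model, features, labels, positive = "fertile",
                     threshold = 0.5, strategy = "holdout") {
  if (nrow(features) == 0L) stop("empty test set")
  prob <- stats::predict(model, features, type = "prob")[, positive]
  labels <- as.character(labels)
  negative <- setdiff(unique(c(labels, model$classes)), positive)[1]
  pred <- ifelse(prob >= threshold, positive, negative)
  tp <- sum(pred == positive & labels == positive)
  tn <- sum(pred != positive & labels != positive)
  fp <- sum(pred == positive & labels != positive)
  fn <- sum(pred != positive & labels == positive)
  rc <- roc_curve(prob, labels, positive)
  structure(list(
    accuracy = (tp + tn) / length(labels),
    auc = rc$auc,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    roc = rc$roc,
    predictions = data.frame(sample = rownames(features) %||%
                               as.character(seq_along(labels)),
                             actual = labels, predicted = pred,
                             probability = prob, stringsAsFactors = FALSE),
    strategy = strategy), class = "ModelReport")
}

#' @export
print.ModelReport <- function(x, ...) {
  cat(sprintf("ModelReport [%s]: accuracy %.3f, AUC %s, sensitivity %s, specificity %s\n",
              x$strategy, x$accuracy,
              formatC(x$auc, digits = 3, format = "f"),
              formatC(x$sensitivity, digits = 3, format = "f"),
              formatC(x$specificity, digits = 3, format = "f")))
  invisible(x)
}

#' Cross-validation by repeated stratified resampling
#'
#' Repeats `iterations` times: stratified 2/3 - 1/3 split, train, evaluate;
#' reports the mean (and SD) of accuracy, AUC, sensitivity and specificity
#' across iterations (iteration-level averaging).
#'
#' @inheritParams train_model
#' @param iterations number of resampling iterations (default 50).
#' @param train_frac training fraction.
#' @return list `mean`, `sd` (named numeric), `reports` (per-iteration
#'   `ModelReport`s), `iterations`.
#' @export
crossvalidate_resampled <- function(features, labels, iterations = 50L,
                                    train_frac = 2 / 3, n_trees = 500L,
                                    seed = 1L) {
  labels <- as.character(labels)
  reports <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    sp <- stratified_split(labels, train_frac,
                           seed = derive_seed(seed, "cv_split", i))
    fit <- train_model(features[sp$train, , drop = FALSE], labels[sp$train],
                       n_trees = n_trees,
                       seed = derive_seed(seed, "cv_fit", i))
    reports[[i]] <- evaluate(fit, features[sp$test, , drop = FALSE],
                             labels[sp$test],
                             strategy = sprintf("resample_%02d", i))
  }
  metrics <- c("accuracy", "auc", "sensitivity", "specificity")
  m <- vapply(reports, function(r) unlist(r[metrics]), numeric(4))
  list(mean = rowMeans(m, na.rm = TRUE),
       sd = apply(m, 1, stats::sd, na.rm = TRUE),
       reports = reports, iterations = iterations)
}

#' Train-on-one-group, test-on-the-other evaluation
#'
#' Splits the cohort by a grouping column (e.g. semen collection center),
#' trains on each group and tests on the other; no resampling.
#'
#' @inheritParams train_model
#' @param groups per-sample group labels (exactly two).
#' @return named list of two `ModelReport`s (`"A_to_B"`, `"B_to_A"` with the
#'   actual group labels substituted).
#' @export
evaluate_group_split <- function(features, labels, groups, n_trees = 500L,
                                 seed = 1L) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required")
  one_way <- function(train_g, test_g) {
    tr <- groups == train_g
    fit <- train_model(features[tr, , drop = FALSE], labels[tr],
                       n_trees = n_trees,
                       seed = derive_seed(seed, paste0("group_", train_g)))
    evaluate(fit, features[!tr, , drop = FALSE], labels[!tr],
             strategy = sprintf("%s_to_%s", train_g, test_g))
  }
  out <- list(one_way(lev[1], lev[2]), one_way(lev[2], lev[1]))
  names(out) <- c(sprintf("%s_to_%s", lev[1], lev[2]),
                  sprintf("%s_to_%s", lev[2], lev[1]))
  out
}

#' Train on a whole cohort, test on an independent cohort
#'
#' @param train_features,train_labels the training cohort.
#' @param test_features,test_labels the independent cohort; feature columns
#'   must match the training columns.
#' @inheritParams train_model
#' @return a `ModelReport`.
#' @export
evaluate_independent <- function(train_features, train_labels,
                                 test_features, test_labels,
                                 n_trees = 500L, seed = 1L) {
  absent <- setdiff(colnames(train_features), colnames(test_features))
  if (length(absent))
    stop("features absent from the independent cohort: ",
         paste(absent, collapse = ", "))
  test_features <- test_features[, colnames(train_features), drop = FALSE]
  fit <- train_model(train_features, train_labels, n_trees = n_trees,
                     seed = derive_seed(seed, "independent"))
  evaluate(fit, test_features, test_labels, strategy = "independent")
}

#' PCA of samples tagged by actual/predicted class quadrant
#'
#' Principal components of the centered (optionally scaled) feature matrix;
#' each sample is tagged FF, FS, SF or SS (actual then predicted class
#' initial, F = fertile, S = subfertile), the scheme used to show that
#' misclassified samples carry a methylation signature typical of the
#' opposite class.
#'
#' @param features complete numeric matrix samples x features.
#' @param labels actual classes.
#' @param predictions predicted classes.
#' @param scale. scale features to unit variance? (default FALSE: percentages
#'   share units).
#' @return data.frame `sample, PC1, PC2, actual, predicted, quadrant`;
#'   attribute `"var_explained"`.
#' @export
misclassification_pca <- function(features, labels, predictions,
                                  scale. = FALSE) {
  if (anyNA(features)) stop("features must be complete")
  keep <- apply(features, 2, stats::sd) > 0
  if (!any(keep)) stop("degenerate input: all features are constant")
  pc <- stats::prcomp(features[, keep, drop = FALSE], center = TRUE,
                      scale. = scale.)
  tag <- function(x) ifelse(as.character(x) == "fertile", "F", "S")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(sample = rownames(features) %||%
                      as.character(seq_len(nrow(features))),
                    PC1 = pc$x[, 1],
                    PC2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0,
                    actual = as.character(labels),
                    predicted = as.character(predictions),
                    quadrant = paste0(tag(labels), tag(predictions)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "var_explained") <- ve
  out
}

#' Two-group comparison with the study's test-selection rule
#'
#' The two-sample t-test is used only when all three criteria hold: more
#' than 15 values per group, normality of both groups by the Shapiro-Wilk
#' test, and equal variances by the F-test (both at alpha = 0.05); otherwise
#' the rank-sum (Wilcoxon) test is used.
#'
#' @param values numeric vector.
#' @param groups two-level grouping of `values` (each group >= 2 values).
#' @return list `test` (`"t"` or `"wilcoxon"`), `p`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required")
  a <- values[groups == lev[1]]; b <- values[groups == lev[2]]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  use_t <- length(a) > 15 && length(b) > 15
  if (use_t) {
    sw <- function(x) if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
    use_t <- sw(a) > 0.05 && sw(b) > 0.05
  }
  if (use_t) use_t <- stats::var.test(a, b)$p.value > 0.05
  if (use_t)
    list(test = "t", p = stats::t.test(a, b, var.equal = TRUE)$p.value)
  else
    list(test = "wilcoxon",
         p = suppressWarnings(stats::wilcox.test(a, b))$p.value)
}

#' Hierarchical clustering of samples by correlation distance
#'
#' Distance between sample profiles is `1 - Pearson correlation`; Ward's
#' method is the linkage function. Deterministic.
#'
#' @param mat numeric matrix samples x features, no missing cells.
#' @return an `hclust` tree (labels = row names).
#' @export
hierarchical_cluster <- function(mat) {
  if (anyNA(mat)) stop("matrix must be complete")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    stop("constant sample profile(s): correlation undefined for ",
         paste(rownames(mat)[sds == 0] %||% which(sds == 0), collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  stats::hclust(d, method = "ward.D2")
}

#' Remove a batch effect by linear-model residuals
#'
#' Ordinary least squares of the values on batch indicators; the residuals
#' (per-batch mean-centered values) are returned. A single batch reduces to
#' overall centering (with a warning); batches with one sample get residual
#' 0 and are flagged.
#'
#' @param values numeric vector.
#' @param batches batch labels aligned with `values`.
#' @return numeric residuals; attribute `"flagged"` marks singleton batches.
#' @export
correct_batch <- function(values, batches) {
  batches <- as.character(batches)
  if (length(unique(batches)) < 2L)
    warning("single batch: correction reduces to centering")
  mu <- tapply(values, batches, mean)
  res <- values - mu[batches]
  names(res) <- names(values)
  single <- names(which(table(batches) == 1L))
  attr(res, "flagged") <- which(batches %in% single)
  res
}
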