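# a stub classifier whose predict() returns fixed probabilities, to test
# metric arithmetic independently of any learner
fixed_model <- function(probs) {
  structure(list(probs = probs, classes = c("fertile", "subfertile")),
            class = "fixed_prob")
}
predict.fixed_prob <- function(object, newdata, type = "prob", ...) {
  p <- object$probs[seq_len(nrow(newdata))]
  cbind(fertile = p, subfertile = 1 - p)
}
registerS3method("predict", "fixed_prob", predict.fixed_prob,
                 envir = asNamespace("stats"))

test_that("feature preparation enforces the missing-value policies", {
  set.seed(2)
  mm <- matrix(5L, 20, 10); tt <- matrix(10L, 20, 10)
  tt[1, 1:4] <- NA; mm[1, 1:4] <- NA       # 40% missing
  tt[2, 1] <- NA; mm[2, 1] <- NA           # 10% missing (not < 10%)
  tt[3, 1] <- 9L                           # below CpG10 -> missing
  m <- tiny_matrix(meth = mm, total = tt)
  dmcs <- m$sites
  f_complete <- prepare_features(m, dmcs, "complete_only")
  expect_equal(ncol(f_complete), 17L)
  expect_false(anyNA(f_complete))
  f_imp <- prepare_features(m, dmcs, "impute_lt_10pct")
  expect_equal(ncol(f_imp), 17L)  # 10% is not "less than 10%"
  # no missing cells: both policies return the matrix unchanged
  m2 <- tiny_matrix(meth = matrix(5L, 4, 6), total = matrix(10L, 4, 6))
  expect_equal(prepare_features(m2, m2$sites, "complete_only"),
               prepare_features(m2, m2$sites, "impute_lt_10pct"),
               ignore_attr = TRUE)
  expect_error(prepare_features(subset_matrix(m, sites = 1), m$sites[1, ],
                                "complete_only"), "no features")
})

test_that("low-rank imputation recovers a rank-1 completion", {
  set.seed(6)
  u <- runif(30, 1, 2); v <- runif(8, 10, 20)
  X <- outer(u, v)
  Xm <- X; Xm[4, 3] <- NA; Xm[17, 6] <- NA
  Z <- impute_low_rank(Xm, max_rank = 3, seed = 1)
  expect_equal(Z[4, 3], X[4, 3], tolerance = 1e-4)
  expect_equal(Z[17, 6], X[17, 6], tolerance = 1e-4)
  expect_equal(Z[!is.na(Xm)], X[!is.na(Xm)])  # observed cells untouched
})

test_that("stratified split reproduces the 67/33 arithmetic and determinism", {
  cls <- c(rep("fertile", 57), rep("subfertile", 43))
  sp <- stratified_split(cls, 2 / 3, seed = 1)
  expect_length(sp$train, 67L)
  expect_length(sp$test, 33L)
  expect_equal(sum(cls[sp$train] == "fertile"), 38L)
  expect_equal(sum(cls[sp$train] == "subfertile"), 29L)
  # per-class rounding at one half goes up
  cls2 <- c(rep("a", 4), rep("b", 16))
  sp2 <- stratified_split(cls2, 0.5, seed = 3)
  expect_equal(sum(cls2[sp2$train] == "a"), 2L)
  expect_equal(sum(cls2[sp2$train] == "b"), 8L)
  expect_identical(stratified_split(cls, seed = 9),
                   stratified_split(cls, seed = 9))
  sp3 <- stratified_split(cls, seed = 10)
  expect_false(identical(sp3$train, stratified_split(cls, seed = 9)$train))
  expect_length(sp3$train, 67L)  # sizes are seed-independent
  expect_error(stratified_split(c("a", "a", "b"), 0.9), "empty")
})

test_that("the forest uses sqrt-mtry and separates separable clusters", {
  set.seed(12)
  X <- rbind(matrix(rnorm(30 * 107), 30),
             matrix(rnorm(30 * 107, mean = 5), 30))
  colnames(X) <- paste0("f", 1:107)
  y <- rep(c("fertile", "subfertile"), each = 30)
  fit <- train_model(X, y, n_trees = 100, seed = 4)
  expect_equal(fit$mtry, 10L)  # floor(sqrt(107))
  rep <- evaluate(fit, X, y, strategy = "training")
  expect_equal(rep$accuracy, 1)
  expect_error(train_model(X, rep("fertile", 60)), "single class")
  expect_error(train_model(cbind(c(NA, 1)), c("a", "b")), "missing")
})

test_that("confusion metrics and ROC/AUC follow their definitions", {
  # 10 fertile, 8 predicted fertile; 8 subfertile, 5 predicted subfertile
  labels <- rep(c("fertile", "subfertile"), c(10, 8))
  probs <- c(rep(0.9, 8), rep(0.1, 2), rep(0.8, 3), rep(0.2, 5))
  rep <- evaluate(fixed_model(probs),
                  matrix(0, 18, 1, dimnames = list(paste0("s", 1:18), "f")),
                  labels)
  expect_equal(rep$sensitivity, 0.8)
  expect_equal(rep$specificity, 0.625)
  expect_equal(rep$accuracy, 13 / 18)
  # accuracy equals the class-size-weighted mix of sensitivity/specificity
  expect_equal(rep$accuracy, (10 * rep$sensitivity + 8 * rep$specificity) / 18)
  # perfect and constant scores
  expect_equal(roc_curve(c(2, 3, 0, 1), rep(c("fertile", "subfertile"),
                                            each = 2))$auc, 1)
  expect_equal(roc_curve(rep(1, 10), rep(c("fertile", "subfertile"), 5))$auc,
               0.5)
  # AUC is invariant under strictly monotone transforms of the scores
  set.seed(7)
  sc <- runif(40); lb <- sample(rep(c("fertile", "subfertile"), 20))
  expect_equal(roc_curve(sc, lb)$auc, roc_curve(qlogis(sc), lb)$auc)
  # single-class test set: AUC undefined, other metrics still computed
  rep1 <- evaluate(fixed_model(rep(0.9, 3)), matrix(0, 3, 1),
                   rep("fertile", 3))
  expect_true(is.na(rep1$auc))
  expect_equal(rep1$accuracy, 1)
})

test_that("random scores give chance-level AUC", {
  set.seed(19)
  auc <- replicate(400, {
    roc_curve(runif(20), rep(c("fertile", "subfertile"), 10))$auc
  })
  expect_lt(abs(mean(auc) - 0.5), 0.02)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    sc <- round(runif(30), 2)  # ties included
    lb <- sample(rep(c("fertile", "subfertile"), 15))
    want <- as.numeric(pROC::auc(pROC::roc(
      response = lb, predictor = sc, levels = c("subfertile", "fertile"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_curve(sc, lb)$auc, want, tolerance = 1e-12)
  }
})

test_that("one-iteration cross-validation equals a single split/evaluate run", {
  set.seed(31)
  X <- rbind(matrix(rnorm(12 * 20), 12), matrix(rnorm(12 * 20, 2), 12))
  rownames(X) <- paste0("s", 1:24)
  y <- rep(c("fertile", "subfertile"), each = 12)
  cv <- crossvalidate_resampled(X, y, iterations = 1, n_trees = 50, seed = 8)
  sp <- stratified_split(y, 2 / 3, seed = derive_seed(8, "cv_split", 1))
  fit <- train_model(X[sp$train, ], y[sp$train], n_trees = 50,
                     seed = derive_seed(8, "cv_fit", 1))
  rep <- evaluate(fit, X[sp$test, ], y[sp$test])
  expect_equal(unname(cv$mean["accuracy"]), rep$accuracy)
  expect_equal(unname(cv$mean["auc"]), rep$auc)
})

test_that("group-split evaluation is symmetric for identical groups", {
  set.seed(37)
  X <- rbind(matrix(rnorm(10 * 15), 10), matrix(rnorm(10 * 15, 3), 10))
  y <- rep(c("fertile", "subfertile"), each = 10)
  X2 <- rbind(X, X); y2 <- c(y, y)
  g <- rep(c("c1", "c2"), each = 20)
  res <- evaluate_group_split(X2, y2, g, n_trees = 50, seed = 5)
  expect_equal(res[[1]]$accuracy, res[[2]]$accuracy)
  expect_equal(res[[1]]$auc, res[[2]]$auc)
  expect_error(evaluate_group_split(X2, y2, rep("c1", 40)), "two groups")
})

test_that("independent-cohort evaluation honours imbalance and label flips", {
  set.seed(41)
  Xtr <- rbind(matrix(rnorm(20 * 12), 20), matrix(rnorm(20 * 12, 4), 20))
  colnames(Xtr) <- paste0("f", 1:12)
  ytr <- rep(c("fertile", "subfertile"), each = 20)
  Xte <- rbind(matrix(rnorm(16 * 12), 16), matrix(rnorm(4 * 12, 4), 4))
  colnames(Xte) <- colnames(Xtr)
  yte <- rep(c("fertile", "subfertile"), c(16, 4))
  rep <- evaluate_independent(Xtr, ytr, Xte, yte, n_trees = 100, seed = 2)
  cm <- table(rep$predictions$actual)
  expect_equal(unname(cm["fertile"]), 16L)
  expect_equal(unname(cm["subfertile"]), 4L)
  flipped <- ifelse(yte == "fertile", "subfertile", "fertile")
  rep2 <- evaluate_independent(Xtr, ytr, Xte, flipped, n_trees = 100,
                               seed = 2)
  expect_equal(rep2$accuracy, 1 - rep$accuracy)
  expect_error(evaluate_independent(Xtr, ytr, Xte[, 1:5], yte), "absent")
})

test_that("misclassification PCA tags quadrants and flags degenerate input", {
  set.seed(43)
  X <- rbind(matrix(rnorm(10 * 6, 0), 10), matrix(rnorm(10 * 6, 6), 10))
  y <- rep(c("fertile", "subfertile"), each = 10)
  pc <- misclassification_pca(X, y, y)
  expect_setequal(unique(pc$quadrant), c("FF", "SS"))
  # two samples planted in the opposite cluster land on the opposite side
  Xs <- X; Xs[1, ] <- rnorm(6, 6); Xs[11, ] <- rnorm(6, 0)
  pred <- c("subfertile", y[2:10], "fertile", y[12:20])
  pc2 <- misclassification_pca(Xs, y, pred)
  mid <- mean(c(mean(pc2$PC1[pc2$quadrant == "FF"]),
                mean(pc2$PC1[pc2$quadrant == "SS"])))
  side_ss <- sign(mean(pc2$PC1[pc2$quadrant == "SS"]) - mid)
  expect_equal(sign(pc2$PC1[1] - mid), side_ss)   # FS sample on the S side
  expect_equal(unique(pc2$quadrant[c(1, 11)]), c("FS", "SF"))
  expect_error(misclassification_pca(matrix(1, 5, 3), rep("fertile", 5),
                                     rep("fertile", 5)), "degenerate")
})

test_that("the test-selection rule picks t or Wilcoxon as stated", {
  set.seed(47)
  # 5 per group: criterion 1 fails -> rank-sum
  r1 <- compare_groups(c(rnorm(5), rnorm(5, 2)), rep(c("a", "b"), each = 5))
  expect_equal(r1$test, "wilcoxon")
  # 30 per group, normal, equal variance -> t-test
  r2 <- compare_groups(c(rnorm(30), rnorm(30, 0.5)),
                       rep(c("a", "b"), each = 30))
  expect_equal(r2$test, "t")
  # heavy non-normality with large n -> rank-sum
  r3 <- compare_groups(c(rexp(30)^3, rexp(30)^3 + 1),
                       rep(c("a", "b"), each = 30))
  expect_equal(r3$test, "wilcoxon")
  # identical samples -> p = 1
  r4 <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(r4$p, 1)
})

test_that("correlation/Ward clustering matches a Lance-Williams oracle", {
  set.seed(53)
  X <- matrix(rnorm(10 * 50), 10)
  rownames(X) <- paste0("s", 1:10)
  hc <- hierarchical_cluster(X)
  # identical samples merge first at height 0
  X2 <- rbind(X, X[1, , drop = FALSE] + 0)
  rownames(X2) <- c(rownames(X), "dup")
  hc2 <- hierarchical_cluster(X2)
  first <- sort(rownames(X2)[-hc2$merge[1, ]])
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  expect_setequal(first, c("s1", "dup"))
  # naive Ward (ward.D2 Lance-Williams recurrence) reproduces merge heights
  d <- as.matrix(as.dist(1 - cor(t(X))))
  sizes <- rep(1, 10); active <- 1:10; heights <- numeric(0)
  dm <- d
  repeat {
    if (length(active) < 2) break
    pairs <- t(combn(active, 2))
    vals <- dm[pairs]
    k <- which.min(vals)
    i <- pairs[k, 1]; j <- pairs[k, 2]
    heights <- c(heights, dm[i, j])
    ni <- sizes[i]; nj <- sizes[j]
    for (h in setdiff(active, c(i, j))) {
      nh <- sizes[h]
      dm[i, h] <- dm[h, i] <- sqrt(((ni + nh) * dm[i, h]^2 +
        (nj + nh) * dm[j, h]^2 - nh * dm[i, j]^2) / (ni + nj + nh))
    }
    sizes[i] <- ni + nj; active <- setdiff(active, j)
  }
  expect_equal(hc$height, sort(heights), tolerance = 1e-9)
  # constant profiles are rejected by name
  X3 <- X; X3[4, ] <- 7
  expect_error(hierarchical_cluster(X3), "s4")
})

test_that("batch correction returns per-batch centered residuals", {
  v <- c(1, 2, 3, 11, 12, 13)
  b <- rep(c("A", "B"), each = 3)
  r <- correct_batch(v, b)
  expect_equal(as.numeric(r), c(-1, 0, 1, -1, 0, 1))
  # residuals orthogonal to batch indicators
  set.seed(59)
  v2 <- rnorm(40); b2 <- sample(c("A", "B", "C"), 40, replace = TRUE)
  r2 <- correct_batch(v2, b2)
  for (lvl in unique(b2))
    expect_lt(abs(sum(r2[b2 == lvl])), 1e-8)
  # single batch centers with a warning; singleton batches are flagged
  expect_warning(r3 <- correct_batch(v, rep("A", 6)), "single batch")
  expect_equal(as.numeric(r3), v - mean(v))
  r4 <- correct_batch(c(1, 2, 9), c("A", "A", "B"))
  expect_equal(as.numeric(r4), c(-0.5, 0.5, 0))
  expect_equal(attr(r4, "flagged"), 3L)
})
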