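two_class <- c("fertile", "subfertile")

test_that("coverage-weighted class methylation pools reads", {
  # fertile samples (2/10) and (9/30): 100 * 11/40 = 27.5
  m <- tiny_matrix(meth = rbind(c(2L, 9L, 3L)),
                   total = rbind(c(10L, 30L, 4L)))
  wm <- weighted_group_methylation(m, c("fertile", "fertile", "subfertile"),
                                   coverage_filter(m, 1L))
  expect_equal(unname(wm[1, "fertile"]), 27.5)
  expect_equal(unname(wm[1, "subfertile"]), 75)
  # with equal coverages the weighted value equals the unweighted mean
  m2 <- tiny_matrix(meth = rbind(c(2L, 6L, 1L, 5L)),
                    total = rbind(c(20L, 20L, 20L, 20L)))
  cls <- c("fertile", "fertile", "subfertile", "subfertile")
  wm2 <- weighted_group_methylation(m2, cls, coverage_filter(m2, 1L))
  expect_equal(unname(wm2[1, "fertile"]), mean(c(2, 6) / 20 * 100),
               tolerance = 1e-9)
})

test_that("pooled LR test agrees with a per-sample binomial GLM", {
  set.seed(8)
  for (rep in 1:20) {
    n <- matrix(rpois(12, 20) + 1L, 2, 6)
    pr <- runif(1, 0.1, 0.9)
    mm <- matrix(rbinom(12, as.vector(n), pr), 2, 6)
    mat <- tiny_matrix(meth = mm, total = n)
    cls <- rep(two_class, each = 3)
    p <- dmc_test_pooled(mat, cls, coverage_filter(mat, 1L))
    for (i in 1:2) {
      fit <- glm(cbind(mm[i, ], n[i, ] - mm[i, ]) ~ factor(cls),
                 family = binomial)
      p_glm <- anova(fit, test = "LRT")$`Pr(>Chi)`[2]
      expect_equal(unname(p[i]), p_glm, tolerance = 1e-8)
    }
  }
})

test_that("pooled test null identity and Fisher decision agreement", {
  m <- tiny_matrix(meth = rbind(c(5L, 5L)), total = rbind(c(10L, 10L)))
  p <- dmc_test_pooled(m, two_class, coverage_filter(m, 1L))
  expect_equal(unname(p[1]), 1)
  # one sample per class, 8/10 vs 1/10: same decision as Fisher's exact test
  m2 <- tiny_matrix(meth = rbind(c(8L, 1L)), total = rbind(c(10L, 10L)))
  p2 <- unname(dmc_test_pooled(m2, two_class, coverage_filter(m2, 1L))[1])
  # two-sided Fisher by full enumeration of the hypergeometric support
  support <- 0:9  # methylated in class A given margins (9 meth, 10+10 trials)
  probs <- dhyper(support, 10, 10, 9)
  p_fisher <- sum(probs[probs <= dhyper(8, 10, 10, 9) * (1 + 1e-7)])
  expect_true((p2 < 0.05) == (p_fisher < 0.05))
  expect_error(dmc_test_pooled(
    tiny_matrix(meth = rbind(c(1L, NA)), total = rbind(c(10L, NA))),
    two_class, coverage_filter(tiny_matrix(meth = rbind(c(1L, NA)),
                                           total = rbind(c(10L, NA))), 1L)),
    "zero total")
})

test_that("dispersion-aware test matches pooled at zero dispersion and
           deflates inflated sites", {
  # equal per-sample proportions within class -> zero estimated dispersion
  m <- tiny_matrix(meth = rbind(c(6L, 12L, 10L, 20L)),
                   total = rbind(c(20L, 40L, 20L, 40L)))
  cls <- rep(two_class, each = 2)
  cpg <- coverage_filter(m, 1L)
  p_disp <- unname(dmc_test_dispersion(m, cls, cpg)[1])
  p_pool <- unname(dmc_test_pooled(m, cls, cpg)[1])
  expect_gt(p_disp, p_pool / 2)
  expect_lt(p_disp, p_pool * 2)
  # similar class means but highly variable samples -> larger p than pooled
  m2 <- tiny_matrix(meth = rbind(c(2L, 18L, 16L, 18L)),
                    total = rbind(rep(20L, 4)))
  p2_disp <- unname(dmc_test_dispersion(m2, cls, coverage_filter(m2, 1L))[1])
  p2_pool <- unname(dmc_test_pooled(m2, cls, coverage_filter(m2, 1L))[1])
  expect_gt(p2_disp, p2_pool)
  # fewer than two covered samples in a class -> skipped, not guessed
  m3 <- tiny_matrix(meth = rbind(c(2L, NA, 9L, 11L)),
                    total = rbind(c(20L, NA, 20L, 20L)))
  p3 <- dmc_test_dispersion(m3, cls, coverage_filter(m3, 1L))
  expect_true(is.na(p3[1]))
  expect_equal(attr(p3, "skipped"), 1L)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(200)
  expect_equal(adjust_pvalues(p), oracle_bh(p))
  expect_true(all(adjust_pvalues(p) >= p))
  expect_error(adjust_pvalues(c(0.1, NaN)), "NaN")
})

test_that("DMC calling requires both the q and the difference criterion", {
  set.seed(5)
  # strong signal but small difference: never a DMC
  nA <- 4000L; nB <- 4000L
  m <- tiny_matrix(meth = rbind(c(as.integer(0.50 * nA),
                                  as.integer(0.55 * nB))),
                   total = rbind(c(nA, nB)))
  d <- call_dmcs(m, two_class, cpg10 = coverage_filter(m, 1L),
                 keep_all = TRUE)
  expect_lt(d$q[1], 1e-3)          # highly significant...
  expect_lt(abs(d$delta[1]), 10)   # ...but a 5-point difference
  expect_false(d$is_dmc[1])
  # q_threshold = 1, diff_threshold = 0 returns every tested site
  sim <- small_cohort(n_per_class = 6L, n_cpg = 300L, seed = 23L)
  d2 <- call_dmcs(sim$matrix, sim$sheet$fertility, q_threshold = 1.01,
                  diff_threshold = 0, cpg10 = coverage_filter(sim$matrix, 1L))
  expect_equal(nrow(d2), attr(d2, "n_tested"))
})

test_that("delta is antisymmetric under class-label swap and order-invariant", {
  sim <- small_cohort(n_per_class = 6L, n_cpg = 300L, seed = 29L,
                      frac_dmc = 0.05, effect_delta = 30)
  cls <- sim$sheet$fertility
  cpg <- coverage_filter(sim$matrix)
  d1 <- call_dmcs(sim$matrix, cls, cpg10 = cpg, keep_all = TRUE)
  swapped <- ifelse(cls == "fertile", "subfertile", "fertile")
  d2 <- call_dmcs(sim$matrix, swapped, cpg10 = cpg, keep_all = TRUE)
  expect_equal(d1$delta, -d2$delta)
  hyper1 <- d1$direction == "hyper"
  expect_equal(d1$direction[hyper1], rep("hyper", sum(hyper1)))
  expect_equal(d2$direction[hyper1 & d1$delta != 0],
               rep("hypo", sum(hyper1 & d1$delta != 0)))
  # permuting samples leaves the DMC set unchanged
  perm <- sample(seq_along(cls))
  mp <- subset_matrix(sim$matrix, samples = perm)
  d3 <- call_dmcs(mp, cls[perm], cpg10 = cpg[, perm], keep_all = TRUE)
  expect_equal(d1$p, d3$p)
  expect_equal(d1$is_dmc, d3$is_dmc)
})

test_that("repeat profiles report per-position class differences and trends", {
  # identical counts in both classes -> zero difference everywhere
  mm <- matrix(rep(c(5L, 5L), each = 10), 10, 2)
  tt <- matrix(20L, 10, 2)
  m <- tiny_matrix(meth = mm, total = tt, pos = seq(10L, 100L, by = 10L))
  pr <- repeat_profile(m, two_class)
  expect_true(all(pr$profile$difference == 0))
  expect_equal(pr$mean_difference, 0)
  # fertile 40.0% vs subfertile 37.3% at all 60 positions -> mean diff -2.7
  mm2 <- cbind(rep(400L, 60), rep(373L, 60))
  tt2 <- matrix(1000L, 60, 2)
  m2 <- tiny_matrix(meth = mm2, total = tt2, pos = seq_len(60) * 5L)
  pr2 <- repeat_profile(m2, two_class)
  expect_equal(pr2$mean_difference, -2.7, tolerance = 1e-9)
  # single position: mean difference equals that position's difference
  m3 <- tiny_matrix(meth = rbind(c(10L, 5L)), total = rbind(c(20L, 20L)))
  pr3 <- repeat_profile(m3, two_class)
  expect_equal(pr3$mean_difference, pr3$profile$difference[1])
  expect_true(is.na(pr3$profile[[5]][1]))  # trend undefined at one position
})

test_that("pooled-test power is non-decreasing in coverage", {
  ann <- simulate_annotation(2, 2e5, seed = 41)
  power_at <- function(cov) {
    p <- sim_params(n_fertile = 10, n_subfertile = 10, n_cpg = 400,
                    frac_dmc = 0.2, effect_delta = 12, indiv_sd = 0,
                    missing_rate = 0, frac_variant_sites = 0,
                    cov_mean = cov, seed = 99)
    sim <- simulate_methylation(p, ann)
    cls <- attr(sim$matrix, "sample_sheet")$fertility
    pv <- dmc_test_pooled(sim$matrix, cls, coverage_filter(sim$matrix, 1L))
    mean(pv[sim$truth$is_planted_dmc] < 0.01)
  }
  pw <- vapply(c(5, 15, 40), power_at, numeric(1))
  expect_true(all(diff(pw) >= -0.02))  # monotone up to simulation noise
})
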