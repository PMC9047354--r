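#' Coverage-weighted per-class methylation percentages
#'
#' The percentage of a class at a site is `100 * sum(methylated) /
#' sum(total)` over the class's CpG10 cells, i.e. samples with higher
#' coverage weigh more; with equal coverages it reduces to the unweighted
#' mean of per-sample percentages.
#'
#' @param matrix a [meth_count_matrix()].
#' @param classes per-sample class labels (two levels).
#' @param cpg10 logical CpG10 mask (default: coverage >= 10).
#' @param sites optional site subset (indices or logical).
#' @return numeric matrix, sites x classes, percentages (`NaN` where a class
#'   has no covered cell).
#' @export
weighted_group_methylation <- function(matrix, classes,
                                       cpg10 = coverage_filter(matrix),
                                       sites = NULL) {
  stopifnot(inherits(matrix, "MethCountMatrix"))
  classes <- as.character(classes)
  lev <- sort(unique(classes))
  meth <- matrix$meth; total <- matrix$total
  meth[!cpg10] <- NA_integer_; total[!cpg10] <- NA_integer_
  if (!is.null(sites)) {
    meth <- meth[sites, , drop = FALSE]; total <- total[sites, , drop = FALSE]
  }
  out <- vapply(lev, function(l) {
    j <- classes == l
    100 * rowSums(meth[, j, drop = FALSE], na.rm = TRUE) /
      rowSums(total[, j, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(meth)))
  out <- base::matrix(out, ncol = length(lev), dimnames = list(NULL, lev))
  out
}

#' @noRd
binom_ll <- function(m, n, p) {
  # log-likelihood kernel with 0*log(0) = 0
  t1 <- ifelse(m > 0, m * log(p), 0)
  t2 <- ifelse(n - m > 0, (n - m) * log1p(-p), 0)
  t1 + t2
}

#' Coverage-pooled likelihood-ratio DMC test
#'
#' Likelihood-ratio test of a binomial (logistic) regression of
#' `(methylated, unmethylated)` counts on class membership. Because class is
#' the only covariate, the fit is saturated in the class-pooled proportions,
#' giving a closed-form LR statistic compared to chi-square(1). Pooling reads
#' across samples makes the test powerful but blind to inter-individual
#' variability. Returns exactly 1 when both pooled proportions are equal.
#'
#' @inheritParams weighted_group_methylation
#' @return numeric vector of two-sided p-values, one per site; attribute
#'   `"stat"` carries the LR statistics.
#' @export
dmc_test_pooled <- function(matrix, classes,
                            cpg10 = coverage_filter(matrix), sites = NULL) {
  stopifnot(inherits(matrix, "MethCountMatrix"))
  classes <- as.character(classes)
  lev <- sort(unique(classes))
  if (length(lev) != 2L) stop("exactly two classes are required")
  meth <- matrix$meth; total <- matrix$total
  meth[!cpg10] <- NA_integer_; total[!cpg10] <- NA_integer_
  if (!is.null(sites)) {
    meth <- meth[sites, , drop = FALSE]; total <- total[sites, , drop = FALSE]
  }
  jA <- classes == lev[1]
  mA <- rowSums(meth[, jA, drop = FALSE], na.rm = TRUE)
  nA <- rowSums(total[, jA, drop = FALSE], na.rm = TRUE)
  mB <- rowSums(meth[, !jA, drop = FALSE], na.rm = TRUE)
  nB <- rowSums(total[, !jA, drop = FALSE], na.rm = TRUE)
  if (any(nA == 0) || any(nB == 0))
    stop("site with zero total reads in a class; filter the background first")
  pA <- mA / nA; pB <- mB / nB; p0 <- (mA + mB) / (nA + nB)
  lr <- 2 * (binom_ll(mA, nA, pA) + binom_ll(mB, nB, pB) -
             binom_ll(mA, nA, p0) - binom_ll(mB, nB, p0))
  lr <- pmax(lr, 0)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  p[pA == pB] <- 1
  attr(p, "stat") <- lr
  p
}

#' Dispersion-aware beta-binomial DMC test
#'
#' Wald test on the difference of class mean methylation proportions using a
#' beta-binomial variance. The intra-class (beta-binomial) correlation is
#' estimated per class by method of moments from the per-sample proportions
#' and coverages, floored at 0; no shrinkage across sites is performed. With
#' zero estimated dispersion in both classes the test reduces to a
#' two-proportion z-test on the pooled counts. Sites with fewer than two
#' CpG10 samples in either class are returned as `NA` and counted in the
#' `"skipped"` attribute.
#'
#' @inheritParams weighted_group_methylation
#' @return numeric vector of two-sided p-values (`NA` where skipped);
#'   attributes `"stat"` (Wald z) and `"skipped"` (count).
#' @export
dmc_test_dispersion <- function(matrix, classes,
                                cpg10 = coverage_filter(matrix),
                                sites = NULL) {
  stopifnot(inherits(matrix, "MethCountMatrix"))
  classes <- as.character(classes)
  lev <- sort(unique(classes))
  if (length(lev) != 2L) stop("exactly two classes are required")
  meth <- matrix$meth; total <- matrix$total
  meth[!cpg10] <- NA_integer_; total[!cpg10] <- NA_integer_
  if (!is.null(sites)) {
    meth <- meth[sites, , drop = FALSE]; total <- total[sites, , drop = FALSE]
  }
  class_stats <- function(j) {
    m <- meth[, j, drop = FALSE]; n <- total[, j, drop = FALSE]
    k <- rowSums(!is.na(n))
    N <- rowSums(n, na.rm = TRUE)
    M <- rowSums(m, na.rm = TRUE)
    phat <- M / N
    S <- rowSums(n * (m / n - phat)^2, na.rm = TRUE)
    sum_n2 <- rowSums(n^2, na.rm = TRUE)
    denom <- N - sum_n2 / N - (k - 1)
    pq <- phat * (1 - phat)
    rho <- ifelse(pq > 0 & denom > 0, (S / pmax(pq, 1e-12) - (k - 1)) / denom,
                  0)
    rho <- pmin(pmax(rho, 0), 1)  # floored at 0
    v <- pq * (N + rho * rowSums(n * (n - 1), na.rm = TRUE)) / N^2
    list(k = k, phat = phat, var = v)
  }
  A <- class_stats(classes == lev[1])
  B <- class_stats(classes == lev[2])
  ok <- A$k >= 2 & B$k >= 2
  se <- sqrt(A$var + B$var)
  z <- ifelse(se > 0, (A$phat - B$phat) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  zerovar <- se == 0
  p[zerovar] <- ifelse(A$phat[zerovar] == B$phat[zerovar], 1, 0)
  p[A$phat == B$phat] <- 1
  p[!ok] <- NA_real_
  attr(p, "stat") <- ifelse(ok, z, NA_real_)
  attr(p, "skipped") <- sum(!ok)
  p
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p numeric p-values in \[0, 1\]; `NA` entries (e.g. skipped sites)
#'   are passed through as `NA`.
#' @param method only `"bh"` is offered.
#' @return q-values, monotone non-decreasing after sorting by p.
#' @export
adjust_pvalues <- function(p, method = c("bh")) {
  method <- match.arg(method)
  if (any(is.nan(p))) stop("NaN p-values")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated cytosines
#'
#' A site is a DMC iff its BH q-value is below `q_threshold` and the absolute
#' coverage-weighted class difference is at least `diff_threshold` percentage
#' points. Defaults follow the test: the pooled test uses q < 0.01, the
#' dispersion-aware test q < 0.1; both require a 10-point difference.
#' `delta` is alt-class minus ref-class (subfertile minus fertile), so
#' `direction = "hyper"` means hypermethylated in the subfertile class.
#'
#' @inheritParams weighted_group_methylation
#' @param test `"pooled"` or `"dispersion"`.
#' @param q_threshold q-value cut; `NULL` picks the test default.
#' @param diff_threshold minimal absolute difference in percentage points.
#' @param ref,alt class labels for the reference (fertile) and alternative
#'   (subfertile) group.
#' @param keep_all return every tested site (with an `is_dmc` column) rather
#'   than DMCs only.
#' @return data.frame `chrom, pos, p, q, meth_<ref>, meth_<alt>, delta,
#'   direction, test, is_dmc`; attribute `"n_tested"`.
#' @export
call_dmcs <- function(matrix, classes, test = c("pooled", "dispersion"),
                      q_threshold = NULL, diff_threshold = 10,
                      cpg10 = coverage_filter(matrix),
                      ref = "fertile", alt = "subfertile",
                      keep_all = FALSE) {
  test <- match.arg(test)
  classes <- as.character(classes)
  if (!all(sort(unique(classes)) == sort(c(ref, alt))))
    stop("classes must take exactly the labels '", ref, "' and '", alt, "'")
  if (is.null(q_threshold))
    q_threshold <- if (test == "pooled") 0.01 else 0.1
  p <- if (test == "pooled") dmc_test_pooled(matrix, classes, cpg10)
       else dmc_test_dispersion(matrix, classes, cpg10)
  q <- adjust_pvalues(p)
  wm <- weighted_group_methylation(matrix, classes, cpg10)
  delta <- wm[, alt] - wm[, ref]
  out <- data.frame(chrom = matrix$sites$chrom, pos = matrix$sites$pos,
                    p = as.numeric(p), q = q,
                    meth_ref = wm[, ref], meth_alt = wm[, alt],
                    delta = delta,
                    direction = ifelse(delta > 0, "hyper",
                                       ifelse(delta < 0, "hypo", "none")),
                    test = test, stringsAsFactors = FALSE)
  names(out)[names(out) == "meth_ref"] <- paste0("meth_", ref)
  names(out)[names(out) == "meth_alt"] <- paste0("meth_", alt)
  out$is_dmc <- !is.na(q) & q < q_threshold & abs(delta) >= diff_threshold
  n_tested <- sum(!is.na(p))
  if (!keep_all) out <- out[out$is_dmc, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  attr(out, "q_threshold") <- q_threshold
  attr(out, "diff_threshold") <- diff_threshold
  out
}

#' Write a DMC/DMR table as TSV and BED
#'
#' @param tab data.frame with `chrom` and `pos` (sites) or `chrom, start,
#'   end` (regions).
#' @param path_tsv,path_bed output paths (`NULL` skips either).
#' @export
write_dmc_table <- function(tab, path_tsv = NULL, path_bed = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(tab, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(path_bed)) {
    iv <- if ("start" %in% names(tab))
      data.frame(chrom = tab$chrom, start = tab$start, end = tab$end)
    else data.frame(chrom = tab$chrom, start = tab$pos, end = tab$pos)
    if ("direction" %in% names(tab)) iv$name <- tab$direction
    write_bed(iv, path_bed)
  }
  invisible(NULL)
}

#' Per-position methylation profile of a consensus repeat
#'
#' For a matrix restricted to the CpG positions of one Repbase-style
#' consensus repeat, computes the coverage-weighted methylation of each class
#' at every position, the per-position class difference, its overall mean,
#' and a moving-average trend per class.
#'
#' @inheritParams weighted_group_methylation
#' @param window moving-average window (positions) for the trend.
#' @param ref,alt class labels, difference = alt - ref.
#' @return list with `profile` (data.frame `pos, meth_<ref>, meth_<alt>,
#'   difference, trend_<ref>, trend_<alt>`) and `mean_difference`.
#' @export
repeat_profile <- function(matrix, classes,
                           cpg10 = coverage_filter(matrix, 1L),
                           window = 5L, ref = "fertile", alt = "subfertile") {
  wm <- weighted_group_methylation(matrix, classes, cpg10)
  ord <- order(matrix$sites$pos)
  pos <- matrix$sites$pos[ord]
  a <- wm[ord, ref]; b <- wm[ord, alt]
  trend <- function(x) {
    if (length(x) < 2L) return(rep(NA_real_, length(x)))
    w <- min(window, length(x))
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  }
  prof <- data.frame(pos = pos, meth_ref = a, meth_alt = b,
                     difference = b - a,
                     trend_ref = trend(a), trend_alt = trend(b))
  names(prof) <- c("pos", paste0("meth_", ref), paste0("meth_", alt),
                   "difference", paste0("trend_", ref), paste0("trend_", alt))
  list(profile = prof, mean_difference = mean(b - a, na.rm = TRUE))
}
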