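#' Per-cell coverage filter (CpG10 status)
#'
#' A cell (site x sample) has CpG10 status iff it is covered by at least
#' `min_reads` reads; "at least" is inclusive, so a total of exactly 10
#' passes the default. Not-covered cells never qualify.
#'
#' @param matrix a [meth_count_matrix()].
#' @param min_reads minimum total reads (default 10).
#' @return logical sites x samples matrix of CpG10 status.
#' @export
coverage_filter <- function(matrix, min_reads = 10L) {
  stopifnot(inherits(matrix, "MethCountMatrix"))
  min_reads <- check_count(min_reads, "min_reads", 1L)
  mask <- !is.na(matrix$total) & matrix$total >= min_reads
  mask[is.na(mask)] <- FALSE
  mask
}

#' Group-presence filter defining the testing background
#'
#' A site is kept iff its number of CpG10 samples reaches `min_per_group` in
#' each of the two fertility classes. `"auto"` uses half of the smallest
#' class, rounded up (`ceiling(min(class sizes) / 2)`), which yields 22 for
#' classes of 57 and 43 samples.
#'
#' @param cpg10 logical mask from [coverage_filter()].
#' @param classes character/factor vector of length `ncol(cpg10)` with two
#'   levels.
#' @param min_per_group integer threshold or `"auto"`.
#' @return logical vector over sites; attribute `"threshold"` records the
#'   resolved threshold.
#' @export
group_presence_filter <- function(cpg10, classes, min_per_group = "auto") {
  classes <- as.character(classes)
  stopifnot(length(classes) == ncol(cpg10))
  lev <- unique(classes)
  if (length(lev) != 2L) stop("exactly two classes are required")
  sizes <- table(classes)
  if (any(sizes == 0)) stop("a class has zero samples")
  if (identical(min_per_group, "auto"))
    min_per_group <- ceiling(min(sizes) / 2)
  min_per_group <- check_count(min_per_group, "min_per_group", 1L)
  n1 <- rowSums(cpg10[, classes == lev[1], drop = FALSE])
  n2 <- rowSums(cpg10[, classes == lev[2], drop = FALSE])
  keep <- n1 >= min_per_group & n2 >= min_per_group
  attr(keep, "threshold") <- as.integer(min_per_group)
  keep
}

#' Variant-mask filter
#'
#' Removes every CpG that co-localizes with a masked sequence polymorphism.
#' The mask lists 1-based positions; a strand-merged CpG at position `pos`
#' spans `pos` (the C) and `pos + 1` (the G), and is removed if either
#' position is masked.
#'
#' @param sites data.frame `chrom, pos` (the C positions).
#' @param mask data.frame `chrom, pos` of masked positions.
#' @return logical vector, `TRUE` for retained sites.
#' @export
variant_mask_filter <- function(sites, mask) {
  if (nrow(mask) == 0L) return(rep(TRUE, nrow(sites)))
  key <- paste(mask$chrom, mask$pos)
  !(paste(sites$chrom, sites$pos) %in% key |
    paste(sites$chrom, sites$pos + 1L) %in% key)
}

#' Apply the site-retention rules in order and account for removals
#'
#' Rules, applied with first-matching-rule attribution: (1) chromosome
#' allow-list (unplaced-scaffold removal), (2) variant mask, (3) group
#' presence of CpG10 coverage. The per-cell coverage rule defines CpG10
#' status used by rule 3 and by all downstream summaries; it removes cells,
#' not sites. The accounting identity
#' `sites_out = sites_in - sum(removed)` holds exactly.
#'
#' @param matrix a [meth_count_matrix()].
#' @param classes per-sample class labels.
#' @param min_reads coverage threshold for CpG10 status.
#' @param min_per_group see [group_presence_filter()].
#' @param mask optional variant-mask data.frame `chrom, pos`.
#' @param chrom_allow optional character vector of allowed chromosomes.
#' @return list with `matrix` (filtered, background sites only), `cpg10`
#'   (mask aligned to the filtered matrix) and `report` (a `FilterReport`
#'   list: `sites_in`, `removed` by rule, `sites_out`, `thresholds`).
#' @export
apply_site_filters <- function(matrix, classes, min_reads = 10L,
                               min_per_group = "auto", mask = NULL,
                               chrom_allow = NULL) {
  stopifnot(inherits(matrix, "MethCountMatrix"))
  n_in <- nrow(matrix$sites)
  alive <- rep(TRUE, n_in)
  removed <- c(scaffold = 0L, variant_mask = 0L, group_presence = 0L)
  if (!is.null(chrom_allow)) {
    drop <- alive & !(matrix$sites$chrom %in% chrom_allow)
    removed["scaffold"] <- sum(drop); alive[drop] <- FALSE
  }
  if (!is.null(mask)) {
    keep <- variant_mask_filter(matrix$sites, mask)
    drop <- alive & !keep
    removed["variant_mask"] <- sum(drop); alive[drop] <- FALSE
  }
  cpg10_all <- coverage_filter(matrix, min_reads)
  gp <- group_presence_filter(cpg10_all, classes, min_per_group)
  drop <- alive & !gp
  removed["group_presence"] <- sum(drop); alive[drop] <- FALSE
  out <- subset_matrix(matrix, sites = which(alive))
  attr(out, "sample_sheet") <- attr(matrix, "sample_sheet")
  report <- structure(list(
    sites_in = n_in, removed = as.list(removed),
    sites_out = sum(alive),
    thresholds = list(min_reads = as.integer(min_reads),
                      min_per_group = attr(gp, "threshold"))),
    class = "FilterReport")
  stopifnot(report$sites_out == report$sites_in - sum(unlist(report$removed)))
  list(matrix = out, cpg10 = cpg10_all[alive, , drop = FALSE],
       report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %d sites in, %d out\n", x$sites_in, x$sites_out))
  for (nm in names(x$removed))
    cat(sprintf("  removed by %s: %d\n", nm, x$removed[[nm]]))
  invisible(x)
}

#' Per-sample global methylation summary
#'
#' Computed over CpG10 cells only: mean methylation percentage and the
#' fractions of hypomethylated (< 20%), intermediate (\[20%, 80%\], closed
#' interval) and hypermethylated (> 80%) CpGs10. The three fractions sum
#' to 1. Samples with zero CpG10 cells get `NA` summaries and are flagged.
#'
#' @param matrix a [meth_count_matrix()].
#' @param cpg10 logical mask from [coverage_filter()] (same dimensions).
#' @param sites optional logical/integer site subset over which to summarize.
#' @return data.frame `sample_id, n_cpg10, mean_meth, frac_hypo,
#'   frac_intermediate, frac_hyper, undefined`.
#' @export
global_summary <- function(matrix, cpg10 = coverage_filter(matrix),
                           sites = NULL) {
  stopifnot(inherits(matrix, "MethCountMatrix"))
  pct <- meth_percent(matrix)
  if (!is.null(sites)) {
    pct <- pct[sites, , drop = FALSE]
    cpg10 <- cpg10[sites, , drop = FALSE]
  }
  pct[!cpg10] <- NA_real_
  n10 <- colSums(cpg10)
  res <- data.frame(
    sample_id = matrix$samples, n_cpg10 = n10,
    mean_meth = colMeans(pct, na.rm = TRUE),
    frac_hypo = colMeans(pct < 20, na.rm = TRUE),
    frac_intermediate = colMeans(pct >= 20 & pct <= 80, na.rm = TRUE),
    frac_hyper = colMeans(pct > 80, na.rm = TRUE),
    stringsAsFactors = FALSE)
  res$undefined <- n10 == 0L
  res[res$undefined, c("mean_meth", "frac_hypo", "frac_intermediate",
                       "frac_hyper")] <- NA_real_
  rownames(res) <- NULL
  res
}
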