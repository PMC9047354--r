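#' Per-CpG methylation count matrix
#'
#' The central container of the package: per-CpG, per-sample methylated and
#' total read counts, from which every methylation percentage is derived.
#' "Not covered" is a first-class state encoded as `NA` in both count layers;
#' it is never conflated with a covered cell of zero methylation. Percentages
#' are always recomputed from counts (`methylated * 100 / total`) and never
#' stored independently.
#'
#' @param sites data.frame with columns `chrom` (character) and `pos`
#'   (1-based integer position of the C of the CpG, strand-merged).
#' @param meth,total integer matrices (sites x samples) of methylated and
#'   total read counts; `NA` marks cells with no coverage.
#' @param samples character vector of sample identifiers (column names).
#' @return an object of class `MethCountMatrix`.
#' @export
meth_count_matrix <- function(sites, meth, total, samples) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (!all(dim(meth) == dim(total)))
    stop("'meth' and 'total' must have identical dimensions")
  if (nrow(meth) != nrow(sites))
    stop("count matrices must have one row per site")
  if (ncol(meth) != length(samples))
    stop("count matrices must have one column per sample")
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicate (chrom, pos) sites are not allowed")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  cov <- !is.na(total)
  if (any(is.na(meth[cov]))) stop("covered cells must have methylated counts")
  if (any(meth[cov] < 0) || any(total[cov] < 1))
    stop("covered cells need total >= 1 and methylated >= 0")
  if (any(meth[cov] > total[cov]))
    stop("methylated counts exceed totals")
  dimnames(meth) <- dimnames(total) <- list(NULL, samples)
  structure(list(sites = sites[, c("chrom", "pos")], meth = meth,
                 total = total, samples = as.character(samples)),
            class = "MethCountMatrix")
}

#' @export
dim.MethCountMatrix <- function(x) c(nrow(x$sites), length(x$samples))

#' @export
print.MethCountMatrix <- function(x, ...) {
  cov <- mean(!is.na(x$total)) * 100
  cat(sprintf("MethCountMatrix: %d CpG sites x %d samples (%.1f%% cells covered)\n",
              nrow(x$sites), length(x$samples), cov))
  invisible(x)
}

#' Methylation percentages derived from counts
#'
#' @param x a [meth_count_matrix()].
#' @return numeric matrix of percentages in \[0, 100\], `NA` where not covered.
#' @export
meth_percent <- function(x) {
  stopifnot(inherits(x, "MethCountMatrix"))
  x$meth * 100 / x$total
}

#' Subset a count matrix by site index and/or sample
#'
#' @param x a [meth_count_matrix()].
#' @param sites integer or logical index over rows.
#' @param samples character, integer or logical index over samples.
#' @return a [meth_count_matrix()].
#' @export
subset_matrix <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "MethCountMatrix"))
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  sj <- if (is.null(samples)) seq_along(x$samples) else samples
  if (is.character(sj)) sj <- match(sj, x$samples)
  meth_count_matrix(x$sites[si, , drop = FALSE],
                    x$meth[si, sj, drop = FALSE],
                    x$total[si, sj, drop = FALSE],
                    x$samples[sj])
}

#' Read a Bismark coverage file for one sample
#'
#' Parses the standard Bismark `.cov` dialect: tab-separated
#' `chrom, start, end, methylation%, count_methylated, count_unmethylated`
#' with 1-based per-base records (`start == end`). The stated percentage is
#' recomputed from the counts, which are authoritative; lines whose stated
#' percentage deviates from `count_meth * 100 / total` by more than 0.05 are
#' kept with the recomputed value and reported via a `"discrepancies"`
#' attribute.
#'
#' @param path file path.
#' @param sample_id identifier attached to the returned table.
#' @return data.frame `chrom, pos, meth, total, pct` with attributes
#'   `sample_id` and `discrepancies` (line numbers, possibly empty).
#' @export
read_bismark_cov <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer(), pct = numeric())
    attr(out, "sample_id") <- sample_id
    attr(out, "discrepancies") <- integer()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop(sprintf("line %d: expected 6 tab-separated fields, got %d",
                 which(nf != 6L)[1], nf[nf != 6L][1]))
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  cm <- suppressWarnings(as.numeric(m[, 5]))
  cu <- suppressWarnings(as.numeric(m[, 6]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(cm) | is.na(cu) | is.na(pct))
  if (length(bad))
    stop(sprintf("line %d: non-numeric field", bad[1]))
  bad <- which(start != end)
  if (length(bad))
    stop(sprintf("line %d: start != end (per-base records required)", bad[1]))
  bad <- which(cm != round(cm) | cu != round(cu) | cm < 0 | cu < 0 |
               start < 1 | start != round(start))
  if (length(bad))
    stop(sprintf("line %d: counts must be non-negative integers and pos >= 1",
                 bad[1]))
  total <- as.integer(cm + cu)
  if (any(total == 0L))
    stop(sprintf("line %d: zero total reads", which(total == 0L)[1]))
  true_pct <- cm * 100 / total
  disc <- which(abs(pct - true_pct) > 0.05)
  out <- data.frame(chrom = m[, 1], pos = as.integer(start),
                    meth = as.integer(cm), total = total, pct = true_pct,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "discrepancies") <- disc
  out
}

#' Write one sample's counts as a Bismark coverage file
#'
#' @param tab data.frame as returned by [read_bismark_cov()] (columns
#'   `chrom, pos, meth, total`).
#' @param path output path.
#' @export
write_bismark_cov <- function(tab, path) {
  stopifnot(all(c("chrom", "pos", "meth", "total") %in% names(tab)))
  pct <- ifelse(tab$total > 0, tab$meth * 100 / tab$total, NA_real_)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", tab$chrom, tab$pos, tab$pos,
                   formatC(pct, format = "fg", digits = 15, flag = "#"),
                   tab$meth, tab$total - tab$meth)
  # formatC with "#" can leave a trailing "."; normalize
  lines <- sub("\\.\t", "\t", lines)
  writeLines(lines, path)
}

#' Assemble per-sample count tables into a MethCountMatrix
#'
#' The site universe is the union of all per-sample sites; sites absent from
#' a sample are marked not-covered. Chromosomes keep their order of first
#' appearance across the inputs; positions are ascending within chromosome.
#'
#' @param tables named list of per-sample tables (names are sample ids), each
#'   as returned by [read_bismark_cov()].
#' @param sample_sheet optional data.frame with a `sample_id` column; every
#'   sample in the sheet must have a table.
#' @return a [meth_count_matrix()]; the sheet (if given) is attached as
#'   attribute `"sample_sheet"` ordered like the columns.
#' @export
assemble_matrix <- function(tables, sample_sheet = NULL) {
  if (!is.null(sample_sheet)) {
    stopifnot("sample_id" %in% names(sample_sheet))
    missing <- setdiff(sample_sheet$sample_id, names(tables))
    if (length(missing))
      stop("samples in sheet without a count table: ",
           paste(missing, collapse = ", "))
    tables <- tables[as.character(sample_sheet$sample_id)]
  }
  ids <- names(tables)
  if (is.null(ids) || any(!nzchar(ids))) stop("tables must be a named list")
  for (id in ids) {
    t <- tables[[id]]
    if (anyDuplicated(paste(t$chrom, t$pos)))
      stop(sprintf("duplicate (chrom, pos) within sample '%s'", id))
  }
  chrom_order <- unique(unlist(lapply(tables, function(t) unique(t$chrom))))
  all_sites <- unique(do.call(rbind, lapply(tables, function(t)
    t[, c("chrom", "pos")])))
  all_sites <- all_sites[order(match(all_sites$chrom, chrom_order),
                               all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  key <- paste(all_sites$chrom, all_sites$pos)
  n <- nrow(all_sites)
  meth <- matrix(NA_integer_, n, length(ids))
  total <- matrix(NA_integer_, n, length(ids))
  for (j in seq_along(ids)) {
    t <- tables[[ids[j]]]
    idx <- match(paste(t$chrom, t$pos), key)
    meth[idx, j] <- t$meth
    total[idx, j] <- t$total
  }
  out <- meth_count_matrix(all_sites, meth, total, ids)
  if (!is.null(sample_sheet)) attr(out, "sample_sheet") <- sample_sheet
  out
}

#' Read genomic intervals in BED or 1-based TSV dialect
#'
#' BED input is 0-based half-open and converted on read; the `one_based_tsv`
#' dialect is 1-based inclusive. All intervals are normalized internally to
#' 1-based inclusive coordinates. A strand column (4th for `one_based_tsv`,
#' 6th for BED) is kept when present.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"one_based_tsv"`.
#' @return data.frame `chrom, start, end` (1-based inclusive) plus `name` and
#'   `strand` when present in the input.
#' @export
read_intervals <- function(path, dialect = c("bed", "one_based_tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(parts))
  if (nf < 3L) stop("interval lines need at least 3 fields")
  m <- t(vapply(parts, function(p) p[1:nf], character(nf)))
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  if (anyNA(start) || anyNA(end)) stop("non-integer interval bounds")
  if (dialect == "bed") start <- start + 1L
  bad <- which(end < start)
  if (length(bad))
    stop(sprintf("line %d: empty or inverted interval after normalization",
                 bad[1]))
  out <- data.frame(chrom = m[, 1], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (nf >= 4L && dialect == "bed") out$name <- m[, 4]
  if (dialect == "bed" && nf >= 6L) out$strand <- m[, 6]
  if (dialect == "one_based_tsv" && nf >= 4L &&
      all(m[, 4] %in% c("+", "-", "."))) out$strand <- m[, 4]
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data.frame `chrom, start, end` (1-based inclusive),
#'   optionally `name` and `score`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  sc <- if ("score" %in% names(intervals)) intervals$score else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", intervals$chrom,
                   intervals$start - 1L, intervals$end, nm, format(sc))
  writeLines(lines, path)
}

#' Read a variant mask (chrom/pos TSV, 1-based)
#'
#' @param path two-column tab-separated file of chromosome and 1-based
#'   position; both members (C and G) of a flagged CpG are expected as rows.
#' @return data.frame `chrom, pos`.
#' @export
read_variant_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(data.frame(chrom = character(), pos = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  m <- t(vapply(parts, function(p) p[1:2], character(2)))
  pos <- as.integer(m[, 2])
  if (anyNA(pos)) stop("non-integer position in variant mask")
  data.frame(chrom = m[, 1], pos = pos, stringsAsFactors = FALSE)
}

#' Read a sample sheet CSV
#'
#' Requires at minimum `sample_id` and `fertility` columns; typical sheets
#' also carry `center`, `batch`, `age_months`, `n_ejaculates` and the
#' corrected NRR 56 estimate.
#'
#' @param path CSV path with header.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fertility")
  missing <- setdiff(need, names(sheet))
  if (length(missing))
    stop("sample sheet lacks mandatory columns: ",
         paste(missing, collapse = ", "))
  sheet
}
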