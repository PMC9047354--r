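#' Merge DMCs into differentially methylated regions
#'
#' A DMR is a maximal run of consecutive DMCs on one chromosome in which
#' every inter-DMC distance is at most `max_gap` bases (inclusive: a gap of
#' exactly 100 bp continues the run) and which contains at least `min_dmcs`
#' members. The region spans the first to the last member DMC. DMRs are not
#' required to be direction-consistent; the direction is the sign of the
#' mean member delta and mixed-direction DMRs are flagged.
#'
#' @param dmcs data.frame with `chrom` and `pos` (and optionally `delta`),
#'   e.g. from [call_dmcs()]; duplicates not allowed.
#' @param min_dmcs minimum member count (default 3).
#' @param max_gap maximal inter-DMC distance in bp (default 100, inclusive).
#' @return data.frame `chrom, start, end, n_dmcs, direction, mixed` (columns
#'   `direction`/`mixed` only when `delta` is available); attribute
#'   `"members"` lists member row indices into `dmcs` per DMR.
#' @export
call_dmrs <- function(dmcs, min_dmcs = 3L, max_gap = 100L) {
  stopifnot(is.data.frame(dmcs), all(c("chrom", "pos") %in% names(dmcs)))
  if (anyDuplicated(paste(dmcs$chrom, dmcs$pos)))
    stop("duplicate DMC positions")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_dmcs = integer())
  if (nrow(dmcs) == 0L) {
    attr(empty, "members") <- list()
    return(empty)
  }
  ord <- order(dmcs$chrom, dmcs$pos)
  out <- list(); members <- list()
  for (ch in unique(dmcs$chrom[ord])) {
    idx <- ord[dmcs$chrom[ord] == ch]
    pos <- dmcs$pos[idx]
    run_id <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    for (r in split(seq_along(pos), run_id)) {
      if (length(r) >= min_dmcs) {
        rec <- data.frame(chrom = ch, start = pos[r[1]],
                          end = pos[r[length(r)]],
                          n_dmcs = length(r), stringsAsFactors = FALSE)
        if ("delta" %in% names(dmcs)) {
          d <- dmcs$delta[idx[r]]
          rec$direction <- ifelse(mean(d) > 0, "hyper",
                                  ifelse(mean(d) < 0, "hypo", "none"))
          rec$mixed <- any(d > 0) && any(d < 0)
        }
        out[[length(out) + 1L]] <- rec
        members[[length(members) + 1L]] <- idx[r]
      }
    }
  }
  if (!length(out)) {
    if ("delta" %in% names(dmcs)) {
      empty$direction <- character(); empty$mixed <- logical()
    }
    attr(empty, "members") <- list()
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "members") <- members
  res
}

#' Per-sample mean methylation over the CpGs of each DMR
#'
#' For every DMR and sample, the unweighted mean of the methylation
#' percentages over the member CpGs with CpG10 status; samples covering no
#' member CpG of a DMR are `NA` (driving, e.g., the subsetting to DMRs
#' covered in all samples).
#'
#' @param dmrs data.frame `chrom, start, end` from [call_dmrs()].
#' @param matrix a [meth_count_matrix()].
#' @param cpg10 logical CpG10 mask for `matrix`.
#' @return numeric matrix, DMRs x samples.
#' @export
dmr_sample_means <- function(dmrs, matrix,
                             cpg10 = coverage_filter(matrix)) {
  stopifnot(inherits(matrix, "MethCountMatrix"))
  pct <- meth_percent(matrix)
  pct[!cpg10] <- NA_real_
  out <- base::matrix(NA_real_, nrow(dmrs), length(matrix$samples),
                      dimnames = list(NULL, matrix$samples))
  for (i in seq_len(nrow(dmrs))) {
    in_dmr <- matrix$sites$chrom == dmrs$chrom[i] &
      matrix$sites$pos >= dmrs$start[i] & matrix$sites$pos <= dmrs$end[i]
    if (any(in_dmr))
      out[i, ] <- colMeans(pct[in_dmr, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

# ---- annotation ------------------------------------------------------------

#' @noRd
gene_windows <- function(bundle) {
  g <- bundle$genes
  w <- bundle$windows
  if (!nrow(g)) return(NULL)
  plus <- g$strand == "+"
  if (any(!g$strand %in% c("+", "-"))) {
    warning("unstranded gene(s) treated as plus strand")
    plus[!g$strand %in% c("+", "-")] <- TRUE
  }
  win <- function(start, end, type)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = pmax(1L, as.integer(start)), end = as.integer(end),
               type = type, stringsAsFactors = FALSE)
  tss_w <- win(g$tss - w$tss, g$tss + w$tss, "TSS")
  prom_w <- win(ifelse(plus, g$tss - w$promoter_upstream,
                       g$tss + w$promoter_downstream),
                ifelse(plus, g$tss - w$promoter_downstream,
                       g$tss + w$promoter_upstream), "promoter")
  tts_w <- win(g$tts - w$tts, g$tts + w$tts, "TTS")
  up_w <- win(ifelse(plus, g$tss - w$upstream, g$tss + 1L),
              ifelse(plus, g$tss - 1L, g$tss + w$upstream), "upstream")
  down_w <- win(ifelse(plus, g$tts + 1L, g$tts - w$downstream),
                ifelse(plus, g$tts + w$downstream, g$tts - 1L), "downstream")
  body_w <- win(g$start, g$end, "gene_body")
  add_type <- function(df, type) if (nrow(df))
    data.frame(df[c("gene_id", "chrom", "start", "end")], type = type)
  else NULL
  rbind(tss_w, prom_w, tts_w,
        add_type(bundle$utr5, "utr5"), add_type(bundle$utr3, "utr3"),
        add_type(bundle$exons, "exon"), up_w, down_w, body_w)
}

#' @noRd
cgi_bands <- function(bundle) {
  cgi <- bundle$cgi
  w <- bundle$windows
  per_chrom <- function(ch) {
    ci <- cgi[cgi$chrom == ch, ]
    ir_cgi <- IRanges::reduce(IRanges::IRanges(ci$start, ci$end))
    ext1 <- IRanges::reduce(ir_cgi + w$shore)
    ext2 <- IRanges::reduce(ir_cgi + (w$shore + w$shelf))
    list(cgi = ir_cgi,
         shore = IRanges::setdiff(ext1, ir_cgi),
         shelf = IRanges::setdiff(ext2, ext1))
  }
  stats::setNames(lapply(unique(cgi$chrom), per_chrom), unique(cgi$chrom))
}

#' @noRd
overlap_width <- function(start, end, ir) {
  # total bp of [start, end] covered by the (reduced) IRanges set
  q <- IRanges::IRanges(start, end)
  hits <- IRanges::findOverlaps(q, ir)
  w <- IRanges::width(IRanges::pintersect(
    q[S4Vectors::queryHits(hits)], ir[S4Vectors::subjectHits(hits)]))
  out <- numeric(length(q))
  if (length(hits)) {
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Feature precedence used for gene annotation
#' @noRd
feature_precedence <- c("TSS", "promoter", "TTS", "utr5", "utr3", "exon",
                        "intron", "upstream", "downstream", "intergenic")

#' @noRd
annotate_intervals <- function(chrom, start, end, bundle, region_rule) {
  n <- length(start)
  w <- bundle$windows
  gw <- gene_windows(bundle)
  feature <- rep("intergenic", n)
  genes <- vector("list", n)
  bands <- cgi_bands(bundle)
  cgi_context <- rep("open_sea", n)
  rep_flag <- rep(FALSE, n)
  rep_family <- rep(NA_character_, n)
  known <- unique(c(bundle$genes$chrom, bundle$cgi$chrom,
                    bundle$repeats$chrom))
  unknown <- !(chrom %in% known)
  if (any(unknown))
    warning(sum(unknown), " interval(s) on chromosomes absent from the ",
            "annotation bundle: labelled intergenic / open sea")
  for (ch in intersect(unique(chrom), known)) {
    sel <- which(chrom == ch)
    q <- IRanges::IRanges(start[sel], end[sel])
    # gene features by precedence; any-overlap of the interval with windows
    if (!is.null(gw)) {
      gwc <- gw[gw$chrom == ch, ]
      if (nrow(gwc)) {
        ir_w <- IRanges::IRanges(gwc$start, gwc$end)
        hits <- IRanges::findOverlaps(q, ir_w)
        if (length(hits)) {
          qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
          typ <- gwc$type[sh]
          typ[typ == "gene_body"] <- "intron"  # body minus higher-precedence
          rank <- match(typ, feature_precedence)
          best <- tapply(rank, qh, min)
          feature[sel[as.integer(names(best))]] <-
            feature_precedence[as.integer(best)]
        }
        # gene assignment: any gene whose body +/- 10 kb contains the site
        gb <- bundle$genes[bundle$genes$chrom == ch, ]
        ir_g <- IRanges::IRanges(pmax(1L, gb$start - w$upstream),
                                 gb$end + w$downstream)
        gh <- IRanges::findOverlaps(q, ir_g)
        if (length(gh)) {
          qh <- S4Vectors::queryHits(gh)
          gl <- split(gb$gene_id[S4Vectors::subjectHits(gh)], qh)
          for (nm in names(gl)) genes[[sel[as.integer(nm)]]] <-
            sort(unique(gl[[nm]]))
        }
      }
    }
    # CpG-island context: precedence CGI > shore > shelf
    if (!is.null(bands[[ch]])) {
      b <- bands[[ch]]
      len <- end[sel] - start[sel] + 1
      for (ctx in c("shelf", "shore", "cgi")) {
        ow <- overlap_width(start[sel], end[sel], b[[ctx]])
        hit <- if (region_rule) ow / len >= w$region_overlap else ow > 0
        cgi_context[sel[hit]] <- if (ctx == "cgi") "CGI" else ctx
      }
    }
    # repeats: any overlap counts, whatever its extent
    rp <- bundle$repeats[bundle$repeats$chrom == ch, ]
    if (nrow(rp)) {
      ir_r <- IRanges::IRanges(rp$start, rp$end)
      rh <- IRanges::findOverlaps(q, ir_r)
      if (length(rh)) {
        qh <- S4Vectors::queryHits(rh)
        rep_flag[sel[unique(qh)]] <- TRUE
        fam <- split(rp$family[S4Vectors::subjectHits(rh)], qh)
        for (nm in names(fam)) rep_family[sel[as.integer(nm)]] <-
          paste(sort(unique(fam[[nm]])), collapse = ",")
      }
    }
  }
  data.frame(gene_feature = feature, cgi_context = cgi_context,
             repeat_overlap = rep_flag, repeat_family = rep_family,
             genes = vapply(genes, function(g)
               if (is.null(g)) NA_character_ else paste(g, collapse = ","),
               character(1)),
             stringsAsFactors = FALSE)
}

#' Annotate CpG sites against gene features, CpG-island context and repeats
#'
#' Each site receives exactly one gene-feature label by the precedence
#' TSS > promoter > TTS > 5'UTR > 3'UTR > exon > intron > upstream >
#' downstream > intergenic (windows: TSS +/-100 bp, promoter -2000..-100 bp
#' of the TSS on the gene's strand, TTS +/-100 bp, upstream/downstream
#' 10 kb), exactly one CpG-island context from CGI > shore > shelf >
#' open sea by point membership (shore: up to 2 kb from a CGI; shelf: the
#' next 2 kb), a repeat flag set by any overlap whatever its extent, and the
#' list of all genes whose body +/- 10 kb contains the site.
#'
#' @param sites data.frame `chrom, pos`.
#' @param bundle an `AnnotationBundle` (see [simulate_annotation()]).
#' @return data.frame `gene_feature, cgi_context, repeat_overlap,
#'   repeat_family, genes` aligned with `sites`.
#' @export
annotate_site <- function(sites, bundle) {
  stopifnot(inherits(bundle, "AnnotationBundle"),
            all(c("chrom", "pos") %in% names(sites)))
  annotate_intervals(sites$chrom, sites$pos, sites$pos, bundle,
                     region_rule = FALSE)
}

#' Annotate regions (e.g. DMRs)
#'
#' Gene features use the same precedence as [annotate_site()] with
#' any-overlap of the region against each window. The CpG-island context is
#' assigned only when at least 75% of the region's length overlaps the CGI
#' (respectively shore, shelf) band; repeats by any overlap.
#'
#' @param regions data.frame `chrom, start, end` (1-based inclusive).
#' @param bundle an `AnnotationBundle`.
#' @return data.frame as [annotate_site()], aligned with `regions`.
#' @export
annotate_region <- function(regions, bundle) {
  stopifnot(inherits(bundle, "AnnotationBundle"),
            all(c("chrom", "start", "end") %in% names(regions)))
  annotate_intervals(regions$chrom, regions$start, regions$end, bundle,
                     region_rule = TRUE)
}

#' Category enrichment of DMC annotations against the background
#'
#' For every category of an annotation column: the proportion among DMCs,
#' the proportion among background sites, their ratio (fold change) and a
#' two-sided Fisher exact p-value from the 2x2 count table.
#'
#' @param dmc_ann annotation data.frame (or factor/character vector) for the
#'   DMCs.
#' @param bg_ann annotation of the background universe.
#' @param column column name to tabulate when data.frames are given.
#' @return data.frame `category, n_dmc, n_bg, prop_dmc, prop_bg, fold, p`;
#'   categories absent from the background have `fold = NA`.
#' @export
enrichment <- function(dmc_ann, bg_ann, column = "gene_feature") {
  pick <- function(x) if (is.data.frame(x)) x[[column]] else as.character(x)
  d <- pick(dmc_ann); b <- pick(bg_ann)
  if (!length(b)) stop("background annotations are empty")
  cats <- sort(unique(c(d, b)))
  nd <- length(d); nb <- length(b)
  res <- lapply(cats, function(ct) {
    kd <- sum(d == ct); kb <- sum(b == ct)
    fold <- if (kb == 0) NA_real_ else (kd / nd) / (kb / nb)
    p <- stats::fisher.test(base::matrix(c(kd, nd - kd, kb, nb - kb), 2))$p.value
    data.frame(category = ct, n_dmc = kd, n_bg = kb,
               prop_dmc = kd / nd, prop_bg = kb / nb, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
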