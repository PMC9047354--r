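#' Simulation parameters for a synthetic RRBS fertility cohort
#'
#' Defaults emulate the study conditions of a two-class bull cohort profiled
#' by RRBS: 57 fertile and 43 subfertile samples, ~23x mean per-CpG coverage,
#' a bimodal methylation landscape in which about half the CpGs sit below 20%
#' methylation (low mode concentrated in CpG islands), logit-scale
#' inter-individual variability, a small fraction of planted differentially
#' methylated cytosines with at least 10-percentage-point effects (mostly
#' hypermethylated in the subfertile class, a minority hypomethylated and
#' spatially clustered), genotype-confounded CpGs and missing coverage.
#'
#' @param n_fertile,n_subfertile class sizes (samples).
#' @param n_cpg number of CpG sites to simulate.
#' @param frac_dmc fraction of sites planted as DMCs.
#' @param effect_delta planted methylation difference, percentage points, on
#'   the probability scale (converted per site to a logit offset).
#' @param frac_hypo_dmc fraction of planted DMCs hypomethylated in the
#'   subfertile class; these are placed in spatial clusters.
#' @param hypo_cluster_size,hypo_cluster_width sites per hypo cluster and the
#'   maximal genomic span (bp) of a cluster.
#' @param indiv_sd standard deviation of the per-sample logit-scale random
#'   effect (inter-individual variability).
#' @param cov_mean,cov_dispersion negative-binomial coverage mean and
#'   dispersion (variance = mu + dispersion * mu^2; 0 gives Poisson).
#' @param missing_rate probability a cell's coverage is zeroed (not covered).
#' @param frac_variant_sites fraction of sites whose readout is driven by a
#'   segregating genotype rather than methylation.
#' @param variant_class_imbalance shift in variant allele frequency between
#'   classes (0 = balanced genotypes; positive values confound genotype with
#'   class and inflate apparent between-class differences).
#' @param baseline_low,baseline_high,baseline_low_weight two-mode baseline
#'   methylation mixture (fractions): low-mode mean, high-mode mean and the
#'   overall weight of the low mode.
#' @param seed integer seed recorded in the object.
#' @return a list of class `SimParams`.
#' @export
sim_params <- function(n_fertile = 57L, n_subfertile = 43L, n_cpg = 5000L,
                       frac_dmc = 0.005, effect_delta = 15,
                       frac_hypo_dmc = 0.21, hypo_cluster_size = 5L,
                       hypo_cluster_width = 2000L, indiv_sd = 0.5,
                       cov_mean = 23, cov_dispersion = 0.15,
                       missing_rate = 0.05, frac_variant_sites = 0.02,
                       variant_class_imbalance = 0,
                       baseline_low = 0.05, baseline_high = 0.85,
                       baseline_low_weight = 0.5, seed = 1L) {
  n_fertile <- check_count(n_fertile, "n_fertile", 1L)
  n_subfertile <- check_count(n_subfertile, "n_subfertile", 1L)
  if (n_fertile + n_subfertile < 2L) stop("need at least 2 samples in total")
  n_cpg <- check_count(n_cpg, "n_cpg", 1L)
  for (f in c("frac_dmc", "frac_hypo_dmc", "missing_rate",
              "frac_variant_sites", "baseline_low", "baseline_high",
              "baseline_low_weight"))
    check_fraction(get(f), f)
  if (cov_mean <= 0) stop("'cov_mean' must be > 0")
  if (cov_dispersion < 0) stop("'cov_dispersion' must be >= 0")
  if (effect_delta < 0) stop("'effect_delta' must be >= 0")
  if (indiv_sd < 0) stop("'indiv_sd' must be >= 0")
  structure(list(n_fertile = n_fertile, n_subfertile = n_subfertile,
                 n_cpg = n_cpg, frac_dmc = frac_dmc,
                 effect_delta = effect_delta, frac_hypo_dmc = frac_hypo_dmc,
                 hypo_cluster_size = as.integer(hypo_cluster_size),
                 hypo_cluster_width = as.integer(hypo_cluster_width),
                 indiv_sd = indiv_sd, cov_mean = cov_mean,
                 cov_dispersion = cov_dispersion,
                 missing_rate = missing_rate,
                 frac_variant_sites = frac_variant_sites,
                 variant_class_imbalance = variant_class_imbalance,
                 baseline_low = baseline_low, baseline_high = baseline_high,
                 baseline_low_weight = baseline_low_weight,
                 seed = as.integer(seed)),
            class = "SimParams")
}

#' Simulate a toy annotated genome
#'
#' Places `n_genes` non-overlapping gene bodies (with exons, UTR spans and
#' strand), CpG-island intervals (one near each TSS plus intergenic islands)
#' and repeat intervals with family labels, all on a single chromosome within
#' `[1, genome_length]`. Deterministic for a fixed seed.
#'
#' @param n_genes number of genes (0 allowed: islands and repeats only).
#' @param genome_length chromosome length in bases.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return a list of class `AnnotationBundle` with elements `genes`, `exons`,
#'   `utr5`, `utr3`, `cgi`, `repeats`, `windows`, `chrom`, `genome_length`.
#' @export
simulate_annotation <- function(n_genes, genome_length, seed = 1L,
                                chrom = "chr1") {
  n_genes <- check_count(n_genes, "n_genes", 0L)
  set.seed(derive_seed(seed, "annotation"))
  gene_len <- if (n_genes > 0) sample(3000:12000, n_genes, replace = TRUE)
              else integer()
  # require room for gene bodies plus flanking windows
  if (n_genes > 0 && sum(gene_len + 24000) > genome_length)
    stop("placement error: genome_length too small to place ", n_genes,
         " non-overlapping genes with flanking windows")
  genes <- exons <- utr5 <- utr3 <- NULL
  if (n_genes > 0) {
    starts <- integer(n_genes)
    occupied <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (try in 1:200) {
        s <- sample.int(genome_length - gene_len[i] - 12000L, 1L) + 12000L
        e <- s + gene_len[i] - 1L
        if (nrow(occupied) == 0 ||
            all(e + 12000 < occupied[, 1] | s - 12000 > occupied[, 2])) {
          occupied <- rbind(occupied, c(s, e)); starts[i] <- s
          placed <- TRUE; break
        }
      }
      if (!placed)
        stop("placement error: could not place gene ", i,
             " without overlap after bounded retries")
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    ends <- starts + gene_len - 1L
    genes <- data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                        chrom = chrom, start = starts, end = ends,
                        strand = strand,
                        tss = ifelse(strand == "+", starts, ends),
                        tts = ifelse(strand == "+", ends, starts),
                        stringsAsFactors = FALSE)
    ex_list <- lapply(seq_len(n_genes), function(i) {
      k <- sample(2:5, 1)
      # split the gene span into 2k+1 blocks, exons at odd blocks
      cuts <- sort(sample((starts[i] + 1):(ends[i] - 1), 2 * k - 1))
      bnd <- c(starts[i], cuts, ends[i])
      es <- bnd[seq(1, 2 * k, by = 2)]
      ee <- bnd[seq(2, 2 * k + 1, by = 2)]
      data.frame(gene_id = genes$gene_id[i], chrom = chrom,
                 start = as.integer(es), end = as.integer(ee),
                 stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, ex_list)
    # UTRs: 5' part of the first exon and 3' part of the last, gene-strand aware
    utr_of <- function(i, side) {
      ex <- ex_list[[i]]
      first <- if (genes$strand[i] == "+") 1L else nrow(ex)
      last <- if (genes$strand[i] == "+") nrow(ex) else 1L
      row <- if (side == 5) ex[first, ] else ex[last, ]
      len <- max(1L, as.integer((row$end - row$start + 1) * 0.3))
      at_start <- (side == 5) == (genes$strand[i] == "+")
      if (at_start) data.frame(gene_id = row$gene_id, chrom = chrom,
                               start = row$start,
                               end = row$start + len - 1L)
      else data.frame(gene_id = row$gene_id, chrom = chrom,
                      start = row$end - len + 1L, end = row$end)
    }
    utr5 <- do.call(rbind, lapply(seq_len(n_genes), utr_of, side = 5))
    utr3 <- do.call(rbind, lapply(seq_len(n_genes), utr_of, side = 3))
  }
  # CpG islands: one spanning each TSS, plus intergenic ones
  cgi <- NULL
  if (n_genes > 0) {
    half <- sample(300:800, n_genes, replace = TRUE)
    cgi <- data.frame(chrom = chrom,
                      start = pmax(1L, as.integer(genes$tss - half)),
                      end = pmin(genome_length,
                                 as.integer(genes$tss + half)))
  }
  n_extra <- max(3L, ceiling(n_genes / 2))
  ext_start <- sort(sample.int(max(1L, genome_length - 2000L), n_extra))
  cgi <- rbind(cgi, data.frame(chrom = chrom, start = ext_start,
                               end = ext_start + sample(400:1500, n_extra,
                                                        replace = TRUE)))
  cgi <- cgi[order(cgi$start), ]
  cgi$end <- pmin(cgi$end, genome_length)
  rownames(cgi) <- NULL
  # repeats
  n_rep <- max(5L, n_genes * 2L)
  rep_start <- sort(sample.int(max(1L, genome_length - 6000L), n_rep))
  repeats <- data.frame(chrom = chrom, start = rep_start,
                        end = pmin(genome_length,
                                   rep_start + sample(200:6000, n_rep,
                                                      replace = TRUE)),
                        family = sample(c("L1", "BovB", "LTR", "SINE",
                                          "TandemRepeat"),
                                        n_rep, replace = TRUE),
                        stringsAsFactors = FALSE)
  empty_iv <- data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer())
  structure(list(
    genes = genes %||% data.frame(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), tss = integer(),
                                  tts = integer()),
    exons = exons %||% empty_iv, utr5 = utr5 %||% empty_iv,
    utr3 = utr3 %||% empty_iv, cgi = cgi, repeats = repeats,
    windows = default_windows(), chrom = chrom,
    genome_length = as.integer(genome_length)), class = "AnnotationBundle")
}

#' Annotation window constants
#'
#' TSS +/-100 bp, promoter -2000..-100 bp of the TSS, TTS +/-100 bp,
#' upstream/downstream 10 kb, CpG-island shore 2 kb, shelf a further 2 kb,
#' and the 75% minimum overlap fraction used when assigning regions to a
#' CpG-island context.
#'
#' @return named list of window constants (bases, and one fraction).
#' @export
default_windows <- function() {
  list(tss = 100L, promoter_upstream = 2000L, promoter_downstream = 100L,
       tts = 100L, upstream = 10000L, downstream = 10000L,
       shore = 2000L, shelf = 2000L, region_overlap = 0.75)
}

#' Simulate per-CpG bisulfite counts with known ground truth
#'
#' For sample `s` and site `j`, total reads are negative-binomial with mean
#' `cov_mean`, zeroed with probability `missing_rate`; methylated reads are
#' binomial with success probability `p_sj` where
#' `logit(p_sj) = logit(baseline_j) + a_s + delta_j * I(s subfertile)`.
#' `a_s ~ N(0, indiv_sd^2)` is the per-sample effect; `delta_j` is the logit
#' offset that moves the baseline by `effect_delta` percentage points (sign
#' per `frac_hypo_dmc`, hypo sites spatially clustered) at planted DMCs and 0
#' elsewhere. Baselines are drawn from the two-mode mixture with the low mode
#' concentrated inside CpG islands. Genotype-confounded sites ignore the
#' logit model: each sample carries a dosage 0/1/2 and reads out ~100/50/0%
#' methylation, with allele frequencies optionally class-imbalanced.
#'
#' @param params a [sim_params()] object.
#' @param annotation an `AnnotationBundle` from [simulate_annotation()];
#'   supplies CpG positions (dense inside islands, sparse elsewhere).
#' @param seed integer seed (defaults to `params$seed`).
#' @return list with `matrix` (a [meth_count_matrix()] carrying a
#'   `sample_sheet` attribute) and `truth` (the per-site truth table:
#'   `site_id, chrom, pos, is_planted_dmc, planted_direction, hypo_cluster,
#'   is_variant_site, true_baseline`).
#' @export
simulate_methylation <- function(params, annotation, seed = params$seed) {
  stopifnot(inherits(params, "SimParams"),
            inherits(annotation, "AnnotationBundle"))
  set.seed(derive_seed(seed, "methylation"))
  p <- params
  G <- annotation$genome_length
  # CpG positions: half the sites packed into islands, half elsewhere
  cgi <- annotation$cgi
  island_bp <- unique(unlist(mapply(seq, cgi$start, cgi$end,
                                    SIMPLIFY = FALSE)))
  n_isl <- min(length(island_bp), ceiling(p$n_cpg / 2))
  pos_isl <- sort(sample(island_bp, n_isl))
  outside <- setdiff(seq_len(G), island_bp)
  pos_out <- sort(sample(outside, p$n_cpg - n_isl))
  pos <- sort(unique(c(pos_isl, pos_out)))
  while (length(pos) < p$n_cpg) {  # resolve rare collisions
    extra <- sample(setdiff(seq_len(G), pos), p$n_cpg - length(pos))
    pos <- sort(unique(c(pos, extra)))
  }
  n <- length(pos)
  in_island <- pos %in% island_bp
  f_isl <- mean(in_island)
  # baseline mixture: low mode concentrated in islands, overall low-mode
  # weight equal to baseline_low_weight
  p_low_isl <- if (f_isl > 0) min(1, 0.9) else 0
  p_low_out <- if (f_isl < 1)
    min(1, max(0, (p$baseline_low_weight - p_low_isl * f_isl) / (1 - f_isl)))
  else 0
  is_low <- stats::rbinom(n, 1L, ifelse(in_island, p_low_isl, p_low_out)) == 1L
  rbeta_mean <- function(k, m, conc = 30) stats::rbeta(k, m * conc,
                                                       (1 - m) * conc)
  baseline <- numeric(n)
  baseline[is_low] <- rbeta_mean(sum(is_low), p$baseline_low)
  baseline[!is_low] <- rbeta_mean(sum(!is_low), p$baseline_high)
  baseline <- pmin(pmax(baseline, 0.01), 0.99)

  # planted DMCs: hyper sites scattered, hypo sites in spatial clusters.
  # Effects are planted where the full shift stays inside (0.01, 0.99), so
  # that planted truth really carries the stated effect size; only when too
  # few such sites exist does planting fall back to clipping.
  n_dmc <- round(p$frac_dmc * n)
  n_hypo <- round(p$frac_hypo_dmc * n_dmc)
  d <- p$effect_delta / 100
  feas_hypo <- baseline - d >= 0.01
  feas_hyper <- baseline + d <= 0.99
  is_dmc <- rep(FALSE, n); direction <- rep(NA_character_, n)
  if (n_hypo > 0) {
    pool <- if (sum(feas_hypo) >= n_hypo) which(feas_hypo) else seq_len(n)
    n_clust <- max(1L, ceiling(n_hypo / p$hypo_cluster_size))
    anchors <- sample(pool, min(n_clust * 3L, length(pool)))
    hypo_idx <- integer(); hypo_cl <- integer(); cl <- 0L
    for (a in anchors) {
      near <- intersect(pool, which(abs(pos - pos[a]) <=
                                      p$hypo_cluster_width / 2))
      near <- setdiff(near[!is_dmc[near]], hypo_idx)
      take <- utils::head(near[order(abs(pos[near] - pos[a]))],
                          p$hypo_cluster_size)
      if (!length(take)) next
      cl <- cl + 1L
      hypo_idx <- c(hypo_idx, take)
      hypo_cl <- c(hypo_cl, rep(cl, length(take)))
      if (length(hypo_idx) >= n_hypo) break
    }
    keep_h <- seq_len(min(length(hypo_idx), n_hypo))
    hypo_idx <- hypo_idx[keep_h]; hypo_cl <- hypo_cl[keep_h]
    is_dmc[hypo_idx] <- TRUE; direction[hypo_idx] <- "hypo"
    hypo_cluster <- rep(NA_integer_, n)
    hypo_cluster[hypo_idx] <- hypo_cl
  } else hypo_cluster <- rep(NA_integer_, n)
  n_hyper <- n_dmc - sum(is_dmc)
  if (n_hyper > 0) {
    pool <- which(!is_dmc & feas_hyper)
    if (length(pool) < n_hyper) pool <- which(!is_dmc)
    hyper_idx <- sample(pool, n_hyper)
    is_dmc[hyper_idx] <- TRUE; direction[hyper_idx] <- "hyper"
  }
  # variant sites, disjoint from planted DMCs
  n_var <- round(p$frac_variant_sites * n)
  is_var <- rep(FALSE, n)
  if (n_var > 0) is_var[sample(which(!is_dmc), min(n_var, sum(!is_dmc)))] <- TRUE

  # logit offsets realizing effect_delta percentage points at planted sites
  sgn <- ifelse(direction == "hyper", 1, -1)
  target <- baseline + ifelse(is_dmc, sgn * p$effect_delta / 100, 0)
  clipped <- is_dmc & (target < 0.01 | target > 0.99)
  if (any(clipped, na.rm = TRUE))
    warning(sum(clipped, na.rm = TRUE),
            " planted effect(s) clipped to keep probabilities in [0.01, 0.99]")
  target <- pmin(pmax(target, 0.01), 0.99)
  delta_logit <- ifelse(is_dmc, stats::qlogis(target) -
                                 stats::qlogis(baseline), 0)

  n_samp <- p$n_fertile + p$n_subfertile
  classes <- c(rep("fertile", p$n_fertile), rep("subfertile", p$n_subfertile))
  ids <- sprintf("B%03d", seq_len(n_samp))
  a_s <- stats::rnorm(n_samp, 0, p$indiv_sd)

  # per-cell success probabilities
  eta <- outer(stats::qlogis(baseline), a_s, "+") +
    outer(delta_logit, as.numeric(classes == "subfertile"))
  prob <- stats::plogis(eta)
  # genotype-driven sites override the logit model
  if (any(is_var)) {
    af <- stats::runif(sum(is_var), 0.1, 0.9)
    af_cls <- cbind(fertile = af,
                    subfertile = pmin(pmax(af + p$variant_class_imbalance,
                                           0.02), 0.98))
    vi <- which(is_var)
    for (k in seq_along(vi)) {
      dosage <- stats::rbinom(n_samp, 2L, af_cls[k, classes])
      prob[vi[k], ] <- pmin(pmax(1 - dosage / 2, 0.01), 0.99)
    }
  }
  total <- if (p$cov_dispersion > 0)
    matrix(stats::rnbinom(n * n_samp, mu = p$cov_mean,
                          size = 1 / p$cov_dispersion), n, n_samp)
  else matrix(stats::rpois(n * n_samp, p$cov_mean), n, n_samp)
  if (p$missing_rate > 0)
    total[matrix(stats::runif(n * n_samp) < p$missing_rate, n, n_samp)] <- 0L
  meth <- matrix(stats::rbinom(n * n_samp, total, prob), n, n_samp)
  meth[total == 0L] <- NA_integer_
  total[total == 0L] <- NA_integer_

  sites <- data.frame(chrom = annotation$chrom, pos = as.integer(pos),
                      stringsAsFactors = FALSE)
  mat <- meth_count_matrix(sites, meth, total, ids)
  sheet <- data.frame(
    sample_id = ids, fertility = classes,
    center = sample(1:2, n_samp, replace = TRUE, prob = c(0.56, 0.44)),
    batch = sprintf("batch%d", (seq_len(n_samp) - 1L) %% 7L + 1L),
    age_months = sample(17:19, n_samp, replace = TRUE),
    n_ejaculates = sample(2:5, n_samp, replace = TRUE),
    stringsAsFactors = FALSE)
  attr(mat, "sample_sheet") <- sheet
  truth <- data.frame(site_id = paste0(annotation$chrom, ":", pos),
                      chrom = annotation$chrom, pos = as.integer(pos),
                      is_planted_dmc = is_dmc, planted_direction = direction,
                      hypo_cluster = hypo_cluster,
                      is_variant_site = is_var, true_baseline = baseline,
                      stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth)
}

#' Default fixed-effect structure for simulated AI records
#'
#' Levels and outcome-scale effect SDs for the confounders recorded with
#' each insemination: herd-year, month-year, parity, calving-to-insemination
#' interval class, weekday, AI technician and semen category.
#'
#' @return named list of `list(levels, sd)` entries.
#' @export
default_fixed_effects <- function() {
  list(herd_year = list(levels = 30L, sd = 0.03),
       month_year = list(levels = 24L, sd = 0.02),
       parity = list(levels = 4L, sd = 0.02),
       interval_class = list(levels = 4L, sd = 0.01),
       weekday = list(levels = 7L, sd = 0.005),
       technician = list(levels = 15L, sd = 0.02),
       semen_category = list(levels = 2L, sd = 0.01))
}

#' Simulate binary artificial-insemination outcome records
#'
#' Each AI record carries a 0/1 non-return score drawn with success
#' probability `base_rate + bull effect + fixed effects` (clipped to (0,1)),
#' the outcome model being linear on the probability scale. Fixed-effect
#' levels are assigned uniformly at random per record. True bull effects are
#' returned for recovery checks.
#'
#' @param n_bulls number of bulls (>= 2).
#' @param ai_per_bull AI records per bull (>= 1).
#' @param bull_sd outcome-scale SD of true bull effects.
#' @param fixed_effect_spec named list of `list(levels, sd)`; see
#'   [default_fixed_effects()]. `NULL` disables fixed effects.
#' @param base_rate overall success probability in (0, 1).
#' @param seed integer seed.
#' @return list with `records` (data.frame: `bull_id, cow_id, score` plus one
#'   factor column per fixed effect) and `bull_effects` (named numeric).
#' @export
simulate_ai_records <- function(n_bulls, ai_per_bull, bull_sd = 0.03,
                                fixed_effect_spec = default_fixed_effects(),
                                base_rate = 0.68, seed = 1L) {
  n_bulls <- check_count(n_bulls, "n_bulls", 2L)
  if (ai_per_bull < 1) stop("'ai_per_bull' must be >= 1 (no records otherwise)")
  ai_per_bull <- check_count(ai_per_bull, "ai_per_bull", 1L)
  if (base_rate <= 0 || base_rate >= 1) stop("'base_rate' must be in (0, 1)")
  set.seed(derive_seed(seed, "ai_records"))
  bulls <- sprintf("BULL%03d", seq_len(n_bulls))
  u <- stats::rnorm(n_bulls, 0, bull_sd); names(u) <- bulls
  n_rec <- n_bulls * ai_per_bull
  rec <- data.frame(bull_id = rep(bulls, each = ai_per_bull),
                    cow_id = sprintf("COW%06d", sample.int(n_rec)),
                    stringsAsFactors = FALSE)
  eta <- base_rate + u[rec$bull_id]
  if (!is.null(fixed_effect_spec)) {
    for (fx in names(fixed_effect_spec)) {
      sp <- fixed_effect_spec[[fx]]
      eff <- stats::rnorm(sp$levels, 0, sp$sd)
      lev <- sample.int(sp$levels, n_rec, replace = TRUE)
      rec[[fx]] <- factor(sprintf("%s_%02d", fx, lev))
      eta <- eta + eff[lev]
    }
  }
  eta <- pmin(pmax(eta, 0.001), 0.999)
  rec$score <- stats::rbinom(n_rec, 1L, eta)
  rownames(rec) <- NULL
  list(records = rec, bull_effects = u)
}

#' Write a simulated cohort to disk in the pipeline's external formats
#'
#' Emits one Bismark coverage file per sample, a sample-sheet CSV, the truth
#' table as TSV, annotation intervals as BED and the variant mask as a
#' chrom/pos TSV.
#'
#' @param sim result of [simulate_methylation()].
#' @param annotation the `AnnotationBundle` used for the simulation.
#' @param outdir output directory (created if absent).
#' @return invisibly, a character vector of the files written.
#' @export
write_simulated_cohort <- function(sim, annotation, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mat <- sim$matrix
  files <- character()
  for (j in seq_along(mat$samples)) {
    cov <- !is.na(mat$total[, j])
    tab <- data.frame(chrom = mat$sites$chrom[cov], pos = mat$sites$pos[cov],
                      meth = mat$meth[cov, j], total = mat$total[cov, j])
    f <- file.path(outdir, paste0(mat$samples[j], ".cov"))
    write_bismark_cov(tab, f); files <- c(files, f)
  }
  sheet <- attr(mat, "sample_sheet")
  f <- file.path(outdir, "sample_sheet.csv")
  utils::write.csv(sheet, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(outdir, "truth_table.tsv")
  utils::write.table(sim$truth, f, sep = "\t", row.names = FALSE,
                     quote = FALSE); files <- c(files, f)
  f <- file.path(outdir, "variant_mask.tsv")
  vt <- sim$truth[sim$truth$is_variant_site, ]
  # mask both the C and the G of each flagged CpG
  mask <- data.frame(chrom = rep(vt$chrom, 2),
                     pos = c(vt$pos, vt$pos + 1L))
  utils::write.table(mask[order(mask$pos), ], f, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  files <- c(files, f)
  for (nm in c("cgi", "repeats")) {
    f <- file.path(outdir, paste0(nm, ".bed"))
    write_bed(annotation[[nm]], f); files <- c(files, f)
  }
  if (nrow(annotation$genes)) {
    f <- file.path(outdir, "genes.bed")
    g <- annotation$genes
    write_bed(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                         name = g$gene_id, score = 0), f)
    files <- c(files, f)
  }
  invisible(files)
}
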