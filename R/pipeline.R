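#' Default pipeline configuration
#'
#' Thresholds default to the study settings: CpG10 coverage >= 10 reads,
#' group presence "auto" (half the smallest class, rounded up), pooled-test
#' q < 0.01 with a 10-point difference, DMRs of >= 3 DMCs with gaps <= 100
#' bp, 500 trees, 50 resampling iterations, 2/3 training fraction, and the
#' annotation windows of [default_windows()].
#'
#' @param ... overrides for any configuration key.
#' @return named list (class `RunConfig`).
#' @export
default_config <- function(...) {
  cfg <- list(
    stages = c("simulate", "filter", "dmc", "dmr", "annotate", "classify"),
    seed = 1L,
    sim = list(n_fertile = 20L, n_subfertile = 20L, n_cpg = 3000L,
               frac_dmc = 0.02, effect_delta = 25, indiv_sd = 0.2,
               n_genes = 8L, genome_length = 1000000L),
    min_reads = 10L, min_per_group = "auto",
    test = "pooled", q_threshold = NULL, diff_threshold = 10,
    dmr_min_dmcs = 3L, dmr_max_gap = 100L,
    feature_policy = "complete_only",
    n_trees = 500L, iterations = 50L, train_frac = 2 / 3)
  over <- list(...)
  for (nm in names(over)) {
    if (nm == "sim") cfg$sim[names(over$sim)] <- over$sim
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Keys absent from the file keep their [default_config()] values; the
#' resolved configuration is serialized verbatim into the run manifest.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_config, y)
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order — simulate, filter, dmc,
#' dmr, annotate, classify — writing every output file under `outdir` and a
#' `manifest.json` listing the resolved configuration, the thresholds
#' actually used, and the MD5 hash of every output. A second run with an
#' identical configuration reproduces identical hashes. A stage failure
#' halts the run, renames `outdir` contents under a `failed/` marker and
#' rethrows with the failing stage named.
#'
#' @param config a `RunConfig` from [default_config()] or [read_config()].
#' @param outdir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), thresholds = list(),
                   outputs = list())
  state <- new.env(parent = emptyenv())
  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      marker <- file.path(outdir, "failed")
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 marker)
      stop(sprintf("pipeline halted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    invisible(ok)
  }

  stage("simulate", function() {
    sc <- config$sim
    ann <- simulate_annotation(sc$n_genes, sc$genome_length,
                               seed = derive_seed(config$seed, "pipeline_ann"))
    prm <- do.call(sim_params, c(
      sc[setdiff(names(sc), c("n_genes", "genome_length"))],
      list(seed = derive_seed(config$seed, "pipeline_sim"))))
    sim <- simulate_methylation(prm, ann)
    state$annotation <- ann
    state$sim <- sim
    state$files <- write_simulated_cohort(sim, ann,
                                          file.path(outdir, "simulated"))
  })

  stage("filter", function() {
    sheet <- attr(state$sim$matrix, "sample_sheet")
    truth <- state$sim$truth
    vt <- truth[truth$is_variant_site, ]
    mask <- data.frame(chrom = rep(vt$chrom, 2), pos = c(vt$pos, vt$pos + 1L))
    fl <- apply_site_filters(state$sim$matrix, sheet$fertility,
                             min_reads = config$min_reads,
                             min_per_group = config$min_per_group,
                             mask = mask)
    state$filtered <- fl
    manifest$thresholds <<- c(manifest$thresholds, fl$report$thresholds)
    jsonlite::write_json(unclass(fl$report),
                         file.path(outdir, "filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  stage("dmc", function() {
    sheet <- attr(state$sim$matrix, "sample_sheet")
    dmcs <- call_dmcs(state$filtered$matrix, sheet$fertility,
                      test = config$test, q_threshold = config$q_threshold,
                      diff_threshold = config$diff_threshold,
                      cpg10 = state$filtered$cpg10, keep_all = TRUE)
    state$dmc_all <- dmcs
    state$dmcs <- dmcs[dmcs$is_dmc, , drop = FALSE]
    manifest$thresholds$q_threshold <<- attr(dmcs, "q_threshold")
    manifest$thresholds$diff_threshold <<- attr(dmcs, "diff_threshold")
    write_dmc_table(state$dmcs, file.path(outdir, "dmcs.tsv"),
                    file.path(outdir, "dmcs.bed"))
  })

  stage("dmr", function() {
    dmrs <- call_dmrs(state$dmcs, config$dmr_min_dmcs, config$dmr_max_gap)
    state$dmrs <- dmrs
    if (nrow(dmrs)) {
      means <- dmr_sample_means(dmrs, state$filtered$matrix,
                                state$filtered$cpg10)
      utils::write.table(cbind(dmrs[c("chrom", "start", "end", "n_dmcs")],
                               round(means, 3)),
                         file.path(outdir, "dmr_sample_means.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_dmc_table(dmrs, file.path(outdir, "dmrs.tsv"),
                    if (nrow(dmrs)) file.path(outdir, "dmrs.bed"))
  })

  stage("annotate", function() {
    ann_dmc <- annotate_site(state$dmcs, state$annotation)
    state$dmc_annotation <- ann_dmc
    utils::write.table(cbind(state$dmcs, ann_dmc),
                       file.path(outdir, "dmcs_annotated.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (nrow(state$dmrs)) {
      ann_dmr <- annotate_region(state$dmrs, state$annotation)
      utils::write.table(cbind(state$dmrs, ann_dmr),
                         file.path(outdir, "dmrs_annotated.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    bg_ann <- annotate_site(state$filtered$matrix$sites, state$annotation)
    enr <- enrichment(ann_dmc, bg_ann, "gene_feature")
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  })

  stage("classify", function() {
    if (nrow(state$dmcs) < 2L) {
      writeLines("too few DMCs for classification",
                 file.path(outdir, "classify_skipped.txt"))
      return(invisible(NULL))
    }
    sheet <- attr(state$sim$matrix, "sample_sheet")
    feats <- prepare_features(state$filtered$matrix, state$dmcs,
                              policy = config$feature_policy,
                              cpg10 = state$filtered$cpg10,
                              seed = derive_seed(config$seed, "impute"))
    cv <- crossvalidate_resampled(feats, sheet$fertility,
                                  iterations = config$iterations,
                                  train_frac = config$train_frac,
                                  n_trees = config$n_trees,
                                  seed = derive_seed(config$seed, "classify"))
    rep1 <- cv$reports[[1]]
    jsonlite::write_json(list(mean = as.list(cv$mean), sd = as.list(cv$sd),
                              iterations = cv$iterations),
                         file.path(outdir, "model_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(rep1$roc, file.path(outdir, "roc_points.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(rep1$predictions,
                       file.path(outdir, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  })

  files <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                   file.path(outdir, "manifest.json"))
  manifest$outputs <- lapply(files, function(f)
    list(path = sub(paste0("^", outdir, "/?"), "", f),
         md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
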