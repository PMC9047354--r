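# Fixtures shared across test files; everything is built in code.

# A tiny count matrix from explicit meth/total matrices (NA = not covered).
tiny_matrix <- function(meth, total, chrom = "chr1",
                        pos = seq_len(nrow(as.matrix(meth))) * 100L,
                        samples = paste0("S", seq_len(ncol(as.matrix(meth))))) {
  meth_count_matrix(data.frame(chrom = chrom, pos = pos),
                    as.matrix(meth), as.matrix(total), samples)
}

# A small simulated cohort, reused where exact structure does not matter.
small_cohort <- function(n_per_class = 10L, n_cpg = 800L, seed = 42L, ...) {
  ann <- simulate_annotation(3, 2e5, seed = seed)
  p <- sim_params(n_fertile = n_per_class, n_subfertile = n_per_class,
                  n_cpg = n_cpg, seed = seed, ...)
  sim <- simulate_methylation(p, ann)
  sim$annotation <- ann
  sim$sheet <- attr(sim$matrix, "sample_sheet")
  sim
}

# A deterministic annotation bundle with hand-placed features for window
# boundary checks: one plus-strand and one minus-strand gene, one CpG island
# and one repeat on a dedicated chromosome layout.
fixed_bundle <- function() {
  genes <- data.frame(
    gene_id = c("GP", "GM"), chrom = "chrT",
    start = c(20000L, 60000L), end = c(30000L, 70000L),
    strand = c("+", "-"),
    tss = c(20000L, 70000L), tts = c(30000L, 60000L),
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("GP", "GP", "GM"), chrom = "chrT",
                      start = c(20000L, 25000L, 60000L),
                      end = c(21000L, 26000L, 70000L))
  utr5 <- data.frame(gene_id = c("GP", "GM"), chrom = "chrT",
                     start = c(20000L, 69500L), end = c(20300L, 70000L))
  utr3 <- data.frame(gene_id = c("GP", "GM"), chrom = "chrT",
                     start = c(25800L, 60000L), end = c(26000L, 60400L))
  cgi <- data.frame(chrom = "chrT", start = 40000L, end = 41000L)
  repeats <- data.frame(chrom = "chrT", start = 50000L, end = 50500L,
                        family = "L1", stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
                 cgi = cgi, repeats = repeats, windows = default_windows(),
                 chrom = "chrT", genome_length = 100000L),
            class = "AnnotationBundle")
}

# Brute-force DMR caller: tests every maximal run by direct enumeration.
oracle_dmrs <- function(pos, min_dmcs = 3L, max_gap = 100L) {
  pos <- sort(pos)
  if (!length(pos)) return(list())
  runs <- list(); cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] <= max_gap) cur <- c(cur, p)
    else { runs[[length(runs) + 1]] <- cur; cur <- p }
  }
  runs[[length(runs) + 1]] <- cur
  Filter(function(r) length(r) >= min_dmcs, runs)
}

# Step-up BH oracle, straight from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n); out[o] <- q
  out
}
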