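test_that("genome simulation is deterministic, non-overlapping, and fails
           loudly when genes cannot fit", {
  cfg <- small_config()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  genes <- g1$genes
  expect_equal(nrow(genes), 30L)
  for (ch in unique(genes$chrom)) {
    sub <- genes[genes$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
  expect_true(nrow(simulate_genome(
    sim_config(seed = 1, n_genes = 0L))$genes) == 0L)
  expect_error(simulate_genome(
    sim_config(seed = 1, n_chroms = 1L, chrom_length = 1e5,
               n_genes = 50L)), "cannot fit")
})

test_that("background chain self-transition frequency matches the
           configured bias", {
  cfg <- sim_config(seed = 5, n_chroms = 1L, chrom_length = 2e6,
                    n_genes = 0L)
  truth <- simulate_state_paths(cfg, simulate_genome(cfg)$genes)
  path <- truth$state_path$PFF_like$chr1
  expect_equal(length(path), 10000L)
  self_freq <- mean(path[-1] == path[-length(path)])
  expect_lt(abs(self_freq - 0.96), 0.01)
})

test_that("planted runs: broad genes >= 20 bins, specific genes repressed
           in the other cell type, paths differ only at planted loci", {
  cfg <- small_config()
  genes <- simulate_genome(cfg)$genes
  truth <- simulate_state_paths(cfg, genes)
  planted <- truth$planted
  expect_true(all(planted$n_bins[planted$is_broad] >= 20))
  expect_true(all(planted$n_bins[!planted$is_broad] <= 10))
  # specific gene locus: TSS run in own type, state 7 in the other
  spec_a <- truth$specific_genes$PFF_like[1]
  row <- planted[planted$gene_id == spec_a, ]
  idx <- (row$bin_start:row$bin_end) + 1L
  own <- truth$state_path$PFF_like[[row$chrom]][idx]
  other <- truth$state_path$PTr2_like[[row$chrom]][idx]
  expect_true(all(own %in% c(1L, 2L)))
  expect_true(all(other == 7L))
  # outside planted windows the two cell types share the background path
  mask <- rep(TRUE, length(truth$state_path$PFF_like$chr1))
  for (i in seq_len(nrow(planted))) {
    mask[(planted$bin_start[i]:planted$bin_end[i]) + 1L] <- FALSE
  }
  expect_identical(truth$state_path$PFF_like$chr1[mask],
                   truth$state_path$PTr2_like$chr1[mask])
})

test_that("mark counts are Poisson with state-dependent rates", {
  cfg <- small_config()
  truth <- simulate_state_paths(cfg, simulate_genome(cfg)$genes)
  mk <- simulate_mark_counts(cfg, truth)
  path <- truth$state_path$PFF_like$chr1
  v1 <- mk$tracks$PFF_like$rep1$H3K27me3$values$chr1
  v2 <- mk$tracks$PFF_like$rep2$H3K27me3$values$chr1
  # replicates differ but share state-wise means
  expect_false(identical(v1, v2))
  for (s in c(7L, 9L)) {
    bins <- which(path == s)
    if (length(bins) < 200) next
    rate <- cfg$state_rates[s, "H3K27me3"]
    tol <- 3 * sqrt(rate / length(bins)) + 1e-9
    expect_lt(abs(mean(v1[bins]) - rate), max(tol, 0.05))
  }
  # zero-rate limiting case
  cfg0 <- small_config(state_rates = {
    r <- default_state_rates(); r[9, "H3K4me3"] <- 0; r
  })
  truth0 <- simulate_state_paths(cfg0, simulate_genome(cfg0)$genes)
  mk0 <- simulate_mark_counts(cfg0, truth0)
  bins0 <- which(truth0$state_path$PFF_like$chr1 == 9L)
  expect_true(all(mk0$tracks$PFF_like$rep1$H3K4me3$values$chr1[bins0] == 0))
})

test_that("expression: planted fold change is recovered and the generator
           is deterministic", {
  cfg <- sim_config(seed = 9, n_chroms = 2L, chrom_length = 1e6,
                    n_genes = 200L)
  genes <- simulate_genome(cfg)$genes
  truth <- simulate_state_paths(cfg, genes)
  e1 <- simulate_expression(cfg, truth, genes)
  e2 <- simulate_expression(cfg, truth, genes)
  expect_identical(e1$counts, e2$counts)
  spec <- truth$specific_genes$PFF_like
  own <- e1$samples$sample_id[e1$samples$cell_type == "PFF_like"]
  oth <- e1$samples$sample_id[e1$samples$cell_type == "PTr2_like"]
  ratio <- rowMeans(e1$counts[spec, own]) /
    pmax(rowMeans(e1$counts[spec, oth]), 0.5)
  expect_lt(abs(log2(median(ratio)) - cfg$specific_log2fc), 0.5)
  # the developmental term contains exactly the broad genes
  dev <- e1$terms$gene_id[e1$terms$term == "developmental_process"]
  expect_setequal(dev, unique(unlist(truth$broad_genes)))
})

test_that("negative-binomial counts approach Poisson as dispersion
           vanishes", {
  cfg <- sim_config(seed = 13, n_chroms = 1L, chrom_length = 1e6,
                    n_genes = 100L, n_reps_rna = 40L,
                    nb_dispersion = 1e-4)
  genes <- simulate_genome(cfg)$genes
  truth <- simulate_state_paths(cfg, genes)
  e <- simulate_expression(cfg, truth, genes)
  cols <- e$samples$sample_id[e$samples$cell_type == "PFF_like"]
  x <- e$counts[setdiff(genes$gene_id, unlist(truth$specific_genes)),
                cols]
  vmr <- apply(x, 1, stats::var) / pmax(rowMeans(x), 1e-9)
  expect_lt(abs(mean(vmr) - 1), 0.15)
})

test_that("a full study is byte-deterministic and its files parse with the
           package readers", {
  cfg <- small_config(seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(all(c("genes.gtf", "genes.bed", "spikein.tsv",
                    "expression_counts.tsv", "samples.tsv", "terms.tsv",
                    "truth.json") %in% f1))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  genes <- read_gtf_genes(file.path(d1, "genes.gtf"))
  expect_equal(nrow(genes), 30L)
  bed <- read_bed(file.path(d1, "genes.bed"))
  expect_equal(bed$start, genes$start)
  grid <- bin_grid(c(chr1 = cfg$chrom_length), cfg$bin_size)
  tr <- read_track(
    file.path(d1, "PFF_like_H3K4me3_rep1.bedGraph"), grid)
  expect_equal(length(tr$values$chr1), grid$n_bins[["chr1"]])
})
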