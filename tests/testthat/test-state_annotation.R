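test_that("TSS meta-profiles are flat for constant signal and oriented by
           strand", {
  grid <- bin_grid(c(chr1 = 40000), 200)
  genes <- structure(data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(10000, 26000), end = c(14000, 30000),
    strand = c("+", "-"), tss = c(10000, 29999), tes = c(13999, 26000),
    stringsAsFactors = FALSE), class = c("gene_models", "data.frame"))
  genes$exons <- I(list(NULL, NULL))
  const <- binned_track(grid, list(chr1 = rep(1, 200)))
  mp <- tss_metaprofile(const, genes, flank = 2000)
  expect_equal(length(mp$profile), 2 * 2000 / 200 + 1)
  expect_true(all(mp$profile == 1))
  # signal one bin downstream (genomic) of the minus-strand TSS appears
  # one bin upstream of center in its oriented row
  v <- rep(0, 200)
  v[bin_index(29999, grid) + 1 + 1] <- 5  # one bin right of TSS bin
  tr <- binned_track(grid, list(chr1 = v))
  mp2 <- tss_metaprofile(tr, genes, flank = 2000)
  center <- 2000 / 200 + 1
  expect_equal(unname(mp2$matrix["g2", center - 1]), 5)
  # flipping the strand (same TSS) mirrors the oriented row
  genes_flip <- genes
  genes_flip$strand <- c("-", "+")
  mp3 <- tss_metaprofile(tr, genes_flip, flank = 2000)
  expect_equal(unname(mp3$matrix["g2", center + 1]), 5)
})

test_that("edge genes are excluded from column means via NA padding", {
  grid <- bin_grid(c(chr1 = 4000), 200)
  genes <- structure(data.frame(
    gene_id = "g1", chrom = "chr1", start = 200, end = 1200,
    strand = "+", tss = 200, tes = 1199, stringsAsFactors = FALSE),
    class = c("gene_models", "data.frame"))
  genes$exons <- I(list(NULL))
  tr <- binned_track(grid, list(chr1 = rep(2, 20)))
  mp <- tss_metaprofile(tr, genes, flank = 1000)
  expect_true(anyNA(mp$matrix))
  expect_true(is.na(mp$profile[1]))   # no gene covers far upstream
  expect_equal(unname(mp$profile[6]), 2)  # center column covered
})

test_that("state-feature fold enrichment follows the coverage ratio
           definition", {
  # one chromosome of 10,000 bp; state 1 covers 1,000 bp all inside the
  # 2,000 bp feature -> fold = (1000/2000) / (1000/10000) = 5
  seg <- make_segmentation(data.frame(
    chrom = "chr1",
    start = c(0, 1000, 3000),
    end = c(1000, 3000, 10000),
    state = c(1L, 2L, 3L)), c(chr1 = 10000), 200)
  feat <- list(F = genomic_intervals("chr1", 0, 2000))
  enr <- state_feature_enrichment(seg, feat)
  expect_equal(enr["1", "F"], 5)
  expect_equal(enr["3", "F"], 0)  # state absent from feature
  # single state covering everything -> fold 1
  seg1 <- make_segmentation(data.frame(chrom = "chr1", start = 0,
                                       end = 10000, state = 1L),
                            c(chr1 = 10000), 200)
  expect_equal(state_feature_enrichment(seg1, feat)["1", "F"], 1)
  expect_error(state_feature_enrichment(seg, list()), "non-empty")
})

test_that("state labeling follows the priority ladder and is total", {
  E <- rbind(c(0.90, 0.80, 0.05, 0.30),
             c(0.85, 0.10, 0.70, 0.10),
             c(0.02, 0.03, 0.04, 0.01),
             c(0.10, 0.70, 0.05, 0.40),
             c(0.05, 0.30, 0.05, 0.10),
             c(0.05, 0.05, 0.80, 0.05),
             c(0.05, 0.05, 0.30, 0.05),
             c(0.40, 0.05, 0.05, 0.90))
  colnames(E) <- c("H3K4me3", "H3K27ac", "H3K27me3", "BRG1")
  m <- hmm_model(rep(1/8, 8), rand_stochastic(8), E)
  folds <- c(5, 3, 0.5, 0.8, 0.5, 0.2, 0.3, 1.0)
  lab <- label_states(m, folds)
  expect_equal(lab$label, c("TSS Active", "Bivalent/poised TSS",
                            "Quiescent(low)", "Putative active enhancer",
                            "Putative weak enhancer", "Repressed",
                            "Weak repressed", "Other"))
  expect_equal(nrow(lab), 8L)           # every state labeled exactly once
  expect_false(anyNA(lab$label))
  E2 <- E[, 1:2, drop = FALSE]
  m2 <- hmm_model(rep(1/8, 8), rand_stochastic(8), E2)
  expect_error(label_states(m2, folds), "requires marks")
})

test_that("midpoint annotation assigns promoter bands, gene-body and
           distal categories; percentages sum to 100", {
  genes <- structure(data.frame(
    gene_id = c("g1"), chrom = "chr1", start = 50000, end = 70000,
    strand = "+", tss = 50000, tes = 69999, stringsAsFactors = FALSE),
    class = c("gene_models", "data.frame"))
  genes$exons <- I(list(data.frame(start = c(50000, 64000),
                                   end = c(52000, 66000))))
  iv <- genomic_intervals(
    "chr1",
    c(49400, 47500, 55000, 65000, 71000, 150000),
    c(49600, 47700, 55200, 65200, 71200, 150200))
  ann <- annotate_intervals(iv, genes)
  expect_equal(ann$annotation$category,
               c("Promoter (<=1kb)", "Promoter (2-3kb)", "Intron",
                 "Exon", "Downstream", "Distal Intergenic"))
  expect_equal(sum(ann$percentages$percent), 100, tolerance = 0.01)
  expect_equal(ann$annotation$nearest_gene[1], "g1")
  expect_lt(ann$annotation$distance_to_tss[1], 0)   # upstream is negative
  expect_equal(nrow(annotate_intervals(
    genomic_intervals(character(), numeric(), numeric()),
    genes)$annotation), 0L)
})

test_that("interval intersection honours half-open boundaries and matches
           the quadratic oracle", {
  a <- genomic_intervals("chr1", c(0, 0), c(100, 100))
  b <- genomic_intervals("chr1", c(99, 100), c(200, 200))
  res <- intersect_intervals(a[1, ], b)
  expect_equal(res$pairs$b_idx, 1L)      # 1 bp overlap reported
  expect_equal(res$pairs$overlap_bp, 1)
  res2 <- intersect_intervals(a[1, ], b[2, , drop = FALSE])
  expect_equal(nrow(res2$pairs), 0L)     # touching intervals do not overlap
  withr::with_seed(3, {
    ra <- rand_intervals(500)
    rb <- rand_intervals(500)
  })
  got <- intersect_intervals(ra, rb)
  want <- intersect_bruteforce(ra, rb)
  expect_equal(got$pairs[, c("a_idx", "b_idx")], want)
  expect_equal(got$n_a_overlapping, length(unique(want$a_idx)))
})
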