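test_that("TSS-region extraction merges state-1/2 runs and applies the
           4 kb broad threshold inclusively", {
  # 20 consecutive 200-bp TSS-state bins = 4,000 bp -> broad
  seg20 <- make_segmentation(data.frame(
    chrom = "chr1",
    start = c(0, 1000, 3000, 5000, 10000),
    end = c(1000, 3000, 5000, 10000, 20000),
    state = c(3L, 1L, 2L, 3L, 9L)), c(chr1 = 20000), 200)
  tr <- extract_tss_regions(seg20)
  expect_equal(tr$n_regions, 1L)
  expect_equal(tr$regions$length, 4000)
  expect_true(tr$regions$is_broad)          # "at least 4 kb" is inclusive
  expect_equal(tr$regions$states_spanned, "1,2")
  # 3,800 bp is not broad
  seg19 <- make_segmentation(data.frame(
    chrom = "chr1", start = c(0, 3800), end = c(3800, 20000),
    state = c(1L, 9L)), c(chr1 = 20000), 200)
  expect_false(extract_tss_regions(seg19)$regions$is_broad)
  # an intervening non-TSS state splits the run
  seg_split <- make_segmentation(data.frame(
    chrom = "chr1", start = c(0, 400, 600, 1000),
    end = c(400, 600, 1000, 20000),
    state = c(1L, 3L, 1L, 9L)), c(chr1 = 20000), 200)
  trs <- extract_tss_regions(seg_split)
  expect_equal(trs$n_regions, 2L)
  expect_equal(trs$regions$length, c(400, 400))
  expect_error(extract_tss_regions(seg20, tss_states = integer(0)),
               "non-empty")
  # histogram totals match the region count
  expect_equal(sum(tr$histogram$count), tr$n_regions)
})

test_that("gene attachment uses TSS +/- window half-open overlap and
           matches a brute-force scan", {
  region <- data.frame(chrom = "chr1", start = 10000, end = 14000,
                       states_spanned = "1", length = 4000,
                       is_broad = TRUE, stringsAsFactors = FALSE)
  mk_genes <- function(tss_vec) {
    g <- structure(data.frame(
      gene_id = paste0("g", seq_along(tss_vec)), chrom = "chr1",
      start = tss_vec, end = tss_vec + 1000, strand = "+",
      tss = tss_vec, tes = tss_vec + 999, stringsAsFactors = FALSE),
      class = c("gene_models", "data.frame"))
    g$exons <- I(rep(list(NULL), length(tss_vec)))
    g
  }
  # TSS at region center attached; TSS 1,001 bp beyond the end not
  genes <- mk_genes(c(12000, 15001, 14999))
  gm <- genes_for_regions(region, genes, window = 1000)
  expect_setequal(gm$map$gene_id, c("g1", "g3"))
  expect_equal(gm$broad_genes, c("g1", "g3"))
  # brute force on random instances
  withr::with_seed(8, {
    regs <- rand_intervals(60, chroms = "chr1", max_pos = 50000)
    regs$is_broad <- runif(60) < 0.5
    regs$length <- regs$end - regs$start
    tsses <- sample(0:50000, 80)
  })
  genes_r <- mk_genes(tsses)
  got <- genes_for_regions(regs, genes_r, window = 1000)
  want <- unlist(lapply(seq_len(nrow(regs)), function(i) {
    hits <- which(pmax(tsses - 1000, 0) < regs$end[i] &
                    regs$start[i] < tsses + 1000)
    if (!length(hits)) return(character(0))
    paste0(i, ":", genes_r$gene_id[hits])
  }))
  expect_setequal(paste0(got$map$region_idx, ":", got$map$gene_id), want)
})

test_that("TMM factors are invariant to gene order, neutral for identical
           or purely depth-scaled columns, and counter composition bias", {
  withr::with_seed(4, {
    base <- rnbinom(2000, mu = 100, size = 10) + 1
  })
  counts <- cbind(s1 = base, s2 = base)
  expect_equal(unname(tmm_factors(counts)), c(1, 1))
  # pure depth change: composition identical -> factors stay 1 and CPM is
  # unchanged because the library size absorbs the depth
  counts2 <- cbind(s1 = base, s2 = 2L * base)
  f2 <- tmm_factors(counts2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-6)
  cpm2 <- cpm_matrix(counts2, f2)
  expect_equal(cpm2[, "s1"], cpm2[, "s2"], tolerance = 1e-12)
  # permuting genes leaves factors unchanged
  perm <- sample(length(base))
  expect_equal(unname(tmm_factors(counts2[perm, ])), unname(f2))
  # composition bias: a minority of very highly expressed genes in s2
  counts3 <- cbind(s1 = base, s2 = base)
  counts3[1:40, "s2"] <- counts3[1:40, "s2"] * 50L
  f3 <- tmm_factors(counts3)
  expect_lt(f3[["s2"]] / f3[["s1"]], 1)  # s2 scaled down for its outliers
  expect_equal(prod(f3), 1, tolerance = 1e-9)
  expect_error(tmm_factors(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
  expect_error(tmm_factors(matrix(1, 2, 1)), "2 samples")
})

test_that("CPM and expressed-gene calls follow their definitions", {
  counts <- matrix(c(100, 0, 900000, 99900, 100, 0, 900000, 99900),
                   nrow = 4,
                   dimnames = list(paste0("g", 1:4), c("a1", "a2")))
  f <- c(a1 = 1, a2 = 1)
  cpm <- cpm_matrix(counts, f)
  expect_equal(unname(cpm["g1", "a1"]), 100)  # 100 / 1e6 * 1e6
  samples <- data.frame(sample_id = c("a1", "a2"),
                        cell_type = "A", category = "cat")
  ex <- call_expressed(cpm, samples)
  expect_true(ex["g1", "A"])
  expect_false(ex["g2", "A"])   # zero counts are never expressed
})

test_that("the Welch t-statistic matches the hand-computed example and its
           symmetries", {
  expect_equal(broadstates:::welch_t(c(10, 12), c(2, 4, 3)),
               8 / sqrt(1 + 1/3), tolerance = 1e-12)
  expect_equal(broadstates:::welch_t(c(10, 12), c(2, 4, 3)), 6.928,
               tolerance = 1e-3)
  expect_equal(broadstates:::welch_t(c(5, 7), c(5, 7)), 0)
  expect_equal(broadstates:::welch_t(c(2, 4, 3), c(10, 12)),
               -broadstates:::welch_t(c(10, 12), c(2, 4, 3)))
  expect_equal(broadstates:::welch_t(c(3, 3), c(3, 3)), 0)  # 0/0 -> 0
})

test_that("specificity ranking excludes same-category samples, ranks all
           genes, and flags the top decile", {
  cpm <- matrix(2^c(10, 10, 10, 2, 2, 2, 2,
                    5, 5, 5, 5, 5, 5, 5,
                    3, 3, 3, 3, 3, 9, 9),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"),
                                c("t1", "t2", "t3", "sis1", "sis2",
                                  "o1", "o2")))
  samples <- data.frame(
    sample_id = colnames(cpm),
    cell_type = c("T", "T", "T", "SIS", "SIS", "O", "O"),
    category = c("fib", "fib", "fib", "fib", "fib", "other", "other"),
    stringsAsFactors = FALSE)
  res <- specificity_t(cpm, samples, "T")
  expect_equal(res$rank, 1:3)
  expect_equal(res$gene_id[1], "gA")
  expect_equal(sum(res$is_specific), ceiling(0.1 * 3))
  # gA: target ~10, comparison restricted to o1/o2 (~2): large positive t;
  # had sisters been included the contrast would be unchanged for gA but
  # gC shows the difference between modes
  t_strict <- specificity_t(cpm, samples, "T", mode = "all_others")
  gC_loco <- res$t_stat[res$gene_id == "gC"]
  gC_strict <- t_strict$t_stat[t_strict$gene_id == "gC"]
  expect_false(isTRUE(all.equal(gC_loco, gC_strict)))
  expect_error(specificity_t(cpm[, 1:2], samples[1:2, ], "T"), ">= 2")
})

test_that("broad/specific overlap percentages reproduce the k-of-n
           arithmetic", {
  broad <- paste0("g", 1:52)
  specific <- c(paste0("g", 1:27), paste0("x", 1:100))
  ov <- broad_specific_overlap(broad, specific)
  expect_equal(ov$overlap, 27)
  expect_equal(ov$total, 52)
  expect_equal(ov$percentage, 100 * 27 / 52, tolerance = 1e-12)
  expect_equal(round(ov$percentage), 52)
  expect_equal(broad_specific_overlap(c("a"), c("b"))$percentage, 0)
  expect_equal(broad_specific_overlap(c("a", "b"),
                                      c("a", "b", "c"))$percentage, 100)
  expect_error(broad_specific_overlap(character(0), "a"), "empty")
  # restriction to an annotated subset
  ov2 <- broad_specific_overlap(broad, specific,
                                annotated_subset = paste0("g", 20:30))
  expect_equal(ov2$total, 11)
  expect_equal(ov2$overlap, 8)
})
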