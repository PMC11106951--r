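# Broad TSS-state domain detection and cell-type specificity ranking:
# TSS-state region extraction, region-gene attachment, TMM/CPM expression
# normalization, expressed-gene calls, leave-category-out Welch t ranking.

#' Extract predicted-TSS-state regions and flag broad domains
#'
#' Maximal runs of consecutive bins whose decoded state is in `tss_states`
#' (runs mixing states 1 and 2 form a single region) become regions; a
#' region is broad when its length is at least `broad_min` bp (inclusive).
#'
#' @param seg a [decode()] segmentation.
#' @param tss_states set of TSS states (default `c(1, 2)`).
#' @param broad_min broad-domain threshold in bp (default 4000).
#' @param hist_bin histogram bin width in bp (default 1000).
#' @return list of class `tss_regions`: `regions` (chrom, start, end,
#'   length, states_spanned, is_broad), `histogram` (length-bin counts),
#'   `n_regions`, `n_broad`, `pct_broad`.
#' @export
extract_tss_regions <- function(seg, tss_states = c(1L, 2L),
                                broad_min = 4000, hist_bin = 1000) {
  if (length(tss_states) == 0L) stop("tss_states must be non-empty",
                                     call. = FALSE)
  regions <- list()
  for (ch in unique(seg$chrom)) {
    sub <- seg[seg$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    in_tss <- sub$state %in% tss_states
    if (!any(in_tss)) next
    r <- rle(in_tss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    regions[[ch]] <- do.call(rbind, lapply(runs, function(i) {
      rows <- sub[starts[i]:ends[i], , drop = FALSE]
      data.frame(chrom = ch, start = min(rows$start), end = max(rows$end),
                 states_spanned = paste(sort(unique(rows$state)),
                                        collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               states_spanned = character(), stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  regions$length <- regions$end - regions$start
  regions$is_broad <- regions$length >= broad_min
  n <- nrow(regions)
  hist_counts <- if (n) {
    bins <- floor((regions$length - 1) / hist_bin)
    tab <- table(bins)
    data.frame(length_from = as.integer(names(tab)) * hist_bin,
               length_to = (as.integer(names(tab)) + 1L) * hist_bin,
               count = as.integer(tab))
  } else {
    data.frame(length_from = integer(), length_to = integer(),
               count = integer())
  }
  structure(list(regions = regions, histogram = hist_counts,
                 n_regions = n, n_broad = sum(regions$is_broad),
                 pct_broad = if (n) 100 * sum(regions$is_broad) / n else 0,
                 broad_min = broad_min),
            class = "tss_regions")
}

#' Attach genes to TSS-state regions
#'
#' A gene is attached to a region iff its TSS +/- `window` interval
#' overlaps the region by at least 1 bp (half-open arithmetic). Regions
#' may carry zero or several genes; a gene may appear in several regions.
#'
#' @param tssr an [extract_tss_regions()] result (or its `regions` frame).
#' @param genes `gene_models`.
#' @param window bp around the TSS (default 1000).
#' @return list with `map` (region_idx, gene_id, is_broad), `broad_genes`
#'   (genes attached to any broad region) and `regions` with a
#'   comma-separated `genes` column.
#' @export
genes_for_regions <- function(tssr, genes, window = 1000) {
  regions <- if (inherits(tssr, "tss_regions")) tssr$regions else tssr
  tw <- tss_windows(genes, window)
  hits <- intersect_intervals(regions, tw)
  map <- data.frame(region_idx = hits$pairs$a_idx,
                    gene_id = tw$name[hits$pairs$b_idx],
                    is_broad = regions$is_broad[hits$pairs$a_idx],
                    stringsAsFactors = FALSE)
  gene_col <- vapply(seq_len(nrow(regions)), function(i) {
    paste(sort(map$gene_id[map$region_idx == i]), collapse = ",")
  }, "")
  regions$genes <- gene_col
  list(map = map,
       broad_genes = sort(unique(map$gene_id[map$is_broad])),
       regions = regions)
}

#' TMM scale factors for a count matrix
#'
#' Trimmed-mean-of-M-values normalization (weighted trimmed mean of
#' per-gene log ratios against a reference sample, after trimming the
#' stated fractions of M and A values; factors are rescaled to geometric
#' mean 1). Computed via edgeR.
#'
#' @param counts genes x samples count matrix (>= 2 samples, no all-zero
#'   sample).
#' @param trim_M,trim_A trim fractions for log-ratios (0.30) and average
#'   intensities (0.05).
#' @return named per-sample factor vector.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(colSums(counts) == 0)) {
    stop("sample with all-zero counts", call. = FALSE)
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  setNames(as.numeric(f), colnames(counts))
}

#' Counts per million with TMM-effective library sizes
#'
#' `cpm = counts / (library_size * factor) * 1e6`.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample TMM factors ([tmm_factors()]); default
#'   computed from `counts`.
#' @return genes x samples CPM matrix.
#' @export
cpm_matrix <- function(counts, factors = tmm_factors(counts)) {
  counts <- as.matrix(counts)
  eff <- colSums(counts) * factors
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Call expressed genes per cell type
#'
#' A gene is expressed in a cell type iff its CPM reaches `threshold` in
#' at least `min_samples` of that type's samples (default: all of them).
#'
#' @param cpm CPM matrix from [cpm_matrix()].
#' @param samples metadata with `sample_id` and `cell_type`.
#' @param threshold CPM cutoff (default 1).
#' @param min_samples minimum qualifying samples; `NULL` = all replicates
#'   of the type.
#' @return genes x cell_types logical matrix.
#' @export
call_expressed <- function(cpm, samples, threshold = 1, min_samples = NULL) {
  cts <- unique(samples$cell_type)
  out <- matrix(FALSE, nrow = nrow(cpm), ncol = length(cts),
                dimnames = list(rownames(cpm), cts))
  for (ct in cts) {
    cols <- samples$sample_id[samples$cell_type == ct]
    need <- if (is.null(min_samples)) length(cols) else min_samples
    out[, ct] <- rowSums(cpm[, cols, drop = FALSE] >= threshold) >= need
  }
  out
}

welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- if (n1 > 1) stats::var(x) else 0
  v2 <- if (n2 > 1) stats::var(y) else 0
  se2 <- v1 / n1 + v2 / n2
  d <- mean(x) - mean(y)
  if (se2 == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else {
    d / sqrt(se2)
  }
}

#' Rank cell-type-specific genes by leave-category-out t-statistic
#'
#' For each gene a Welch two-sample t-statistic is computed on
#' `log2(cpm + 1)` between the target cell type's samples and all samples
#' whose biological category differs from the target's (same-category
#' non-target samples are excluded entirely, so sister cell lines cannot
#' deflate specificity). Genes are ranked by t descending (ties broken by
#' gene id) and the top `ceil(top_fraction * G)` are flagged specific. A
#' strict "target vs all other samples" comparison is available via
#' `mode = "all_others"`.
#'
#' @param cpm CPM matrix.
#' @param samples metadata with `sample_id`, `cell_type`, `category`.
#' @param target_cell_type cell type being ranked.
#' @param top_fraction fraction flagged specific (default 0.10).
#' @param mode `"leave_category_out"` (default) or `"all_others"`.
#' @return data frame (`gene_id`, `cell_type`, `t_stat`, `rank`,
#'   `is_specific`) sorted by rank.
#' @export
specificity_t <- function(cpm, samples, target_cell_type,
                          top_fraction = 0.10,
                          mode = c("leave_category_out", "all_others")) {
  mode <- match.arg(mode)
  in_target <- samples$cell_type == target_cell_type
  if (sum(in_target) < 2L) {
    stop("need >= 2 samples in the target cell type", call. = FALSE)
  }
  target_cat <- unique(samples$category[in_target])
  comp <- if (mode == "leave_category_out") {
    !in_target & !(samples$category %in% target_cat)
  } else {
    !in_target
  }
  if (sum(comp) < 2L) {
    stop("need >= 2 comparison samples outside the target's category",
         call. = FALSE)
  }
  x <- log2(cpm[, samples$sample_id[in_target], drop = FALSE] + 1)
  y <- log2(cpm[, samples$sample_id[comp], drop = FALSE] + 1)
  t_stat <- vapply(seq_len(nrow(cpm)),
                   function(i) welch_t(x[i, ], y[i, ]), 0)
  gene_id <- rownames(cpm)
  ord <- order(-t_stat, gene_id)
  G <- length(gene_id)
  n_top <- ceiling(top_fraction * G)
  res <- data.frame(gene_id = gene_id[ord],
                    cell_type = target_cell_type,
                    t_stat = t_stat[ord],
                    rank = seq_len(G),
                    is_specific = seq_len(G) <= n_top,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Overlap of broad-domain genes with cell-type-specific genes
#'
#' `percentage = 100 * |broad ∩ specific| / |broad|`, optionally after
#' restricting the broad set to an annotated subset (e.g. the genes of the
#' top overrepresented biological-process terms).
#'
#' @param broad_genes character vector of broad-domain gene ids
#'   (non-empty).
#' @param specific a [specificity_t()] result (or a character vector of
#'   specific gene ids).
#' @param annotated_subset optional gene set to restrict `broad_genes` to.
#' @return list with `overlap`, `total`, `percentage`, `genes`.
#' @export
broad_specific_overlap <- function(broad_genes, specific,
                                   annotated_subset = NULL) {
  if (length(broad_genes) == 0L) stop("broad gene set is empty",
                                      call. = FALSE)
  spec_ids <- if (is.data.frame(specific)) {
    specific$gene_id[specific$is_specific]
  } else {
    specific
  }
  set <- unique(broad_genes)
  if (!is.null(annotated_subset)) set <- intersect(set, annotated_subset)
  if (length(set) == 0L) stop("broad gene set empty after restriction",
                              call. = FALSE)
  hit <- intersect(set, spec_ids)
  list(overlap = length(hit), total = length(set),
       percentage = 100 * length(hit) / length(set), genes = sort(hit))
}
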