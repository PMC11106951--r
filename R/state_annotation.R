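# Relating states and peaks to genome features: TSS meta-profiles,
# state-vs-feature fold enrichment, emission-based state labeling, peak
# feature annotation, and interval intersection.

#' TSS-centered meta-profile of a binned track
#'
#' For each gene a strand-oriented row of signal around the TSS (upstream
#' on the left) is extracted at bin resolution; the profile is the column
#' mean. Genes whose window crosses a chromosome edge contribute `NA` in
#' the out-of-range columns and are excluded from those columns' means.
#'
#' @param track a [binned_track()].
#' @param genes `gene_models`.
#' @param flank bp on each side of the TSS (multiple of the bin size;
#'   default 3000).
#' @return list with `profile` (length `2*flank/bin_size + 1`) and
#'   `matrix` (genes x columns, rows ordered by row sum descending, the
#'   usual heatmap order; rownames are gene ids).
#' @export
tss_metaprofile <- function(track, genes, flank = 3000L) {
  bs <- track$grid$bin_size
  if (flank %% bs != 0) stop("flank must be a multiple of the bin size",
                             call. = FALSE)
  fb <- flank %/% bs
  ncol_out <- 2L * fb + 1L
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = ncol_out,
                dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) next
    center <- bin_index(genes$tss[i], track$grid)
    idx <- (center - fb):(center + fb)
    ok <- idx >= 0 & idx < length(v)
    row <- rep(NA_real_, ncol_out)
    row[ok] <- v[idx[ok] + 1L]
    strand <- genes$strand[i]
    if (strand == "-") row <- rev(row)  # "." treated as "+"
    mat[i, ] <- row
  }
  profile <- colMeans(mat, na.rm = TRUE)
  profile[is.nan(profile)] <- NA_real_
  ord <- order(-rowSums(mat, na.rm = TRUE))
  list(profile = profile, matrix = mat[ord, , drop = FALSE])
}

# total bp of pairwise overlap between two interval sets on shared chroms
overlap_bp <- function(a, b) {
  total <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- IRanges::reduce(IRanges::IRanges(
      start = a$start[a$chrom == ch] + 1L, end = a$end[a$chrom == ch]))
    ib <- IRanges::reduce(IRanges::IRanges(
      start = b$start[b$chrom == ch] + 1L, end = b$end[b$chrom == ch]))
    total <- total + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  total
}

#' State-by-feature fold enrichment
#'
#' `fold = (bp of state within feature / bp of feature) /
#' (bp of state genome-wide / genome bp)`; 0/0 is reported as 0.
#'
#' @param seg a [decode()] segmentation.
#' @param features named list of `genomic_intervals` feature sets.
#' @return states x features matrix of fold enrichments.
#' @export
state_feature_enrichment <- function(seg, features) {
  if (length(features) == 0L) stop("features must be non-empty",
                                   call. = FALSE)
  grid <- attr(seg, "grid")
  genome_bp <- sum(grid$chrom_lengths)
  states <- sort(unique(seg$state))
  out <- matrix(0, nrow = length(states), ncol = length(features),
                dimnames = list(states, names(features)))
  feat_bp <- vapply(features, function(f) {
    sum(vapply(unique(f$chrom), function(ch) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
        start = f$start[f$chrom == ch] + 1L, end = f$end[f$chrom == ch]))))
    }, 0)) }, 0)
  for (si in seq_along(states)) {
    s <- states[si]
    sub <- seg[seg$state == s, , drop = FALSE]
    state_bp <- sum(sub$end - sub$start)
    state_frac <- state_bp / genome_bp
    for (fi in seq_along(features)) {
      if (feat_bp[fi] == 0 || state_frac == 0) next
      inside <- overlap_bp(sub, features[[fi]])
      out[si, fi] <- (inside / feat_bp[fi]) / state_frac
    }
  }
  out
}

#' Default state-labeling thresholds
#'
#' @return list of the emission and TSS-fold cutoffs used by
#'   [label_states()].
#' @export
label_thresholds <- function() {
  list(strong_emission = 0.5, tss_flanking_emission = 0.3,
       weak_emission = 0.2, quiescent_emission = 0.1, tss_fold = 2)
}

#' Assign biological labels to learned states
#'
#' A fixed priority ladder over emission probabilities and TSS fold
#' enrichment: bivalent/poised TSS (both H3K4me3 and H3K27me3 strong),
#' TSS Active, TSS Flanking, putative active/weak enhancer, repressed,
#' weak repressed, quiescent, else Other. Every state receives exactly one
#' label (first matching rule wins).
#'
#' @param model an [hmm_model()] whose marks include H3K4me3, H3K27ac and
#'   H3K27me3.
#' @param tss_fold per-state fold enrichment at TSS +/- 1 kb (e.g. the
#'   "TSS" column of [state_feature_enrichment()]).
#' @param thresholds see [label_thresholds()].
#' @return data frame (`state`, `label`) of class `state_labels`.
#' @export
label_states <- function(model, tss_fold, thresholds = label_thresholds()) {
  need <- c("H3K4me3", "H3K27ac", "H3K27me3")
  if (!all(need %in% model$marks)) {
    stop("labeling requires marks H3K4me3, H3K27ac and H3K27me3",
         call. = FALSE)
  }
  th <- thresholds
  E <- model$E
  labels <- character(model$K)
  for (k in seq_len(model$K)) {
    k4 <- E[k, "H3K4me3"]; ac <- E[k, "H3K27ac"]; me3 <- E[k, "H3K27me3"]
    fold <- tss_fold[k]
    labels[k] <-
      if (k4 >= th$strong_emission && me3 >= th$strong_emission) {
        "Bivalent/poised TSS"
      } else if (k4 >= th$strong_emission && ac >= th$strong_emission &&
                 fold >= th$tss_fold) {
        "TSS Active"
      } else if (k4 >= th$tss_flanking_emission && fold >= th$tss_fold) {
        "TSS Flanking"
      } else if (ac >= th$strong_emission && fold < th$tss_fold) {
        "Putative active enhancer"
      } else if (ac >= th$weak_emission && ac < th$strong_emission &&
                 fold < th$tss_fold) {
        "Putative weak enhancer"
      } else if (me3 >= th$strong_emission) {
        "Repressed"
      } else if (me3 >= th$weak_emission && me3 < th$strong_emission) {
        "Weak repressed"
      } else if (all(E[k, ] < th$quiescent_emission)) {
        "Quiescent(low)"
      } else {
        "Other"
      }
  }
  structure(data.frame(state = seq_len(model$K), label = labels,
                       stringsAsFactors = FALSE),
            class = c("state_labels", "data.frame"))
}

feature_categories <- c("Promoter (<=1kb)", "Promoter (1-2kb)",
                        "Promoter (2-3kb)", "5' UTR", "3' UTR", "Exon",
                        "Intron", "Downstream", "Distal Intergenic")

#' Annotate intervals with genomic feature categories
#'
#' Each interval is categorized by its midpoint with the priority ladder
#' promoter bands (distance to the nearest TSS within 1/2/3 kb) > UTRs
#' (when gene models carry them) > exon > intron > downstream (within 3 kb
#' past the TES) > distal intergenic. Signed TSS distance is
#' strand-oriented (negative = upstream).
#'
#' @param intervals `genomic_intervals`.
#' @param genes `gene_models` (non-empty).
#' @param downstream_bp downstream window past the TES (default 3000).
#' @return list with `annotation` (interval, category, nearest_gene,
#'   distance_to_tss) and `percentages` (category percentage table summing
#'   to 100).
#' @export
annotate_intervals <- function(intervals, genes, downstream_bp = 3000) {
  if (nrow(genes) == 0L) stop("genes must be non-empty", call. = FALSE)
  if (nrow(intervals) == 0L) {
    return(list(annotation = data.frame(), percentages = data.frame(
      category = character(), count = integer(), percent = numeric())))
  }
  mid <- floor((intervals$start + intervals$end) / 2)
  category <- character(nrow(intervals))
  nearest_gene <- character(nrow(intervals))
  dist_tss <- numeric(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    m <- mid[i]
    cand <- which(genes$chrom == ch)
    if (!length(cand)) {
      category[i] <- "Distal Intergenic"
      nearest_gene[i] <- NA_character_
      dist_tss[i] <- NA_real_
      next
    }
    d_raw <- m - genes$tss[cand]
    # strand-oriented signed distance: negative upstream of the TSS
    d_signed <- ifelse(genes$strand[cand] == "-", -d_raw, d_raw)
    j <- which.min(abs(d_signed))
    g <- cand[j]
    nearest_gene[i] <- genes$gene_id[g]
    dist_tss[i] <- d_signed[j]
    admin <- min(abs(d_signed))
    inside <- genes$chrom == ch & m >= genes$start & m < genes$end
    category[i] <- if (admin <= 1000) {
      "Promoter (<=1kb)"
    } else if (admin <= 2000) {
      "Promoter (1-2kb)"
    } else if (admin <= 3000) {
      "Promoter (2-3kb)"
    } else if (any(inside)) {
      gi <- which(inside)[1]
      ex <- genes$exons[[gi]]
      in_exon <- !is.null(ex) && nrow(ex) > 0 &&
        any(m >= ex$start & m < ex$end)
      utr5 <- if ("utr5" %in% names(genes)) genes$utr5[[gi]]
      utr3 <- if ("utr3" %in% names(genes)) genes$utr3[[gi]]
      in_utr <- function(u) !is.null(u) && NROW(u) > 0 &&
        any(m >= u$start & m < u$end)
      if (in_utr(utr5)) {
        "5' UTR"
      } else if (in_utr(utr3)) {
        "3' UTR"
      } else if (in_exon) "Exon" else "Intron"
    } else {
      downstream <- vapply(seq_along(cand), function(jj) {
        g2 <- cand[jj]
        if (genes$strand[g2] == "-") {
          m < genes$start[g2] & m >= genes$start[g2] - downstream_bp
        } else {
          m >= genes$end[g2] & m < genes$end[g2] + downstream_bp
        }
      }, FALSE)
      if (any(downstream)) "Downstream" else "Distal Intergenic"
    }
  }
  ann <- data.frame(chrom = intervals$chrom, start = intervals$start,
                    end = intervals$end, category = category,
                    nearest_gene = nearest_gene,
                    distance_to_tss = dist_tss, stringsAsFactors = FALSE)
  counts <- table(factor(category, levels = feature_categories))
  pct <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    percent = 100 * as.integer(counts) / nrow(ann),
                    stringsAsFactors = FALSE)
  list(annotation = ann, percentages = pct)
}

#' Intersect two interval sets (bedtools-style)
#'
#' A pair is reported iff the intervals share at least 1 bp under
#' half-open arithmetic (`a.start < b.end && b.start < a.end`).
#'
#' @param a,b `genomic_intervals` data frames.
#' @return list with `pairs` (row indices `a_idx`, `b_idx` plus overlap
#'   bp), `n_a_overlapping` (a-intervals with >= 1 overlap) and
#'   `n_b_overlapping`.
#' @export
intersect_intervals <- function(a, b) {
  pairs <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia_idx <- which(a$chrom == ch)
    ib_idx <- which(b$chrom == ch)
    ia <- IRanges::IRanges(start = a$start[ia_idx] + 1L, end = a$end[ia_idx])
    ib <- IRanges::IRanges(start = b$start[ib_idx] + 1L, end = b$end[ib_idx])
    hits <- IRanges::findOverlaps(ia, ib, minoverlap = 1L)
    if (length(hits)) {
      qa <- ia_idx[S4Vectors::queryHits(hits)]
      qb <- ib_idx[S4Vectors::subjectHits(hits)]
      ov <- pmin(a$end[qa], b$end[qb]) - pmax(a$start[qa], b$start[qb])
      pairs[[ch]] <- data.frame(a_idx = qa, b_idx = qb, overlap_bp = ov)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a_idx = integer(), b_idx = integer(),
               overlap_bp = numeric())
  rownames(pairs) <- NULL
  pairs <- pairs[order(pairs$a_idx, pairs$b_idx), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       n_a_overlapping = length(unique(pairs$a_idx)),
       n_b_overlapping = length(unique(pairs$b_idx)))
}

#' TSS +/- window intervals for a gene set
#'
#' Convenience feature set ("TSS" feature) used for fold enrichment and
#' region-gene attachment.
#'
#' @param genes `gene_models`.
#' @param window bp on each side (default 1000).
#' @return `genomic_intervals` named by gene id.
#' @export
tss_windows <- function(genes, window = 1000) {
  start <- pmax(genes$tss - window, 0)
  end <- genes$tss + window
  genomic_intervals(genes$chrom, start, end, genes$strand,
                    name = genes$gene_id)
}
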