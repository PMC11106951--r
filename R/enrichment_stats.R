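# Gene-set overrepresentation (one-sided Fisher + Benjamini-Hochberg) and
# the 2^-ddCt relative-quantification utility.

#' One-sided (upper-tail) Fisher exact p-value
#'
#' For a gene set of size `n` drawn from a universe of size `N` containing
#' `K` term genes, the probability of observing `k` or more term genes:
#' `p = sum_{i>=k} C(K,i) C(N-K,n-i) / C(N,n)` — the hypergeometric upper
#' tail, evaluated stably in log space.
#'
#' @param k observed overlap; @param K term size; @param n set size;
#' @param N universe size.
#' @return the p-value.
#' @export
fisher_upper <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N <= 0) || k > K || k > n || K > N ||
      n > N) {
    stop("inconsistent contingency values: need 0 <= k <= min(K, n) <= N",
         call. = FALSE)
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (p_(j) * n / j)` on the
#' sorted p-values, capped at 1, mapped back to input order.
#'
#' @param pvalues numeric vector with entries in (0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Term overrepresentation of a gene set
#'
#' One result per term with at least one overlapping gene; BH correction
#' is applied across all tested terms before the significance filters.
#'
#' @param gene_set character vector (subset of `universe`).
#' @param term_map data frame with columns `term` and `gene_id`.
#' @param universe gene universe; default = all genes in the term map
#'   union the gene set. Genes without term annotation stay in the
#'   universe unless `drop_unannotated = TRUE`.
#' @param alpha_p,alpha_q significance cutoffs applied to p and q (default
#'   0.05 each); `NULL` disables a filter.
#' @param drop_unannotated drop universe genes absent from the term map.
#' @return data frame (`term`, `k`, `K`, `n`, `N`, `p`, `q`) sorted by p
#'   ascending, filtered at the cutoffs; the unfiltered table is attached
#'   as attribute `all_terms`.
#' @export
enrich <- function(gene_set, term_map, universe = NULL, alpha_p = 0.05,
                   alpha_q = 0.05, drop_unannotated = FALSE) {
  if (is.null(universe)) {
    universe <- union(unique(term_map$gene_id), gene_set)
  }
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (drop_unannotated) {
    universe <- intersect(universe, unique(term_map$gene_id))
  }
  gene_set <- intersect(unique(gene_set), universe)
  if (length(gene_set) == 0L) stop("gene set empty within universe",
                                   call. = FALSE)
  N <- length(universe)
  n <- length(gene_set)
  terms <- split(term_map$gene_id, term_map$term)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), universe)
    k <- length(intersect(tg, gene_set))
    if (k == 0L) return(NULL)
    data.frame(term = tm, k = k, K = length(tg), n = n, N = N,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(structure(data.frame(term = character(), k = integer(),
                                K = integer(), n = integer(), N = integer(),
                                p = numeric(), q = numeric()),
                     all_terms = NULL))
  }
  rows$p <- vapply(seq_len(nrow(rows)), function(i) {
    fisher_upper(rows$k[i], rows$K[i], rows$n[i], rows$N[i])
  }, 0)
  rows$q <- bh_adjust(rows$p)
  rows <- rows[order(rows$p, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(alpha_p)) keep <- keep & rows$p <= alpha_p
  if (!is.null(alpha_q)) keep <- keep & rows$q <= alpha_q
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_terms") <- rows
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical-replicate Ct values are averaged, normalized to the reference
#' gene (`dCt = Ct_target - Ct_reference`), then to the calibrator sample
#' (`ddCt = dCt_sample - dCt_calibrator`); the relative fold change is
#' `2^-ddCt`.
#'
#' @param records data frame with columns `sample`, `gene`, and one or
#'   more Ct replicate columns (names starting with `ct`); must include
#'   the reference gene for every sample.
#' @param reference_gene housekeeping gene (e.g. "GAPDH").
#' @param calibrator calibrator sample id.
#' @return data frame (`sample`, `gene`, `dct`, `ddct`, `fold`) for all
#'   non-reference genes.
#' @export
ddct <- function(records, reference_gene, calibrator) {
  ct_cols <- grep("^ct", names(records), value = TRUE)
  if (!length(ct_cols)) stop("no Ct columns (named ct*) found",
                             call. = FALSE)
  if (any(records[ct_cols] <= 0, na.rm = TRUE)) {
    stop("Ct values must be > 0", call. = FALSE)
  }
  records$mean_ct <- rowMeans(records[ct_cols], na.rm = TRUE)
  samples <- unique(records$sample)
  if (!calibrator %in% samples) stop("calibrator sample not present",
                                     call. = FALSE)
  ref_ct <- setNames(rep(NA_real_, length(samples)), samples)
  for (s in samples) {
    r <- records$mean_ct[records$sample == s &
                           records$gene == reference_gene]
    if (length(r) != 1L) {
      stop("reference gene missing (or duplicated) for sample ", s,
           call. = FALSE)
    }
    ref_ct[s] <- r
  }
  tgt <- records[records$gene != reference_gene, , drop = FALSE]
  tgt$dct <- tgt$mean_ct - ref_ct[tgt$sample]
  cal <- tgt[tgt$sample == calibrator, c("gene", "dct")]
  idx <- match(tgt$gene, cal$gene)
  if (anyNA(idx)) {
    stop("calibrator measurement missing for gene ",
         tgt$gene[which(is.na(idx))[1]], call. = FALSE)
  }
  tgt$ddct <- tgt$dct - cal$dct[idx]
  tgt$fold <- 2^(-tgt$ddct)
  out <- tgt[, c("sample", "gene", "dct", "ddct", "fold")]
  rownames(out) <- NULL
  out
}
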