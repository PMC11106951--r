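# broadstates

Chromatin-state segmentation and broad H3K4me3 domain analysis for
CUT&RUN profiles of paired cell types, with a matched expression-based
ranking of cell-type-specific genes.

## The problem

Early-development cell types (for example a fetal fibroblast and a
trophectoderm line) can be told apart by how chromatin is organized
around their genes. Profiling a handful of features — H3K4me3 (active
promoters), H3K27ac (active promoters/enhancers), H3K27me3
(Polycomb-repressed chromatin) and the SWI/SNF ATPase BRG1 — and jointly
segmenting the genome into *chromatin states* reveals, among other
things, a small set of unusually **broad (≥ 4 kb) H3K4me3 / TSS-state
domains**. These domains mark genes tied to cell identity: they are
enriched for developmental biological processes and overlap the genes a
transcriptome-based t-statistic ranks as most cell-type-specific.

`broadstates` implements that analysis end to end for R users:

1. **Spike-in normalization** — per-sample scale factor `C /
   spikein_reads` for exported coverage tracks.
2. **Binarization** — per-mark, per-bin Poisson upper-tail test
   (`P(X ≥ x) ≤ 1e-4`) against a global or IgG-conditioned background.
3. **Segmentation** — a K-state hidden Markov model with independent
   Bernoulli emissions per mark,
   `P(x | z) = Π_m E[z,m]^x_m (1 − E[z,m])^(1−x_m)`,
   fitted by Baum–Welch EM (scaled forward–backward in C++, restarts,
   states re-indexed by H3K4me3 emission) and decoded by per-bin
   maximum posterior.
4. **Interpretation** — emission/TSS-fold state labels, midpoint-based
   genomic feature annotation, bedtools-style half-open interval
   intersection.
5. **Broad domains** — maximal runs of predicted-TSS-state bins
   (states 1–2); regions spanning ≥ 4 kb are broad; genes attach via
   TSS ± 1 kb overlap.
6. **Specificity** — TMM-normalized CPM (edgeR), then a per-gene Welch
   t-statistic of the target cell type against all samples *outside its
   biological category*; the top decile is flagged specific.
7. **Overrepresentation** — one-sided Fisher (hypergeometric upper
   tail) with Benjamini–Hochberg correction, and the overlap of
   broad-domain genes with the specific list. A `2^-ddCt` qPCR utility
   is included for wet-lab validation data.

A synthetic-data module (`sim_config()`, `simulate_study()`) generates a
complete miniature study — genome, gene models, ground-truth state
paths, mark counts, spike-ins, negative-binomial expression, term map —
so the whole pipeline runs and is tested without any downloads.

## Worked example

```r
library(broadstates)
res <- run_pipeline(sim_config(seed = 1), out_dir = "run1")

tr <- res$tss_regions$PFF_like
cat("TSS regions (PFF-like):", tr$n_regions, "| broad (>=4 kb):",
    tr$n_broad, sprintf("(%.1f%%)\n", tr$pct_broad))
#> TSS regions (PFF-like): 379 | broad (>=4 kb): 19 (5.0%)

head(res$enrichment$PFF_like, 2)
#>                    term  k  K  n   N            p           q
#> 1 developmental_process 20 20 20 400 3.586336e-34 7.88994e-33

head(res$specificity$spec$PFF_like, 3)
#>    gene_id cell_type   t_stat rank is_specific
#> 1 gene0083  PFF_like 32.01349    1        TRUE
#> 2 gene0330  PFF_like 22.37594    2        TRUE
#> 3 gene0286  PFF_like 16.10371    3        TRUE

str(evaluate_recovery(res)$PFF_like)
#> List of 3
#>  $ broad_recovered   : num 1
#>  $ false_broad       : int 0
#>  $ specific_recovered: num 1
```

Reading the output: the decoded segmentation contains 379 predicted
TSS-state regions in the fibroblast-like cell type, 19 of them broad —
exactly the planted 5%. The planted "developmental_process" term (which
contains the 20 broad-domain genes) tops the overrepresentation table
with `q ≈ 8e-33`, the planted specific genes head the t-statistic
ranking, and the ground-truth comparison confirms that every planted
broad gene was recovered with no false broad calls.

`run1/` holds all stage outputs as plain text: the simulated study
(`simulated/`), scale factors, ChromHMM-style binarized calls, the model
(`model.tsv`), labeled state segments (BED), feature annotations, TSS
region tables and length histograms, specificity rankings, enrichment
tables, the overlap report, and a `manifest.json` recording the
configuration hash and seed. Reruns with the same seed are
byte-identical.

A thin CLI covering simulation and the full run lives at
`inst/scripts/broadstates-run.R`:

```sh
Rscript inst/scripts/broadstates-run.R run-all --seed 1 --out run1
```

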