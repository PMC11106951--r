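# Synthetic study generator: a miniature two-cell-type epigenome with known
# ground truth, used to exercise every stage of the pipeline.

#' Default state-wise Poisson rates (mean reads/bin) per mark
#'
#' Rows are the ten ground-truth chromatin states, columns the profiled
#' marks plus the IgG control. The design gives every state a distinct,
#' near-deterministic binarized signature: a mark is either "present"
#' (18 reads/bin, called in >90% of bins at the default binarization
#' threshold) or "absent" (0.05 reads/bin, essentially never called).
#' Exactly two states carry H3K4me3 — TSS Active (with H3K27ac) and TSS
#' Flanking (alone) — so the two highest-H3K4me3 states of a learned
#' model are always the TSS states; the remaining eight states enumerate
#' the combinations of H3K27ac/H3K27me3/BRG1. IgG is flat (0.2) in every
#' state, as a non-specific control should be.
#'
#' @return a 10 x 5 numeric matrix with dimnames.
#' @export
default_state_rates <- function() {
  hi <- 18; lo <- 0.05
  m <- rbind(
    `1_TSS_Active`       = c(25, 25, lo, lo, 0.2),
    `2_TSS_Flanking`     = c(hi, lo, lo, lo, 0.2),
    `3_Poised_Enhancer`  = c(lo, hi, hi, lo, 0.2),
    `4_Enhancer_Active`  = c(lo, hi, lo, hi, 0.2),
    `5_Enhancer_Weak`    = c(lo, hi, lo, lo, 0.2),
    `6_BRG1_Only`        = c(lo, lo, lo, hi, 0.2),
    `7_Repressed`        = c(lo, lo, hi, lo, 0.2),
    `8_Repressed_BRG1`   = c(lo, lo, hi, hi, 0.2),
    `9_Quiescent`        = c(lo, lo, lo, lo, 0.2),
    `10_Mixed_Signal`    = c(lo, hi, hi, hi, 0.2))
  colnames(m) <- c("H3K4me3", "H3K27ac", "H3K27me3", "BRG1", "IgG")
  m
}

# Jump distribution of the background chain (states 3-10); also its
# stationary distribution, since every state jumps with the same law.
# Quiescent-heavy so high-rate states stay sparse genome-wide.
background_state_weights <- function() {
  c(`3` = 0.02, `4` = 0.03, `5` = 0.04, `6` = 0.08,
    `7` = 0.10, `8` = 0.04, `9` = 0.67, `10` = 0.02)
}

#' Build a simulation configuration
#'
#' Defaults define the study conditions emulated throughout: two cell
#' types ("PFF_like", "PTr2_like") sharing one genome and annotation, four
#' marks plus IgG, 10 chromatin states, 10% planted cell-type-specific
#' genes at log2 fold change 3, and 5% of genes given broad (>= 4.4 kb)
#' TSS-state runs.
#'
#' @param seed master seed; per-component seeds are derived by fixed
#'   offsets.
#' @param n_chroms,chrom_length,bin_size genome shape (2 x 2 Mb, 200 bp).
#' @param n_genes number of genes (400).
#' @param n_states number of ground-truth states (10).
#' @param marks ordered mark names; the last entry is treated as the IgG
#'   control.
#' @param state_rates states x marks Poisson mean reads/bin.
#' @param transition_bias self-transition probability of the background
#'   state chain (0.96).
#' @param n_reps_cutrun CUT&RUN replicates per mark (2).
#' @param n_reps_rna RNA-seq replicates per cell type (3).
#' @param frac_specific_genes fraction of genes planted cell-type-specific
#'   (0.10, split evenly between the two types).
#' @param specific_log2fc planted log2 fold change (3.0).
#' @param frac_broad_genes fraction of genes given broad TSS runs (0.05).
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param spikein_mean Poisson mean of spike-in read totals per sample.
#' @param gene_length_range,min_gap,edge_margin gene placement geometry in
#'   bp; the 6 kb minimum gap guarantees a broad run at one TSS cannot
#'   merge with the next gene's TSS region.
#' @param ordinary_run_bp,broad_run_bp length ranges (bp) of planted
#'   TSS-state runs for ordinary and broad genes.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 2e6,
                       bin_size = 200L,
                       n_genes = 400L,
                       n_states = 10L,
                       marks = c("H3K4me3", "H3K27ac", "H3K27me3", "BRG1",
                                 "IgG"),
                       state_rates = default_state_rates(),
                       transition_bias = 0.96,
                       n_reps_cutrun = 2L,
                       n_reps_rna = 3L,
                       frac_specific_genes = 0.10,
                       specific_log2fc = 3.0,
                       frac_broad_genes = 0.05,
                       nb_dispersion = 0.1,
                       spikein_mean = 5000,
                       gene_length_range = c(1000, 3000),
                       min_gap = 6000,
                       edge_margin = 8000,
                       ordinary_run_bp = c(1000, 2000),
                       broad_run_bp = c(4400, 6000)) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, bin_size = as.integer(bin_size),
              n_genes = as.integer(n_genes), n_states = as.integer(n_states),
              marks = marks, state_rates = state_rates,
              transition_bias = transition_bias,
              cell_types = c("PFF_like", "PTr2_like"),
              n_reps_cutrun = as.integer(n_reps_cutrun),
              n_reps_rna = as.integer(n_reps_rna),
              frac_specific_genes = frac_specific_genes,
              specific_log2fc = specific_log2fc,
              frac_broad_genes = frac_broad_genes,
              nb_dispersion = nb_dispersion, spikein_mean = spikein_mean,
              gene_length_range = gene_length_range, min_gap = min_gap,
              edge_margin = edge_margin, ordinary_run_bp = ordinary_run_bp,
              broad_run_bp = broad_run_bp)
  stopifnot(nrow(state_rates) == cfg$n_states,
            ncol(state_rates) == length(marks))
  if (any(state_rates < 0)) stop("state_rates must be >= 0", call. = FALSE)
  for (f in c("frac_specific_genes", "frac_broad_genes")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      stop(f, " must be in (0,1)", call. = FALSE)
    }
  }
  if (transition_bias <= 0 || transition_bias >= 1) {
    stop("transition_bias must be in (0,1)", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the genome and gene models
#'
#' Genes are placed without overlap at uniform random positions (respecting
#' an edge margin and minimum intergenic gap), on both strands, with a
#' single exon spanning each gene. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return `list(grid, genes)` — a [bin_grid()] and a `gene_models` frame.
#' @export
simulate_genome <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chroms))
  grid <- bin_grid(setNames(rep(config$chrom_length, config$n_chroms),
                            chroms), config$bin_size)
  if (config$n_genes == 0L) {
    return(list(grid = grid, genes = empty_gene_models()))
  }
  withr::with_seed(config$seed + 101L, {
    per_chrom <- table(factor(sample(chroms, config$n_genes, replace = TRUE),
                              levels = chroms))
    rows <- list()
    gi <- 0L
    for (ch in chroms) {
      n <- as.integer(per_chrom[[ch]])
      if (n == 0L) next
      lens <- sample(seq(config$gene_length_range[1],
                         config$gene_length_range[2]), n, replace = TRUE)
      usable <- config$chrom_length - 2 * config$edge_margin
      need <- sum(lens) + (n - 1) * config$min_gap
      if (need > usable) {
        stop(paste0("genes cannot fit on ", ch, " without overlap; ",
                    "reduce n_genes or gene lengths"), call. = FALSE)
      }
      free <- usable - need
      cuts <- sort(runif(n, 0, free))
      starts <- config$edge_margin + cuts +
        c(0, cumsum(lens[-n] + config$min_gap))
      starts <- floor(starts / config$bin_size) * config$bin_size
      strand <- sample(c("+", "-"), n, replace = TRUE)
      rows[[ch]] <- data.frame(
        gene_id = sprintf("gene%04d", gi + seq_len(n)), chrom = ch,
        start = starts, end = starts + lens, strand = strand,
        stringsAsFactors = FALSE)
      gi <- gi + n
    }
    gm <- do.call(rbind, rows)
    rownames(gm) <- NULL
    gm$tss <- ifelse(gm$strand == "-", gm$end - 1, gm$start)
    gm$tes <- ifelse(gm$strand == "-", gm$start, gm$end - 1)
    gm$exons <- I(lapply(seq_len(nrow(gm)), function(i) {
      data.frame(start = gm$start[i], end = gm$end[i])
    }))
    class(gm) <- c("gene_models", "data.frame")
    list(grid = grid, genes = gm)
  })
}

# sample one background-chain path of length n over states 3..10; a jump
# always lands on a different state, so the realized self-transition
# frequency matches transition_bias
sample_background_path <- function(n, transition_bias) {
  w <- background_state_weights()
  states <- as.integer(names(w))
  path <- integer(n)
  path[1] <- sample(states, 1L, prob = w)
  jumps <- which(runif(n - 1) >= transition_bias) + 1L
  for (t in 2:n) path[t] <- path[t - 1]
  for (t in jumps) {
    keep <- states != path[t - 1]
    path[t] <- sample(states[keep], 1L, prob = w[keep])
    # propagate the new state forward to the next jump
    nxt <- jumps[jumps > t]
    stop_at <- if (length(nxt)) nxt[1] - 1L else n
    if (stop_at > t) path[(t + 1L):stop_at] <- path[t]
  }
  path
}

#' Simulate ground-truth chromatin-state paths
#'
#' A background Markov chain (self-transition `transition_bias`, jumps to a
#' quiescent-heavy distribution over states 3-10) is shared between the two
#' cell types; state paths differ only at planted loci. Each gene receives
#' a TSS-state run (state 1 core with state 2 flanks) starting one bin
#' upstream of its TSS and extending into the gene body: 1-2 kb for
#' ordinary genes, >= 4.4 kb for broad genes. Cell-type-specific genes get
#' their TSS run only in their own type and the repressed state (7) at the
#' same locus in the other type.
#'
#' @param config a [sim_config()].
#' @param genes gene models from [simulate_genome()].
#' @return a `ground_truth` list: `state_path[[cell_type]][[chrom]]`,
#'   `broad_genes[[cell_type]]`, `specific_genes[[cell_type]]`, and a
#'   `planted` data frame of run windows (bin coordinates).
#' @export
simulate_state_paths <- function(config, genes) {
  grid <- bin_grid(setNames(rep(config$chrom_length, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms))),
                   config$bin_size)
  withr::with_seed(config$seed + 202L, {
    bg <- lapply(grid$n_bins, function(n) {
      sample_background_path(n, config$transition_bias)
    })
    cts <- config$cell_types
    paths <- setNames(lapply(cts, function(ct) bg), cts)
    G <- nrow(genes)
    specific <- setNames(vector("list", length(cts)), cts)
    broad <- character(0)
    planted <- NULL
    if (G > 0) {
      n_spec <- round(config$frac_specific_genes * G)
      spec_ids <- sample(genes$gene_id, n_spec)
      half <- ceiling(n_spec / 2)
      specific[[cts[1]]] <- sort(spec_ids[seq_len(half)])
      specific[[cts[2]]] <- sort(spec_ids[-seq_len(half)])
      n_broad <- round(config$frac_broad_genes * G)
      broad <- sort(sample(setdiff(genes$gene_id, spec_ids), n_broad))
      bs <- config$bin_size
      run_len_bins <- function(rng) {
        lo <- ceiling(rng[1] / bs); hi <- floor(rng[2] / bs)
        sample(lo:hi, 1L)
      }
      recs <- list()
      for (i in seq_len(G)) {
        gid <- genes$gene_id[i]
        ch <- genes$chrom[i]
        nb <- grid$n_bins[[ch]]
        L <- if (gid %in% broad) run_len_bins(config$broad_run_bp)
             else run_len_bins(config$ordinary_run_bp)
        tss_bin <- bin_index(genes$tss[i], grid)
        if (genes$strand[i] == "-") {
          b1 <- min(tss_bin + 1L, nb - 1L); b0 <- max(b1 - L + 1L, 0L)
        } else {
          b0 <- max(tss_bin - 1L, 0L); b1 <- min(b0 + L - 1L, nb - 1L)
        }
        run <- rep(1L, b1 - b0 + 1L)
        if (length(run) >= 3L) {
          run[1L] <- 2L
          run[length(run)] <- 2L
        }
        own <- cts[vapply(cts, function(ct) gid %in% specific[[ct]], FALSE)]
        if (length(own) == 1L) {
          other <- setdiff(cts, own)
          paths[[own]][[ch]][(b0:b1) + 1L] <- run
          paths[[other]][[ch]][(b0:b1) + 1L] <- 7L
        } else {
          for (ct in cts) paths[[ct]][[ch]][(b0:b1) + 1L] <- run
        }
        recs[[gid]] <- data.frame(gene_id = gid, chrom = ch, bin_start = b0,
                                  bin_end = b1, n_bins = b1 - b0 + 1L,
                                  is_broad = gid %in% broad,
                                  specific_to = if (length(own) == 1L) own
                                                else NA_character_,
                                  stringsAsFactors = FALSE)
      }
      planted <- do.call(rbind, recs)
      rownames(planted) <- NULL
    }
    structure(list(state_path = paths,
                   broad_genes = setNames(list(broad, broad), cts),
                   specific_genes = specific, planted = planted,
                   grid = grid),
              class = "ground_truth")
  })
}

#' Simulate per-bin mark read counts and spike-in totals
#'
#' Counts in bin `b` for mark `m` are Poisson with mean
#' `state_rates[path(b), m]`; IgG is flat by construction of the rate
#' table. Replicates are independent draws sharing the state-wise means.
#' Spike-in totals are Poisson(`spikein_mean`) per sample.
#'
#' @param config a [sim_config()].
#' @param truth from [simulate_state_paths()].
#' @return list with `tracks[[cell_type]][[replicate]][[mark]]`
#'   ([binned_track()] objects) and a `spikein` data frame
#'   (sample_id, cell_type, replicate, mark, spikein_reads).
#' @export
simulate_mark_counts <- function(config, truth) {
  grid <- truth$grid
  withr::with_seed(config$seed + 303L, {
    tracks <- list()
    spike <- list()
    for (ct in config$cell_types) {
      tracks[[ct]] <- list()
      for (r in seq_len(config$n_reps_cutrun)) {
        rep_id <- paste0("rep", r)
        tracks[[ct]][[rep_id]] <- list()
        for (m in seq_along(config$marks)) {
          mark <- config$marks[m]
          vals <- lapply(truth$state_path[[ct]], function(path) {
            rpois(length(path), config$state_rates[path, m])
          })
          sid <- paste(ct, mark, rep_id, sep = "_")
          tracks[[ct]][[rep_id]][[mark]] <-
            binned_track(grid, vals, sample_id = sid, mark = mark)
          spike[[sid]] <- data.frame(
            sample_id = sid, cell_type = ct, replicate = rep_id, mark = mark,
            spikein_reads = rpois(1L, config$spikein_mean),
            stringsAsFactors = FALSE)
        }
      }
    }
    spikein <- do.call(rbind, spike)
    rownames(spikein) <- NULL
    list(tracks = tracks, spikein = spikein)
  })
}

#' Simulate the expression matrix, sample metadata and term map
#'
#' Counts are negative binomial with gene baseline means drawn log-normal
#' (median 200) and dispersion `nb_dispersion`; planted specific genes have
#' mean `baseline * 2^specific_log2fc` in their own cell type and the
#' baseline in the other. A term map is emitted in which one
#' "developmental process" term contains exactly the broad genes; the
#' remaining terms are random gene subsets.
#'
#' @param config a [sim_config()].
#' @param truth from [simulate_state_paths()].
#' @param genes gene models.
#' @param n_terms number of terms in the term map (default 25).
#' @return list with `counts` (genes x samples integer matrix), `samples`
#'   (sample_id, cell_type, category), and `terms` (term, gene_id).
#' @export
simulate_expression <- function(config, truth, genes, n_terms = 25L) {
  withr::with_seed(config$seed + 404L, {
    G <- nrow(genes)
    cts <- config$cell_types
    categories <- setNames(c("fibroblast", "trophectoderm"), cts)
    samples <- do.call(rbind, lapply(cts, function(ct) {
      data.frame(sample_id = paste0(ct, "_rna", seq_len(config$n_reps_rna)),
                 cell_type = ct, category = categories[[ct]],
                 stringsAsFactors = FALSE)
    }))
    rownames(samples) <- NULL
    mu_base <- rlnorm(G, meanlog = log(200), sdlog = 1)
    mu <- matrix(rep(mu_base, length(cts)), nrow = G,
                 dimnames = list(genes$gene_id, cts))
    for (ct in cts) {
      spec <- truth$specific_genes[[ct]]
      mu[spec, ct] <- mu_base[match(spec, genes$gene_id)] *
        2^config$specific_log2fc
    }
    counts <- matrix(0L, nrow = G, ncol = nrow(samples),
                     dimnames = list(genes$gene_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      m <- mu[, samples$cell_type[j]]
      counts[, j] <- if (config$nb_dispersion <= 0) {
        rpois(G, m)
      } else {
        rnbinom(G, mu = m, size = 1 / config$nb_dispersion)
      }
    }
    broad_all <- sort(unique(unlist(truth$broad_genes)))
    terms <- list(data.frame(term = "developmental_process",
                             gene_id = broad_all, stringsAsFactors = FALSE))
    other_pool <- genes$gene_id
    for (t in seq_len(max(0L, n_terms - 1L))) {
      sz <- sample(10:40, 1L)
      terms[[t + 1L]] <- data.frame(
        term = sprintf("term%02d", t),
        gene_id = sort(sample(other_pool, min(sz, length(other_pool)))),
        stringsAsFactors = FALSE)
    }
    terms <- do.call(rbind, terms)
    rownames(terms) <- NULL
    list(counts = counts, samples = samples, terms = terms)
  })
}

#' Generate the complete synthetic study
#'
#' Runs genome, state-path, mark-count and expression simulation under one
#' master seed, optionally writing every artifact to disk in the plain-text
#' formats the readers in this package consume (genes.gtf, genes.bed,
#' per-sample bedGraphs, spikein.tsv, expression_counts.tsv, samples.tsv,
#' terms.tsv, truth.json).
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory to write artifacts into.
#' @return list with `config`, `grid`, `genes`, `truth`, `tracks`,
#'   `spikein`, `expression`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  gen <- simulate_genome(config)
  truth <- simulate_state_paths(config, gen$genes)
  marks <- simulate_mark_counts(config, truth)
  expr <- simulate_expression(config, truth, gen$genes)
  study <- list(config = config, grid = gen$grid, genes = gen$genes,
                truth = truth, tracks = marks$tracks,
                spikein = marks$spikein, expression = expr)
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(study$genes, file.path(out_dir, "genes.gtf"))
  gi <- genomic_intervals(study$genes$chrom, study$genes$start,
                          study$genes$end, study$genes$strand,
                          name = study$genes$gene_id, score = 0)
  write_bed(gi, file.path(out_dir, "genes.bed"))
  for (ct in names(study$tracks)) {
    for (rep_id in names(study$tracks[[ct]])) {
      for (mark in names(study$tracks[[ct]][[rep_id]])) {
        tr <- study$tracks[[ct]][[rep_id]][[mark]]
        write_track(tr, file.path(out_dir,
                                  paste0(tr$sample_id, ".bedGraph")))
      }
    }
  }
  write.table(study$spikein, file.path(out_dir, "spikein.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- data.frame(gene_id = rownames(study$expression$counts),
                       study$expression$counts, check.names = FALSE)
  write.table(counts, file.path(out_dir, "expression_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$expression$samples, file.path(out_dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$expression$terms, file.path(out_dir, "terms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- list(
    broad_genes = study$truth$broad_genes,
    specific_genes = study$truth$specific_genes,
    state_path = lapply(study$truth$state_path, function(p) p))
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(out_dir)
}
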