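# End-to-end orchestration: simulate -> normalize -> binarize -> learn ->
# decode -> label -> annotate -> TSS regions/broad -> expression/
# specificity -> enrichment -> overlap, with a deterministic run manifest.

#' Read a pipeline run configuration from YAML
#'
#' The YAML may contain a `simulate:` block (fields of [sim_config()]) and
#' a flat set of stage parameters (`p_binarize`, `n_states`, `broad_min`,
#' `top_fraction`, `alpha_p`, `alpha_q`, `learn_mode`, `decode_mode`,
#' `n_restarts`, `seed`).
#'
#' @param path YAML file.
#' @return list with `sim` (a [sim_config()]) and `params`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulate %||% list()
  if (!is.null(y$seed) && is.null(sim_args$seed)) sim_args$seed <- y$seed
  if (!is.null(sim_args$state_rates)) {
    sim_args$state_rates <- do.call(rbind, sim_args$state_rates)
    colnames(sim_args$state_rates) <- sim_args$marks %||%
      colnames(default_state_rates())
  }
  sim <- do.call(sim_config, sim_args)
  params <- y[setdiff(names(y), "simulate")]
  list(sim = sim, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes every stage on data generated by [simulate_study()] and writes
#' all stage outputs under `out_dir`. Outputs are pure functions of
#' (config, seed): rerunning with the same configuration reproduces them
#' byte-identically.
#'
#' @param config a [sim_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @param out_dir output directory (created).
#' @param p_binarize Poisson tail probability for binarization (1e-4).
#' @param broad_min broad-domain threshold in bp (4000).
#' @param top_fraction specific-gene decile (0.10).
#' @param alpha_p,alpha_q enrichment significance cutoffs (0.05).
#' @param learn_mode `"concatenated"` (one model shared by both cell
#'   types, the default) or `"per_cell_type"`.
#' @param decode_mode `"posterior"` (default) or `"viterbi"`.
#' @param n_restarts EM restarts (40; generous restarts guard against
#'   local optima that merge or split states).
#' @param n_top_terms number of top overrepresented terms whose genes are
#'   compared with the specific list (5).
#' @param write_normalized also export spike-in-scaled smoothed bedGraphs
#'   (default TRUE).
#' @return invisibly, a list with every stage result (`study`, `models`,
#'   `segmentations`, `labels`, `annotation`, `tss_regions`,
#'   `region_genes`, `expression`, `specificity`, `enrichment`,
#'   `overlap`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         p_binarize = 1e-4, broad_min = 4000,
                         top_fraction = 0.10, alpha_p = 0.05,
                         alpha_q = 0.05,
                         learn_mode = c("concatenated", "per_cell_type"),
                         decode_mode = c("posterior", "viterbi"),
                         n_restarts = 40L, n_top_terms = 5L,
                         write_normalized = TRUE) {
  learn_mode <- match.arg(learn_mode)
  decode_mode <- match.arg(decode_mode)
  if (is.character(config)) {
    rc <- read_run_config(config)
    config <- rc$sim
    for (p in intersect(names(rc$params),
                        c("p_binarize", "broad_min", "top_fraction",
                          "alpha_p", "alpha_q", "learn_mode",
                          "decode_mode", "n_restarts", "n_top_terms"))) {
      assign(p, rc$params[[p]])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  study <- stage("simulate",
                 simulate_study(config, file.path(out_dir, "simulated")))
  genes <- study$genes
  marks_signal <- setdiff(config$marks, "IgG")
  cts <- config$cell_types

  # spike-in scale factors + optional normalized browser tracks
  sf_tab <- study$spikein
  sf_tab$factor <- vapply(sf_tab$spikein_reads, function(r) {
    spikein_scale_factor(r)$factor
  }, 0)
  write.table(sf_tab, file.path(out_dir, "scale_factors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (write_normalized) {
    stage("normalize", {
      norm_dir <- file.path(out_dir, "normalized")
      dir.create(norm_dir, showWarnings = FALSE)
      for (ct in cts) {
        for (rep_id in names(study$tracks[[ct]])) {
          for (mark in marks_signal) {
            tr <- study$tracks[[ct]][[rep_id]][[mark]]
            sf <- spikein_scale_factor(
              sf_tab$spikein_reads[sf_tab$sample_id == tr$sample_id],
              sample_id = tr$sample_id)
            nt <- normalize_track(tr, sf, smooth_bins = 3L)
            write_track(nt, file.path(norm_dir,
                                      paste0(tr$sample_id, ".norm.bedGraph")))
          }
        }
      }
    })
  }

  # binarization (replicates pooled, IgG control)
  binaries <- stage("binarize", {
    out <- list()
    for (ct in cts) {
      reps <- study$tracks[[ct]]
      mark_tracks <- setNames(lapply(marks_signal, function(m) {
        lapply(reps, `[[`, m)
      }), marks_signal)
      igg <- lapply(reps, `[[`, "IgG")
      ctrl <- igg[[1]]
      if (length(igg) > 1L) {
        vals <- Reduce(function(u, v) Map(`+`, u, v),
                       lapply(igg[-1], `[[`, "values"),
                       igg[[1]]$values)
        ctrl <- binned_track(igg[[1]]$grid, vals, sample_id = "IgG_pooled",
                             mark = "IgG")
      }
      bm <- binarize(mark_tracks, control = ctrl, p = p_binarize,
                     cell_type = ct)
      write_binary_matrix(bm, file.path(out_dir, "binarized"))
      out[[ct]] <- bm
    }
    out
  })

  # model learning and decoding
  models <- stage("learn", {
    if (learn_mode == "concatenated") {
      m <- learn_model(unname(binaries), K = config$n_states,
                       seed = config$seed + 707L, n_restarts = n_restarts)
      setNames(rep(list(m), length(cts)), cts)
    } else {
      setNames(lapply(seq_along(cts), function(i) {
        learn_model(binaries[[cts[i]]], K = config$n_states,
                    seed = config$seed + 707L + i,
                    n_restarts = n_restarts)
      }), cts)
    }
  })
  write_hmm_model(models[[1]], file.path(out_dir, "model.tsv"))
  if (learn_mode == "per_cell_type") {
    for (ct in cts) {
      write_hmm_model(models[[ct]],
                      file.path(out_dir, paste0("model_", ct, ".tsv")))
    }
  }
  segmentations <- stage("decode", {
    setNames(lapply(cts, function(ct) {
      decode(models[[ct]], binaries[[ct]], mode = decode_mode)
    }), cts)
  })

  # state labeling (TSS fold enrichment + emissions)
  features <- list(TSS = tss_windows(genes, 1000),
                   gene_body = genomic_intervals(genes$chrom, genes$start,
                                                 genes$end, genes$strand))
  labels <- stage("label", {
    setNames(lapply(cts, function(ct) {
      enr <- state_feature_enrichment(segmentations[[ct]], features)
      fold <- setNames(rep(0, models[[ct]]$K), seq_len(models[[ct]]$K))
      fold[rownames(enr)] <- enr[, "TSS"]
      lab <- label_states(models[[ct]], fold)
      lab$tss_fold <- as.numeric(fold)
      lab
    }), cts)
  })
  for (ct in cts) {
    write.table(labels[[ct]],
                file.path(out_dir, paste0("state_labels_", ct, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_segmentation(segmentations[[ct]],
                       file.path(out_dir, paste0("segments_", ct, ".bed")),
                       labels = labels[[ct]])
  }

  # feature annotation of binarized mark runs (peak stand-ins)
  annotation <- stage("annotate", {
    out <- list()
    for (ct in cts) {
      bm <- binaries[[ct]]
      for (m in marks_signal) {
        peaks <- calls_to_intervals(bm, m)
        if (nrow(peaks) == 0L) next
        ann <- annotate_intervals(peaks, genes)
        out[[paste(ct, m, sep = "_")]] <- ann$percentages
        write.table(ann$annotation,
                    file.path(out_dir,
                              paste0("annotation_", ct, "_", m, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    out
  })

  # TSS regions, broad domains, associated genes
  tss_regions <- stage("tss-regions", {
    setNames(lapply(cts, function(ct) {
      extract_tss_regions(segmentations[[ct]], broad_min = broad_min)
    }), cts)
  })
  region_genes <- setNames(lapply(cts, function(ct) {
    genes_for_regions(tss_regions[[ct]], genes)
  }), cts)
  for (ct in cts) {
    write.table(region_genes[[ct]]$regions,
                file.path(out_dir, paste0("tss_regions_", ct, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tss_regions[[ct]]$histogram,
                file.path(out_dir,
                          paste0("tss_region_histogram_", ct, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # expression normalization and specificity ranking
  expr <- study$expression
  specificity <- stage("specificity", {
    factors <- tmm_factors(expr$counts)
    cpm <- cpm_matrix(expr$counts, factors)
    expressed <- call_expressed(cpm, expr$samples)
    spec <- setNames(lapply(cts, function(ct) {
      specificity_t(cpm, expr$samples, ct, top_fraction = top_fraction)
    }), cts)
    list(factors = factors, cpm = cpm, expressed = expressed, spec = spec)
  })
  for (ct in cts) {
    write.table(specificity$spec[[ct]],
                file.path(out_dir, paste0("specificity_", ct, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # overrepresentation of broad-domain genes, then overlap with the
  # specific list restricted to the top terms' genes
  enrichment <- stage("enrich", {
    setNames(lapply(cts, function(ct) {
      bg <- region_genes[[ct]]$broad_genes
      if (length(bg) == 0L) return(NULL)
      enrich(bg, expr$terms, universe = genes$gene_id,
             alpha_p = alpha_p, alpha_q = alpha_q)
    }), cts)
  })
  overlap <- stage("overlap", {
    out <- list()
    for (ct in cts) {
      er <- enrichment[[ct]]
      bg <- region_genes[[ct]]$broad_genes
      if (is.null(er) || nrow(er) == 0L || length(bg) == 0L) next
      top_terms <- head(er$term, n_top_terms)
      term_genes <- unique(
        expr$terms$gene_id[expr$terms$term %in% top_terms])
      bp_list <- intersect(term_genes, bg)
      if (length(bp_list) == 0L) next
      ov <- broad_specific_overlap(bp_list, specificity$spec[[ct]])
      out[[ct]] <- data.frame(cell_type = ct, overlap = ov$overlap,
                              total = ov$total, percentage = ov$percentage,
                              stringsAsFactors = FALSE)
      write.table(er, file.path(out_dir, paste0("enrichment_", ct, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ov_tab <- do.call(rbind, out)
    if (!is.null(ov_tab)) {
      write.table(ov_tab, file.path(out_dir, "overlap_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ov_tab
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("broadstates")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    params = list(p_binarize = p_binarize, broad_min = broad_min,
                  top_fraction = top_fraction, alpha_p = alpha_p,
                  alpha_q = alpha_q, learn_mode = learn_mode,
                  decode_mode = decode_mode, n_restarts = n_restarts,
                  n_top_terms = n_top_terms),
    outputs = sort(list.files(out_dir, recursive = TRUE),
                   method = "radix"))  # locale-independent order
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(study = study, binaries = binaries, models = models,
                 segmentations = segmentations, labels = labels,
                 annotation = annotation, tss_regions = tss_regions,
                 region_genes = region_genes, expression = expr,
                 specificity = specificity, enrichment = enrichment,
                 overlap = overlap, manifest = manifest))
}

#' Merge a mark's binarized calls into intervals
#'
#' Runs of consecutive 1-bins for one mark become intervals — the
#' binarized-run stand-in for peaks.
#'
#' @param bm a [binarize()] result.
#' @param mark mark name.
#' @return `genomic_intervals`.
#' @export
calls_to_intervals <- function(bm, mark) {
  grid <- bm$grid
  rows <- list()
  for (ch in names(bm$calls)) {
    v <- bm$calls[[ch]][, mark]
    r <- rle(as.integer(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values == 1L
    if (!any(keep)) next
    rows[[ch]] <- data.frame(
      chrom = ch, start = starts[keep] * grid$bin_size,
      end = pmin(ends[keep] * grid$bin_size, grid$chrom_lengths[[ch]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  df <- do.call(rbind, rows)
  genomic_intervals(df$chrom, df$start, df$end)
}

#' Recovery of planted broad and specific genes (ground-truth evaluation)
#'
#' Convenience used by the test-suite and the acceptance script: compares
#' pipeline calls with the simulation's ground truth.
#'
#' @param result a [run_pipeline()] result.
#' @return list with per-cell-type broad recovery (fraction of planted
#'   broad genes called broad), false-broad counts among ordinary genes,
#'   and specific-gene recovery (fraction of planted specific genes in the
#'   top decile).
#' @export
evaluate_recovery <- function(result) {
  truth <- result$study$truth
  cts <- names(result$tss_regions)
  out <- list()
  for (ct in cts) {
    called_broad <- result$region_genes[[ct]]$broad_genes
    planted_broad <- truth$broad_genes[[ct]]
    ordinary <- setdiff(result$study$genes$gene_id,
                        union(planted_broad,
                              unlist(truth$specific_genes)))
    spec_res <- result$specificity$spec[[ct]]
    planted_spec <- truth$specific_genes[[ct]]
    top <- spec_res$gene_id[spec_res$is_specific]
    out[[ct]] <- list(
      broad_recovered = mean(planted_broad %in% called_broad),
      false_broad = sum(ordinary %in% called_broad),
      specific_recovered = mean(planted_spec %in% top))
  }
  out
}
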