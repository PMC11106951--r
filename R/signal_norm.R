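# Spike-in scale factors, coverage smoothing, and Poisson-background
# binarization of binned counts.

#' Spike-in scale factor
#'
#' Exogenous-genome (e.g. E. coli) aligned-read totals calibrate samples
#' against each other: the per-sample factor is `constant_C /
#' spikein_reads`, so samples with fewer spike-in reads (more target
#' material per cell) are scaled up.
#'
#' @param spikein_reads aligned spike-in read count (> 0).
#' @param constant_C scaling constant (default 10000, a common CUT&RUN
#'   convention).
#' @param sample_id optional identifier.
#' @return list of class `scale_factor` with fields `sample_id`,
#'   `spikein_reads`, `constant_C`, `factor`.
#' @export
spikein_scale_factor <- function(spikein_reads, constant_C = 10000,
                                 sample_id = "") {
  if (length(spikein_reads) != 1L || is.na(spikein_reads) ||
      spikein_reads <= 0) {
    stop("spikein_reads must be > 0 (zero suggests a failed spike-in)",
         call. = FALSE)
  }
  if (constant_C <= 0) stop("constant_C must be > 0", call. = FALSE)
  structure(list(sample_id = sample_id,
                 spikein_reads = as.numeric(spikein_reads),
                 constant_C = constant_C,
                 factor = constant_C / spikein_reads),
            class = "scale_factor")
}

#' Scale (and optionally smooth) a binned track
#'
#' Every bin is multiplied by the spike-in factor. Optional smoothing is a
#' centered running mean over `smooth_bins` bins, edge-truncated (edge
#' windows average only the available bins) — the binned analogue of
#' browser-track smoothing (e.g. a 60 bp smooth over 20 bp bins = 3 bins).
#' Smoothing is off by default: binarization operates on raw counts;
#' smoothing is for exported browser tracks.
#'
#' @param track a [binned_track()].
#' @param sf a [spikein_scale_factor()] (or `NULL` for factor 1).
#' @param smooth_bins odd window width in bins; 1 or `NULL` disables.
#' @return a scaled [binned_track()].
#' @export
normalize_track <- function(track, sf = NULL, smooth_bins = NULL) {
  f <- if (is.null(sf)) 1 else sf$factor
  if (!is.null(smooth_bins)) {
    if (smooth_bins < 1) {
      stop("smooth window must cover at least one bin", call. = FALSE)
    }
    smooth_bins <- as.integer(smooth_bins)
  }
  vals <- lapply(track$values, function(v) {
    v <- v * f
    if (!is.null(smooth_bins) && smooth_bins > 1L) {
      v <- zoo::rollapply(v, width = smooth_bins, FUN = mean,
                          partial = TRUE, align = "center")
    }
    v
  })
  binned_track(track$grid, vals, sample_id = track$sample_id,
               mark = track$mark)
}

#' Poisson upper-tail binarization threshold
#'
#' Smallest integer `x` such that `P(X >= x) <= p` for
#' `X ~ Poisson(lambda_bg)` — the count at which a bin is called enriched
#' against a Poisson background.
#'
#' @param lambda_bg background mean (> 0); vectorized.
#' @param p tail probability (0 < p <= 1), default 1e-4.
#' @return integer threshold(s).
#' @export
poisson_threshold <- function(lambda_bg, p = 1e-4) {
  if (any(lambda_bg <= 0)) stop("lambda_bg must be > 0", call. = FALSE)
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("p must be in (0, 1]", call. = FALSE)
  }
  if (p == 1) return(rep.int(0L, length(lambda_bg)))
  # P(X >= x) <= p  <=>  P(X <= x-1) >= 1-p; start from the quantile and
  # adjust locally to be safe against boundary rounding.
  x <- qpois(1 - p, lambda_bg) + 1L
  step_down <- ppois(x - 2L, lambda_bg, lower.tail = FALSE) <= p & x >= 1L
  while (any(step_down)) {
    x[step_down] <- x[step_down] - 1L
    step_down <- ppois(x - 2L, lambda_bg, lower.tail = FALSE) <= p & x >= 1L
  }
  step_up <- ppois(x - 1L, lambda_bg, lower.tail = FALSE) > p
  while (any(step_up)) {
    x[step_up] <- x[step_up] + 1L
    step_up <- ppois(x - 1L, lambda_bg, lower.tail = FALSE) > p
  }
  as.integer(x)
}

#' Binarize pooled mark tracks against a Poisson background
#'
#' Replicate tracks for each mark are summed, then each bin is called 1
#' iff its count reaches [poisson_threshold()] at that bin's background
#' mean. The background mean is the mark's global mean count/bin; when an
#' IgG control track is supplied it is smoothed (running mean over
#' `control_smooth_bins` bins, stabilizing the sparse control) and the
#' per-bin background becomes
#' `max(global mean, smoothed_control * signal_total / control_total)`,
#' so bins with elevated non-specific signal need proportionally more
#' reads to be called.
#'
#' @param tracks named list: mark -> list of replicate [binned_track()]s
#'   (or a single track).
#' @param control optional IgG [binned_track()] (replicates pre-summed) on
#'   the same grid.
#' @param p Poisson tail probability (default 1e-4).
#' @param control_smooth_bins smoothing window for the control (default
#'   25 bins).
#' @param cell_type label stored on the result.
#' @return object of class `binary_matrix`: `grid`, `marks`, `cell_type`,
#'   and `calls[[chrom]]` — bins x marks 0/1 integer matrices.
#' @export
binarize <- function(tracks, control = NULL, p = 1e-4,
                     control_smooth_bins = 25L, cell_type = "") {
  marks <- names(tracks)
  if (is.null(marks) || any(!nzchar(marks))) {
    stop("tracks must be a named list (mark -> tracks)", call. = FALSE)
  }
  pooled <- lapply(tracks, function(trs) {
    if (inherits(trs, "binned_track")) trs <- list(trs)
    out <- trs[[1]]$values
    if (length(trs) > 1L) {
      for (tr in trs[-1]) {
        if (!identical(tr$grid$n_bins, trs[[1]]$grid$n_bins)) {
          stop("replicate tracks are on different grids", call. = FALSE)
        }
        out <- Map(`+`, out, tr$values)
      }
    }
    list(grid = trs[[1]]$grid, values = out)
  })
  grid <- pooled[[1]]$grid
  for (pm in pooled) {
    if (!identical(pm$grid$n_bins, grid$n_bins)) {
      stop("mark tracks are on different grids", call. = FALSE)
    }
  }
  ctrl_smooth <- NULL
  ctrl_total <- NULL
  if (!is.null(control)) {
    if (!identical(control$grid$n_bins, grid$n_bins)) {
      stop("control track grid mismatch", call. = FALSE)
    }
    ctrl_total <- sum(unlist(control$values))
    ctrl_smooth <- lapply(control$values, function(v) {
      zoo::rollapply(v, width = control_smooth_bins, FUN = mean,
                     partial = TRUE, align = "center")
    })
  }
  chroms <- names(grid$n_bins)
  calls <- setNames(lapply(chroms, function(ch) {
    matrix(0L, nrow = grid$n_bins[[ch]], ncol = length(marks),
           dimnames = list(NULL, marks))
  }), chroms)
  for (m in marks) {
    v <- pooled[[m]]$values
    total <- sum(unlist(v))
    lambda_global <- total / sum(grid$n_bins)
    lambda_global <- max(lambda_global, 1e-9)
    for (ch in chroms) {
      lam <- rep(lambda_global, grid$n_bins[[ch]])
      if (!is.null(ctrl_smooth) && ctrl_total > 0) {
        lam <- pmax(lam, ctrl_smooth[[ch]] * (total / ctrl_total))
      }
      thr <- poisson_threshold(lam, p)
      calls[[ch]][, m] <- as.integer(v[[ch]] >= thr)
    }
  }
  structure(list(grid = grid, marks = marks, cell_type = cell_type,
                 calls = calls), class = "binary_matrix")
}

#' Write a binary matrix in ChromHMM-style binarized text
#'
#' One file per chromosome: a header line `cellType<TAB>chrom`, a line of
#' tab-separated mark names, then one 0/1 row per bin.
#'
#' @param bm a [binarize()] result.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_binary_matrix <- function(bm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in names(bm$calls)) {
    path <- file.path(dir, paste0(bm$cell_type, "_", ch, "_binary.txt"))
    con <- file(path, "w")
    writeLines(paste(bm$cell_type, ch, sep = "\t"), con)
    writeLines(paste(bm$marks, collapse = "\t"), con)
    writeLines(apply(bm$calls[[ch]], 1L, paste, collapse = "\t"), con)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read ChromHMM-style binarized text files
#'
#' @param paths files written by [write_binary_matrix()].
#' @param grid the [bin_grid()] the calls refer to.
#' @return a `binary_matrix`.
#' @export
read_binary_matrix <- function(paths, grid) {
  calls <- list()
  cell_type <- NULL
  marks <- NULL
  for (path in paths) {
    lines <- readLines(path)
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    ct <- hdr[1]; ch <- hdr[2]
    mk <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
    if (is.null(marks)) { marks <- mk; cell_type <- ct }
    if (!identical(mk, marks)) stop("mark headers differ between files",
                                    call. = FALSE)
    body <- do.call(rbind, strsplit(lines[-(1:2)], "\t", fixed = TRUE))
    mat <- matrix(as.integer(body), ncol = length(mk),
                  dimnames = list(NULL, mk))
    if (!all(mat %in% c(0L, 1L))) stop("non-binary entries in ", path,
                                       call. = FALSE)
    calls[[ch]] <- mat
  }
  calls <- calls[names(grid$n_bins)[names(grid$n_bins) %in% names(calls)]]
  structure(list(grid = grid, marks = marks, cell_type = cell_type,
                 calls = calls), class = "binary_matrix")
}
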