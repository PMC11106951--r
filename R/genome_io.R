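# Core genomic types and plain-text readers/writers.
#
# Conventions: every interval inside the package is 0-based half-open
# [start, end) on a named chromosome, with strand one of "+", "-", ".".
# GTF (1-based closed) is converted at the boundary.

#' Construct a validated set of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand` (and optionally `name`, `score`), using 0-based half-open
#' coordinates. This constructor validates the invariants shared by all
#' downstream modules.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand character vector in `{"+", "-", "."}`; recycled.
#' @param name optional name column.
#' @param score optional numeric score column.
#' @return a `data.frame` of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NULL,
                              score = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(chrom) | !nzchar(chrom))) {
    stop("chromosome names must be non-empty strings", call. = FALSE)
  }
  if (any(is.na(start) | is.na(end) | start < 0 | start >= end)) {
    bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)[1]
    stop(sprintf("invalid interval at record %d: need 0 <= start < end", bad),
         call. = FALSE)
  }
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- as.character(rep_len(name, n))
  if (!is.null(score)) out$score <- as.numeric(rep_len(score, n))
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Construct a fixed-width bin grid
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param bin_size bin width in bp (default 200, the bin granularity used
#'   for state analysis).
#' @return an object of class `bin_grid` with fields `bin_size`,
#'   `chrom_lengths`, and `n_bins` (bins per chromosome,
#'   `ceiling(length / bin_size)`; the last bin may be short).
#' @export
bin_grid <- function(chrom_lengths, bin_size = 200L) {
  if (length(bin_size) != 1L || is.na(bin_size) || bin_size <= 0) {
    stop("bin_size must be a positive integer", call. = FALSE)
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector", call. = FALSE)
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive",
                                    call. = FALSE)
  structure(list(
    bin_size = as.integer(bin_size),
    chrom_lengths = chrom_lengths,
    n_bins = setNames(as.integer(ceiling(chrom_lengths / bin_size)),
                      names(chrom_lengths))
  ), class = "bin_grid")
}

#' Bin index of a genomic position
#'
#' @param pos 0-based position(s).
#' @param grid a [bin_grid()].
#' @return 0-based bin index `floor(pos / bin_size)`.
#' @export
bin_index <- function(pos, grid) as.integer(floor(pos / grid$bin_size))

#' Construct a binned signal track
#'
#' @param grid a [bin_grid()].
#' @param values named list, chromosome -> numeric vector of per-bin values
#'   (length must equal the grid's bin count for that chromosome).
#' @param sample_id,mark identifying strings.
#' @return object of class `binned_track`.
#' @export
binned_track <- function(grid, values, sample_id = "", mark = "") {
  stopifnot(inherits(grid, "bin_grid"))
  chroms <- names(grid$n_bins)
  if (!setequal(names(values), chroms)) {
    stop("track chromosomes do not match grid", call. = FALSE)
  }
  values <- values[chroms]
  for (ch in chroms) {
    if (length(values[[ch]]) != grid$n_bins[[ch]]) {
      stop(sprintf("track length on %s (%d) != grid bins (%d)", ch,
                   length(values[[ch]]), grid$n_bins[[ch]]), call. = FALSE)
    }
    if (any(values[[ch]] < 0)) stop("track values must be >= 0", call. = FALSE)
  }
  structure(list(grid = grid, values = values, sample_id = sample_id,
                 mark = mark), class = "binned_track")
}

#' Read a BED file
#'
#' BED is 0-based half-open; coordinates are preserved exactly. Optional
#' name/score/strand columns (4-6) are captured when present.
#'
#' @param path path to a tab-separated BED file (>= 3 columns).
#' @return a `genomic_intervals` data frame in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which(nf < 3L)[1]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 bad[1]), call. = FALSE)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: start >= end", bad[1]),
         call. = FALSE)
  }
  name <- if (any(nf >= 4L)) {
    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else ".", "")
  }
  score <- if (any(nf >= 5L)) {
    suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", "")))
  }
  strand <- if (any(nf >= 6L)) {
    vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", "")
  } else "."
  genomic_intervals(chrom, start, end, strand, name = name, score = score)
}

#' Write intervals (optionally labeled segments) as BED
#'
#' Labeled segments (a `name` column, e.g. "1_TSS Active") are emitted in
#' the BED name field; output round-trips through [read_bed()].
#'
#' @param intervals a `genomic_intervals` data frame (or any data frame
#'   with chrom/start/end and optional name/score/strand columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom,
               format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    if (!is.null(intervals$score)) {
      cols <- c(cols, list(intervals$score))
      if (!is.null(intervals$strand) && any(intervals$strand != ".")) {
        cols <- c(cols, list(intervals$strand))
      }
    } else if (!is.null(intervals$strand) && any(intervals$strand != ".")) {
      cols <- c(cols, list(rep(0L, nrow(intervals)), intervals$strand))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Consumes `gene` and `exon` features; 1-based closed GTF coordinates are
#' converted to 0-based half-open (`start - 1`, `end`). The TSS is the
#' strand-dependent 5' end of the gene span: `start` for "+" genes,
#' `end - 1` for "-" genes (unstranded features are treated as "+" where a
#' strand is required).
#'
#' @param path path to a GTF file.
#' @return object of class `gene_models`: a data frame with one row per
#'   gene (`gene_id`, `chrom`, `start`, `end`, `strand`, `tss`, `tes`) and
#'   an `exons` list-column of per-gene exon data frames (sorted,
#'   non-overlapping).
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_gene_models())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop(sprintf("GTF parse error at line %d: fewer than 9 columns",
                 lineno[which(nf < 9L)[1]]), call. = FALSE)
  }
  feat <- vapply(fields, `[[`, "", 3L)
  sel <- feat %in% c("gene", "exon")
  fields <- fields[sel]
  lineno <- lineno[sel]
  feat <- feat[sel]
  attrs <- vapply(fields, `[[`, "", 9L)
  gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", attrs)
  missing_gid <- !grepl("gene_id", attrs)
  if (any(missing_gid)) {
    stop(sprintf("GTF parse error at line %d: missing gene_id attribute",
                 lineno[which(missing_gid)[1]]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (any(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)) {
    bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)[1]
    stop(sprintf("GTF parse error at line %d: bad coordinates", lineno[bad]),
         call. = FALSE)
  }
  strand <- vapply(fields, `[[`, "", 7L)
  start0 <- start1 - 1
  end0 <- end1
  is_gene <- feat == "gene"
  gene_rows <- which(is_gene)
  if (length(gene_rows) == 0L) {
    stop("GTF contains no gene features", call. = FALSE)
  }
  gm <- data.frame(gene_id = gid[gene_rows], chrom = chrom[gene_rows],
                   start = start0[gene_rows], end = end0[gene_rows],
                   strand = strand[gene_rows], stringsAsFactors = FALSE)
  if (anyDuplicated(gm$gene_id)) {
    stop("duplicated gene_id in GTF gene features", call. = FALSE)
  }
  gm$tss <- ifelse(gm$strand == "-", gm$end - 1, gm$start)
  gm$tes <- ifelse(gm$strand == "-", gm$start, gm$end - 1)
  exon_rows <- which(!is_gene)
  exons <- vector("list", nrow(gm))
  names(exons) <- gm$gene_id
  if (length(exon_rows)) {
    ex <- data.frame(gene_id = gid[exon_rows], start = start0[exon_rows],
                     end = end0[exon_rows], line = lineno[exon_rows],
                     stringsAsFactors = FALSE)
    idx <- match(ex$gene_id, gm$gene_id)
    if (anyNA(idx)) {
      stop(sprintf("GTF validation error at line %d: exon for unknown gene_id",
                   ex$line[which(is.na(idx))[1]]), call. = FALSE)
    }
    out_of_span <- ex$start < gm$start[idx] | ex$end > gm$end[idx]
    if (any(out_of_span)) {
      stop(sprintf("GTF validation error at line %d: exon outside gene span",
                   ex$line[which(out_of_span)[1]]), call. = FALSE)
    }
    for (g in unique(ex$gene_id)) {
      e <- ex[ex$gene_id == g, c("start", "end")]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
        stop(sprintf("GTF validation error: overlapping exons for gene %s", g),
             call. = FALSE)
      }
      rownames(e) <- NULL
      exons[[g]] <- e
    }
  }
  gm$exons <- I(unname(exons[gm$gene_id]))
  class(gm) <- c("gene_models", "data.frame")
  gm
}

empty_gene_models <- function() {
  gm <- data.frame(gene_id = character(), chrom = character(),
                   start = numeric(), end = numeric(), strand = character(),
                   tss = numeric(), tes = numeric(), stringsAsFactors = FALSE)
  gm$exons <- I(list())
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' Write gene models as GTF
#'
#' Emits `gene` and `exon` features, converting back to 1-based closed
#' coordinates so that a read/write cycle recovers the original values.
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @param source source field (column 2).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "broadstates") {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    attr <- sprintf('gene_id "%s";', genes$gene_id[i])
    lines <- c(lines, paste(genes$chrom[i], source, "gene",
                            format(genes$start[i] + 1, scientific = FALSE),
                            format(genes$end[i], scientific = FALSE),
                            ".", genes$strand[i], ".", attr, sep = "\t"))
    ex <- genes$exons[[i]]
    if (!is.null(ex) && nrow(ex)) {
      for (j in seq_len(nrow(ex))) {
        lines <- c(lines, paste(genes$chrom[i], source, "exon",
                                format(ex$start[j] + 1, scientific = FALSE),
                                format(ex$end[j], scientific = FALSE),
                                ".", genes$strand[i], ".", attr, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-bin count track (bedGraph or bin-indexed TSV)
#'
#' bedGraph records must align exactly to grid bin boundaries (a record may
#' span several whole bins); bins absent from the file are 0. A TSV
#' alternative with header columns `chrom`, `bin`, `value` (0-based bin
#' index) is also accepted.
#'
#' @param path path to the file.
#' @param grid a [bin_grid()].
#' @param sample_id,mark identifying strings attached to the track.
#' @return a [binned_track()].
#' @export
read_track <- function(path, grid, sample_id = "", mark = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- lapply(grid$n_bins, numeric)
  first <- readLines(path, n = 1L)
  is_tsv <- length(first) && grepl("^chrom\tbin\tvalue", first)
  if (is_tsv) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    for (ch in unique(tab$chrom)) {
      if (!ch %in% names(vals)) stop("unknown chromosome in track: ", ch,
                                     call. = FALSE)
      sub <- tab[tab$chrom == ch, ]
      if (any(sub$bin < 0 | sub$bin >= grid$n_bins[[ch]])) {
        stop("bin index out of range on ", ch, call. = FALSE)
      }
      vals[[ch]][sub$bin + 1L] <- sub$value
    }
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
    if (length(lines)) {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(fields) < 4L)) {
        stop(sprintf("bedGraph parse error at line %d: need 4 columns",
                     which(lengths(fields) < 4L)[1]), call. = FALSE)
      }
      chrom <- vapply(fields, `[[`, "", 1L)
      start <- as.numeric(vapply(fields, `[[`, "", 2L))
      end <- as.numeric(vapply(fields, `[[`, "", 3L))
      value <- as.numeric(vapply(fields, `[[`, "", 4L))
      bs <- grid$bin_size
      chr_len <- grid$chrom_lengths
      cross <- (start %% bs != 0) |
        (end %% bs != 0 & end != chr_len[chrom])
      if (anyNA(cross) || any(cross)) {
        bad <- which(is.na(cross) | cross)[1]
        stop(sprintf(paste0("bedGraph record at line %d does not align to ",
                            "%d-bp bin boundaries; re-bin the input to the ",
                            "analysis grid first"), bad, bs), call. = FALSE)
      }
      for (i in seq_along(chrom)) {
        ch <- chrom[i]
        if (!ch %in% names(vals)) stop("unknown chromosome in track: ", ch,
                                       call. = FALSE)
        b0 <- start[i] %/% bs
        b1 <- ceiling(end[i] / bs) - 1
        vals[[ch]][(b0:b1) + 1L] <- value[i]
      }
    }
  }
  binned_track(grid, vals, sample_id = sample_id, mark = mark)
}

#' Write a binned track as bedGraph
#'
#' Emits one record per bin with a non-zero value (zero bins are implicit),
#' so output round-trips through [read_track()].
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  grid <- track$grid
  bs <- grid$bin_size
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    start <- (nz - 1L) * bs
    end <- pmin(start + bs, grid$chrom_lengths[[ch]])
    writeLines(paste(ch, format(start, scientific = FALSE, trim = TRUE),
                     format(end, scientific = FALSE, trim = TRUE),
                     format(v[nz], scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}
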