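# Bernoulli-emission hidden Markov model: model container, likelihood,
# Baum-Welch learning with restarts, and posterior/Viterbi decoding.

#' Construct (and validate) an HMM
#'
#' @param pi initial state distribution (length K, sums to 1).
#' @param A K x K row-stochastic transition matrix.
#' @param E K x M emission matrix; `E[k, m]` is the probability that mark
#'   `m` is observed (binarized 1) in a bin of state `k`.
#' @param marks mark names (length M).
#' @return list of class `hmm_model` with fields `K`, `marks`, `pi`, `A`,
#'   `E`.
#' @export
hmm_model <- function(pi, A, E, marks = colnames(E)) {
  E <- as.matrix(E)
  A <- as.matrix(A)
  K <- length(pi)
  if (nrow(A) != K || ncol(A) != K || nrow(E) != K) {
    stop("dimension mismatch between pi, A and E", call. = FALSE)
  }
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1", call. = FALSE)
  if (any(abs(rowSums(A) - 1) > 1e-9)) {
    stop("transition rows must sum to 1", call. = FALSE)
  }
  if (any(E < 0 | E > 1)) stop("emission entries must lie in [0,1]",
                               call. = FALSE)
  if (is.null(marks)) marks <- paste0("mark", seq_len(ncol(E)))
  colnames(E) <- marks
  structure(list(K = K, marks = marks, pi = as.numeric(pi), A = A, E = E),
            class = "hmm_model")
}

#' Bernoulli product emission probability
#'
#' `prod_m E[m]^obs[m] * (1 - E[m])^(1 - obs[m])`, evaluated in log space
#' (degenerate probabilities 0/1 are handled exactly).
#'
#' @param E_row emission probabilities for one state (length M).
#' @param obs 0/1 observation vector (length M).
#' @return the emission probability.
#' @export
emission_prob <- function(E_row, obs) {
  if (length(E_row) != length(obs)) stop("length mismatch", call. = FALSE)
  if (!all(obs %in% c(0, 1))) stop("observations must be 0/1",
                                   call. = FALSE)
  on_zero <- obs == 1 & E_row == 0
  off_one <- obs == 0 & E_row == 1
  if (any(on_zero | off_one)) return(0)
  lp <- sum(log(E_row[obs == 1])) + sum(log1p(-E_row[obs == 0]))
  exp(lp)
}

# coerce a binary_matrix (or list of them) to a list of per-sequence
# integer matrices, recording provenance for decoding
as_obs_list <- function(binary, marks = NULL) {
  if (inherits(binary, "binary_matrix")) binary <- list(binary)
  obs <- list()
  meta <- list()
  for (bm in binary) {
    if (!inherits(bm, "binary_matrix")) {
      stop("expected binary_matrix input", call. = FALSE)
    }
    if (!is.null(marks) && !identical(bm$marks, marks)) {
      stop("mark order mismatch between model and binary matrix",
           call. = FALSE)
    }
    for (ch in names(bm$calls)) {
      obs[[length(obs) + 1L]] <- bm$calls[[ch]]
      meta[[length(meta) + 1L]] <- list(cell_type = bm$cell_type,
                                        chrom = ch, grid = bm$grid)
    }
  }
  list(obs = obs, meta = meta)
}

#' Log-likelihood of binary observations under an HMM
#'
#' Scaled forward recursion; sequences (chromosomes) are independent and
#' transitions do not cross their boundaries.
#'
#' @param model an [hmm_model()].
#' @param obs a T x M 0/1 matrix, a list of such matrices, or a
#'   `binary_matrix`.
#' @return `log P(obs | model)`; `-Inf` for a probability-zero sequence.
#' @export
forward_loglik <- function(model, obs) {
  obs_list <- coerce_obs(model, obs)
  cpp_forward_loglik(obs_list, model$pi, model$A, model$E)
}

coerce_obs <- function(model, obs) {
  if (inherits(obs, "binary_matrix")) {
    obs <- as_obs_list(obs, marks = model$marks)$obs
  } else if (is.matrix(obs)) {
    obs <- list(obs)
  }
  lapply(obs, function(o) {
    o <- as.matrix(o)
    if (ncol(o) != ncol(model$E)) {
      stop("observation columns do not match model marks", call. = FALSE)
    }
    if (!all(o %in% c(0L, 1L))) stop("observations must be 0/1",
                                     call. = FALSE)
    storage.mode(o) <- "integer"
    o
  })
}

# spec'd initialization: emissions = overall mark frequencies with uniform
# jitter, clipped; transitions 0.9 self / uniform off-diagonal; pi uniform
init_hmm <- function(obs_list, K, marks) {
  all_obs <- do.call(rbind, obs_list)
  freq <- colMeans(all_obs)
  M <- length(freq)
  E <- matrix(rep(freq, each = K), nrow = K) +
    matrix(runif(K * M, -0.1, 0.1), nrow = K)
  E <- pmin(pmax(E, 0.01), 0.99)
  colnames(E) <- marks
  A <- matrix((1 - 0.9) / (K - 1), K, K)
  diag(A) <- 0.9
  hmm_model(rep(1 / K, K), A, E, marks)
}

#' Learn an HMM by Baum-Welch EM
#'
#' Fits a K-state Bernoulli-emission HMM to binarized bins (per-chromosome
#' sequences; multiple cell types may be concatenated so that one shared
#' model is learned). EM is run from `n_restarts` jittered initializations
#' and the fit with the best final log-likelihood is kept. States are then
#' re-indexed 1..K in descending H3K4me3 emission (ties by H3K27ac) so that
#' "state 1/2" labels are stable across runs.
#'
#' @param binary a `binary_matrix` or list of them.
#' @param K number of states (default 10; must be >= 2).
#' @param seed RNG seed for initialization.
#' @param max_iter,rel_tol EM stopping rule (relative log-likelihood
#'   change).
#' @param n_restarts number of jittered restarts.
#' @param prob_floor floor applied to transition/emission probabilities for
#'   numerical stability.
#' @return an `hmm_model` with extra fields `loglik` and `loglik_trace`.
#' @export
learn_model <- function(binary, K = 10L, seed = 1L, max_iter = 200L,
                        rel_tol = 1e-4, n_restarts = 3L,
                        prob_floor = 1e-6) {
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  parts <- as_obs_list(binary)
  obs_list <- lapply(parts$obs, function(o) {
    storage.mode(o) <- "integer"; o
  })
  marks <- if (inherits(binary, "binary_matrix")) binary$marks
           else binary[[1]]$marks
  all_obs <- do.call(rbind, obs_list)
  n_distinct <- nrow(unique(all_obs))
  if (n_distinct == 1L) {
    warning("all observation rows are identical; ",
            "a single state will dominate the fitted model")
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- init_hmm(obs_list, K, marks)
      fit <- cpp_baum_welch(obs_list, init$pi, init$A, init$E,
                            as.integer(max_iter), rel_tol, prob_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  model <- hmm_model(best$pi, best$A, best$E, marks)
  model <- reorder_states(model)
  model$loglik <- best$loglik
  model$loglik_trace <- best$loglik_trace
  model
}

# re-index states by descending H3K4me3 emission (ties by H3K27ac); falls
# back to the first two marks when those names are absent
reorder_states <- function(model) {
  primary <- if ("H3K4me3" %in% model$marks) "H3K4me3" else model$marks[1]
  secondary <- if ("H3K27ac" %in% model$marks) "H3K27ac"
               else model$marks[min(2L, length(model$marks))]
  ord <- order(-model$E[, primary], -model$E[, secondary])
  hmm_perm(model, ord)
}

hmm_perm <- function(model, ord) {
  out <- hmm_model(model$pi[ord], model$A[ord, ord, drop = FALSE],
                   model$E[ord, , drop = FALSE], model$marks)
  out$loglik <- model$loglik
  out$loglik_trace <- model$loglik_trace
  out
}

#' Decode binarized bins into a chromatin-state segmentation
#'
#' Per-bin states are assigned either by the maximum-posterior rule
#' (default) or by the Viterbi path; consecutive same-state bins are merged
#' into segments.
#'
#' @param model an [hmm_model()].
#' @param binary a `binary_matrix` whose marks match the model.
#' @param mode `"posterior"` or `"viterbi"`.
#' @return object of class `segmentation`: a data frame of segments
#'   (`chrom`, `start`, `end`, `state`), with attributes `state_path`
#'   (per-chrom integer vectors), `grid`, `cell_type`, `K`, and (posterior
#'   mode) `posterior` — per-chrom bins x K matrices.
#' @export
decode <- function(model, binary, mode = c("posterior", "viterbi")) {
  mode <- match.arg(mode)
  if (!identical(binary$marks, model$marks)) {
    stop("mark order mismatch between model and binary matrix",
         call. = FALSE)
  }
  parts <- as_obs_list(binary, marks = model$marks)
  obs_list <- parts$obs
  posterior <- NULL
  if (mode == "posterior") {
    posterior <- cpp_posterior(obs_list, model$pi, model$A, model$E)
    paths <- lapply(posterior, function(g) max.col(g, ties.method = "first"))
  } else {
    paths <- cpp_viterbi(obs_list, model$pi, model$A, model$E)
  }
  chroms <- vapply(parts$meta, `[[`, "", "chrom")
  names(paths) <- chroms
  if (!is.null(posterior)) names(posterior) <- chroms
  grid <- binary$grid
  segs <- list()
  for (i in seq_along(paths)) {
    ch <- chroms[i]
    p <- paths[[i]]
    if (!length(p)) next
    r <- rle(p)
    endbin <- cumsum(r$lengths)
    startbin <- endbin - r$lengths
    segs[[ch]] <- data.frame(
      chrom = ch,
      start = startbin * grid$bin_size,
      end = pmin(endbin * grid$bin_size, grid$chrom_lengths[[ch]]),
      state = r$values, stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, segs)
  rownames(seg) <- NULL
  structure(seg, class = c("segmentation", "data.frame"),
            state_path = paths, posterior = posterior, grid = grid,
            cell_type = binary$cell_type, K = model$K)
}

#' Write an HMM as tab-separated text blocks
#'
#' Layout mirrors ChromHMM's model text: `initial`, `transition` and
#' `emission` blocks with state and mark headers.
#'
#' @param model an [hmm_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("K\t%d", model$K), con)
  writeLines(paste0("initial\t",
                    paste(format(model$pi, digits = 10), collapse = "\t")),
             con)
  for (i in seq_len(model$K)) {
    writeLines(paste0("transition\t", i, "\t",
                      paste(format(model$A[i, ], digits = 10),
                            collapse = "\t")), con)
  }
  writeLines(paste0("marks\t", paste(model$marks, collapse = "\t")), con)
  for (i in seq_len(model$K)) {
    writeLines(paste0("emission\t", i, "\t",
                      paste(format(model$E[i, ], digits = 10),
                            collapse = "\t")), con)
  }
  invisible(path)
}

#' Read an HMM written by [write_hmm_model()]
#'
#' @param path model file.
#' @return an `hmm_model`.
#' @export
read_hmm_model <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  tag <- vapply(lines, `[[`, "", 1L)
  K <- as.integer(lines[[which(tag == "K")]][2])
  pi <- as.numeric(lines[[which(tag == "initial")]][-1])
  marks <- lines[[which(tag == "marks")]][-1]
  A <- matrix(0, K, K)
  for (l in lines[tag == "transition"]) {
    A[as.integer(l[2]), ] <- as.numeric(l[-(1:2)])
  }
  E <- matrix(0, K, length(marks))
  for (l in lines[tag == "emission"]) {
    E[as.integer(l[2]), ] <- as.numeric(l[-(1:2)])
  }
  hmm_model(pi, A, E, marks)
}

#' Write a segmentation as a labeled BED file
#'
#' Segment names are `state` or `state_label` when labels are supplied.
#'
#' @param seg a [decode()] segmentation.
#' @param path output path.
#' @param labels optional data frame (`state`, `label`) from
#'   [label_states()].
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path, labels = NULL) {
  name <- as.character(seg$state)
  if (!is.null(labels)) {
    lab <- labels$label[match(seg$state, labels$state)]
    name <- paste(seg$state, lab, sep = "_")
  }
  df <- genomic_intervals(seg$chrom, seg$start, seg$end, ".", name = name)
  write_bed(df, path)
}
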