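# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own computational
# paths.

# log P(obs | model) by exhaustive enumeration of all K^T state paths
enum_loglik <- function(pi, A, E, obs) {
  K <- length(pi)
  T_ <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- as.integer(paths[r, ])
    p <- pi[s[1]]
    if (T_ > 1) for (t in 2:T_) p <- p * A[s[t - 1], s[t]]
    for (t in seq_len(T_)) {
      e <- E[s[t], ]
      p <- p * prod(ifelse(obs[t, ] == 1, e, 1 - e))
    }
    total <- total + p
  }
  log(total)
}

# joint log-probability of one explicit state path
path_loglik <- function(pi, A, E, obs, states) {
  lp <- log(pi[states[1]])
  T_ <- nrow(obs)
  if (T_ > 1) for (t in 2:T_) lp <- lp + log(A[states[t - 1], states[t]])
  for (t in seq_len(T_)) {
    e <- E[states[t], ]
    lp <- lp + sum(log(ifelse(obs[t, ] == 1, e, 1 - e)))
  }
  lp
}

# random row-stochastic matrix
rand_stochastic <- function(n, m = n) {
  x <- matrix(runif(n * m, 0.05, 1), n, m)
  x / rowSums(x)
}

rand_hmm <- function(K, M) {
  list(pi = as.numeric(rand_stochastic(1, K)),
       A = rand_stochastic(K),
       E = matrix(runif(K * M, 0.05, 0.95), K, M))
}

# sample observations from a known Bernoulli HMM
sample_hmm_obs <- function(pi, A, E, T_) {
  K <- length(pi)
  M <- ncol(E)
  states <- integer(T_)
  states[1] <- sample(K, 1, prob = pi)
  for (t in 2:T_) states[t] <- sample(K, 1, prob = A[states[t - 1], ])
  obs <- matrix(0L, T_, M)
  for (t in seq_len(T_)) {
    obs[t, ] <- as.integer(runif(M) < E[states[t], ])
  }
  list(states = states, obs = obs)
}

# smallest x with P(Poisson(lambda) >= x) <= p, by direct pmf summation
poisson_threshold_bruteforce <- function(lambda, p) {
  x <- 0L
  repeat {
    tail_mass <- sum(dpois(x:(x + ceiling(20 * (lambda + 10))), lambda))
    if (tail_mass <= p) return(x)
    x <- x + 1L
  }
}

# hypergeometric upper tail by log-choose summation
fisher_upper_bruteforce <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k == 0) return(1)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# quadratic all-pairs half-open overlap scan
intersect_bruteforce <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          b$start[j] < a$end[i]) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(pairs)) {
    return(data.frame(a_idx = integer(), b_idx = integer()))
  }
  m <- do.call(rbind, pairs)
  df <- data.frame(a_idx = m[, 1], b_idx = m[, 2])
  df <- df[order(df$a_idx, df$b_idx), ]
  rownames(df) <- NULL
  df
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  start <- sample(0:(max_pos - 2), n, replace = TRUE)
  len <- sample(1:500, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len)
}

# a segmentation object built by hand (bypasses decode)
make_segmentation <- function(df, chrom_lengths, bin_size = 200) {
  grid <- bin_grid(chrom_lengths, bin_size)
  structure(df, class = c("segmentation", "data.frame"), grid = grid,
            K = max(df$state))
}

# small study configuration shared by module tests
small_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_length = 4e5,
             n_genes = 30L, ...)
}
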