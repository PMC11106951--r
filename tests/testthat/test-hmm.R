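test_that("emission probabilities are Bernoulli products, including
           degenerate 0/1 entries", {
  expect_equal(emission_prob(c(0.5, 0.5), c(1, 0)), 0.25)
  expect_equal(emission_prob(c(0.8, 0.2), c(1, 1)), 0.16)
  expect_equal(emission_prob(c(1.0, 0.5), c(0, 1)), 0)
  expect_equal(emission_prob(c(1.0, 0.5), c(1, 1)), 0.5)
  expect_error(emission_prob(c(0.5), c(2)), "0/1")
})

test_that("forward log-likelihood matches path enumeration on the worked
           two-state example", {
  m <- hmm_model(c(0.5, 0.5),
                 rbind(c(0.9, 0.1), c(0.1, 0.9)),
                 matrix(c(0.8, 0.2), ncol = 1), marks = "m")
  obs <- matrix(c(1L, 1L), ncol = 1)
  ll <- forward_loglik(m, obs)
  expect_equal(exp(ll), 0.322, tolerance = 1e-3)
  expect_equal(ll, enum_loglik(m$pi, m$A, m$E, obs), tolerance = 1e-12)
  # T = 1 degenerate case
  m1 <- hmm_model(c(1, 0), rbind(c(0.9, 0.1), c(0.1, 0.9)),
                  matrix(c(0.8, 0.2), ncol = 1), marks = "m")
  expect_equal(exp(forward_loglik(m1, matrix(1L, 1, 1))), 0.8)
})

test_that("forward log-likelihood agrees with enumeration on random
           instances", {
  withr::with_seed(42, {
    for (i in 1:40) {
      K <- sample(2:3, 1); M <- sample(1:3, 1); T_ <- sample(2:8, 1)
      h <- rand_hmm(K, M)
      obs <- matrix(rbinom(T_ * M, 1, 0.5), T_, M)
      m <- hmm_model(h$pi, h$A, h$E)
      expect_lt(abs(forward_loglik(m, obs) -
                      enum_loglik(h$pi, h$A, h$E, obs)), 1e-10)
    }
  })
})

test_that("EM increases the likelihood monotonically and is seed-
           deterministic", {
  withr::with_seed(7, {
    h <- rand_hmm(3, 2)
    obs <- sample_hmm_obs(h$pi, h$A, h$E, 2000)$obs
  })
  bmx <- structure(list(grid = bin_grid(c(chr1 = 2000 * 200), 200),
                        marks = c("a", "b"), cell_type = "x",
                        calls = list(chr1 = obs)),
                   class = "binary_matrix")
  m1 <- learn_model(bmx, K = 3, seed = 5, n_restarts = 2)
  m2 <- learn_model(bmx, K = 3, seed = 5, n_restarts = 2)
  expect_identical(m1$E, m2$E)
  expect_identical(m1$A, m2$A)
  trace <- m1$loglik_trace
  expect_true(all(diff(trace) >= -1e-8 * abs(trace[-length(trace)])))
  expect_error(learn_model(bmx, K = 1), "at least 2")
})

test_that("EM recovers the generating parameters of a separated 3-state
           model", {
  A_true <- rbind(c(0.95, 0.03, 0.02),
                  c(0.04, 0.92, 0.04),
                  c(0.02, 0.03, 0.95))
  E_true <- rbind(c(0.95, 0.85, 0.05, 0.05),
                  c(0.05, 0.05, 0.90, 0.10),
                  c(0.03, 0.05, 0.05, 0.03))
  withr::with_seed(99, {
    sim <- sample_hmm_obs(rep(1/3, 3), A_true, E_true, 20000)
  })
  bmx <- structure(list(grid = bin_grid(c(chr1 = 20000 * 200), 200),
                        marks = paste0("m", 1:4), cell_type = "x",
                        calls = list(chr1 = sim$obs)),
                   class = "binary_matrix")
  fit <- learn_model(bmx, K = 3, seed = 3, n_restarts = 3)
  # match learned states to truth by emission distance
  perm <- unname(apply(as.matrix(
    stats::dist(rbind(fit$E, E_true)))[1:3, 4:6], 2, which.min))
  expect_equal(sort(perm), 1:3)
  expect_lt(max(abs(fit$E[perm, ] - E_true)), 0.05)
  expect_lt(max(abs(diag(fit$A[perm, perm]) - diag(A_true))), 0.03)
})

test_that("decoding merges runs, posteriors are proper, and Viterbi beats
           random paths", {
  # deterministic emissions: obs directly reveal the state
  m <- hmm_model(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)),
                 matrix(c(0.999, 0.001), ncol = 1), marks = "m")
  bmx <- structure(list(grid = bin_grid(c(chr1 = 800), 200),
                        marks = "m", cell_type = "x",
                        calls = list(chr1 = matrix(c(1L, 1L, 0L, 0L)))),
                   class = "binary_matrix")
  seg <- decode(m, bmx, mode = "viterbi")
  expect_equal(seg$state, c(1L, 2L))
  expect_equal(seg$start, c(0, 400))
  expect_equal(seg$end, c(400, 800))
  segp <- decode(m, bmx, mode = "posterior")
  expect_equal(attr(segp, "state_path")$chr1, c(1L, 1L, 2L, 2L))
  post <- attr(segp, "posterior")$chr1
  expect_equal(rowSums(post), rep(1, 4))
  # Viterbi optimality against random paths
  withr::with_seed(11, {
    h <- rand_hmm(3, 2)
    obs <- matrix(rbinom(40, 1, 0.5), 20, 2)
    bm2 <- structure(list(grid = bin_grid(c(chr1 = 20 * 200), 200),
                          marks = c("a", "b"), cell_type = "x",
                          calls = list(chr1 = obs)),
                     class = "binary_matrix")
    hm <- hmm_model(h$pi, h$A, h$E, c("a", "b"))
    vit <- attr(decode(hm, bm2, mode = "viterbi"), "state_path")$chr1
    lv <- path_loglik(h$pi, h$A, h$E, obs, vit)
    for (i in 1:200) {
      rnd <- sample(3, 20, replace = TRUE)
      expect_gte(lv, path_loglik(h$pi, h$A, h$E, obs, rnd))
    }
  })
})

test_that("segmentation tiles the binned genome without overlap", {
  cfg <- small_config()
  study <- simulate_study(cfg)
  bm <- binarize(list(
    H3K4me3 = lapply(study$tracks$PFF_like, `[[`, "H3K4me3"),
    H3K27me3 = lapply(study$tracks$PFF_like, `[[`, "H3K27me3")),
    cell_type = "PFF_like")
  model <- learn_model(bm, K = 3, seed = 2, n_restarts = 1)
  seg <- decode(model, bm)
  expect_equal(sum(seg$end - seg$start), sum(study$grid$chrom_lengths))
  for (ch in unique(seg$chrom)) {
    sub <- seg[seg$chrom == ch, ]
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
    expect_true(all(sub$state[-1] != sub$state[-nrow(sub)]))
  }
})

test_that("states are re-indexed by H3K4me3 emission and the model
           round-trips through its text serialization", {
  E <- rbind(c(0.1, 0.9, 0.1), c(0.9, 0.8, 0.1), c(0.5, 0.2, 0.9))
  colnames(E) <- c("H3K4me3", "H3K27ac", "H3K27me3")
  m <- hmm_model(c(0.2, 0.3, 0.5), rand_stochastic(3), E)
  r <- broadstates:::reorder_states(m)
  expect_equal(r$E[, "H3K4me3"], sort(E[, "H3K4me3"], decreasing = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hmm_model(r, path)
  back <- read_hmm_model(path)
  expect_equal(back$E, r$E, tolerance = 1e-8)
  expect_equal(back$A, r$A, tolerance = 1e-8)
  expect_equal(back$pi, r$pi, tolerance = 1e-8)
  expect_equal(back$marks, r$marks)
})
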