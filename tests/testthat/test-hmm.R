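test_that("forward log-likelihood equals brute-force path enumeration", {
  set.seed(101)
  for (rep in 1:10) {
    K <- sample(2:3, 1); D <- sample(1:2, 1); T_ <- sample(3:6, 1)
    m <- random_hmm(K, D)
    x <- matrix(rnorm(T_ * D, sd = 2), T_, D)
    expect_equal(hmm_loglik(m, x),
                 enum_loglik(x, m$means, m$variances, m$A, m$pi),
                 tolerance = 1e-10)
  }
})

test_that("Viterbi path beats every enumerated path and breaks ties low", {
  set.seed(102)
  for (rep in 1:8) {
    K <- 2; T_ <- sample(4:8, 1)
    m <- random_hmm(K, 1)
    x <- matrix(rnorm(T_, sd = 2), T_, 1)
    ld <- celltrax:::hmm_logdens(x, m)
    v <- celltrax:::hmm_viterbi_cpp(ld, m$A, m$pi)
    paths <- as.matrix(expand.grid(rep(list(1:K), T_)))
    lps <- apply(paths, 1, function(st)
      path_logprob(x, as.integer(st), m$means, m$variances, m$A, m$pi))
    expect_equal(v$logprob, max(lps), tolerance = 1e-10)
    expect_true(all(v$logprob >= lps - 1e-10))
  }
})

test_that("EM recovers the generating 2-state parameters", {
  truth <- hmm_model(means = matrix(c(-2, 2), 2, 1),
                     variances = matrix(0.25, 2, 1),
                     A = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
                     pi = c(0.5, 0.5), feature_names = "speed")
  sim <- simulate_hmm_sequences(truth, n_seqs = 200, length = 100, seed = 7)
  fit <- fit_hmm(sim$sequences, features = "speed", K = 2, n_restarts = 3, seed = 7)
  # means reported on the fit's z-scored scale: map back through the scaling
  means_raw <- fit$scaling$mean + fit$means[, 1] * fit$scaling$sd
  expect_equal(means_raw, c(-2, 2), tolerance = 0.1 / 2)  # +-0.1 absolute
  expect_true(all(abs(fit$A - truth$A) < 0.05))
  expect_true(fit$converged)
})

test_that("K = 1 reduces to sample moments, with a warning", {
  set.seed(104)
  steps <- tibble::tibble(track_id = rep(1:5, each = 20),
                          speed = rnorm(100, 3, 1.2))
  expect_warning(fit <- fit_hmm(steps, features = "speed", K = 1, n_restarts = 1,
                                seed = 1), "degenerate")
  mu_raw <- unname(fit$scaling$mean + fit$means[1, 1] * fit$scaling$sd)
  expect_equal(mu_raw, mean(steps$speed), tolerance = 1e-6)
  sd_raw <- unname(sqrt(fit$variances[1, 1]) * fit$scaling$sd)
  # EM variance is the population variance of the pooled sample
  expect_equal(sd_raw, sqrt(mean((steps$speed - mean(steps$speed))^2)),
               tolerance = 1e-3)
})

test_that("decoding is near-perfect for well-separated emissions", {
  truth <- hmm_model(means = matrix(c(-5, 5), 2, 1),
                     variances = matrix(0.01, 2, 1),
                     A = matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2, byrow = TRUE),
                     pi = c(0.5, 0.5), feature_names = "f")
  sim <- simulate_hmm_sequences(truth, n_seqs = 30, length = 50, seed = 9)
  ann <- decode_states(truth, sim$sequences)
  j <- dplyr::inner_join(ann$states, sim$states, by = c("track_id", "frame"))
  expect_gt(mean(j$hmm_state == j$state), 0.99)
})

test_that("occupancy and transition frequencies follow the counting contract", {
  # a fixed model and a sequence engineered to decode as 1,1,2,2
  m <- hmm_model(means = matrix(c(0, 10), 2, 1), variances = matrix(0.1, 2, 1),
                 A = matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, byrow = TRUE),
                 pi = c(0.9, 0.1), feature_names = "f")
  steps <- tibble::tibble(track_id = 1, frame = 1:4, f = c(0, 0, 10, 10))
  ann <- decode_states(m, steps)
  expect_equal(ann$states$hmm_state, c(1, 1, 2, 2))
  expect_equal(unlist(ann$occupancy[1, c("occ_1", "occ_2")], use.names = FALSE),
               c(0.5, 0.5))
  expect_equal(ann$transitions$trans_1_2, 1 / 3)
  expect_equal(ann$transitions$trans_1_1, 1 / 3)
  expect_equal(ann$transitions$trans_2_2, 1 / 3)
  expect_equal(ann$transitions$trans_2_1, 0)
})

test_that("occupancy and transition masses each sum to one per track", {
  truth <- random_hmm(3, 2)
  truth$feature_names <- c("speed", "turning_angle")
  sim <- simulate_hmm_sequences(truth, n_seqs = 40, length = 30, seed = 10)
  ann <- decode_states(truth, sim$sequences)
  occ_sums <- rowSums(ann$occupancy[-1])
  expect_equal(occ_sums, rep(1, nrow(ann$occupancy)), tolerance = 1e-12)
  tr_sums <- rowSums(ann$transitions[-1])
  expect_equal(tr_sums, rep(1, nrow(ann$transitions)), tolerance = 1e-12)
})

test_that("fits are bit-reproducible for a fixed seed and states are ordered", {
  truth <- random_hmm(2, 1)
  truth$feature_names <- "f"
  sim <- simulate_hmm_sequences(truth, n_seqs = 30, length = 40, seed = 12)
  f1 <- fit_hmm(sim$sequences, features = "f", K = 2, n_restarts = 2, seed = 5)
  f2 <- fit_hmm(sim$sequences, features = "f", K = 2, n_restarts = 2, seed = 5)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$loglik, f2$loglik)
  expect_true(f1$means[1, 1] <= f1$means[2, 1])  # deterministic state order
})

test_that("shape HMM separates alternating rod/sphere morphologies", {
  set.seed(15)
  n <- 40; len <- 30
  mk_track <- function(tid) {
    rod <- rep(c(TRUE, FALSE), length.out = len)
    tibble::tibble(
      track_id = tid, frame = seq_len(len),
      asphericity = ifelse(rod, rnorm(len, 8, 0.4), rnorm(len, 0.5, 0.2)),
      prolateness = ifelse(rod, rnorm(len, 0.8, 0.05), rnorm(len, 0, 0.05)),
      kappa_sq = pmin(1, pmax(0, ifelse(rod, rnorm(len, 0.8, 0.05), rnorm(len, 0.05, 0.02)))),
      volume = rnorm(len, 200, 10)
    )
  }
  steps <- dplyr::bind_rows(lapply(seq_len(n), mk_track))
  res <- fit_shape_hmm(steps, K = 4, n_restarts = 2, seed = 3)
  occ <- colMeans(res$annotation$occupancy[-1])
  # two states dominate when only two morphologies exist (a uniform spread
  # over the 4 fitted states would put only 0.5 on the top two)
  expect_gt(sum(sort(occ, decreasing = TRUE)[1:2]), 0.75)

  const <- tibble::tibble(track_id = 1, frame = 1:30,
                          asphericity = 2, prolateness = 0.1,
                          kappa_sq = 0.2, volume = 100)
  res2 <- fit_shape_hmm(const, K = 2, n_restarts = 1, seed = 1)
  expect_gte(max(res2$annotation$occupancy[-1]), 0.99)
})

test_that("glance and tidy expose the fit in broom style", {
  truth <- random_hmm(2, 1)
  truth$feature_names <- "f"
  sim <- simulate_hmm_sequences(truth, 10, 20, seed = 2)
  fit <- fit_hmm(sim$sequences, features = "f", K = 2, n_restarts = 1, seed = 1)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(all(c("K", "loglik", "BIC", "converged") %in% names(g)))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("state", "feature", "mean", "variance") %in% names(td)))
})
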