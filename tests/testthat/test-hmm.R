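test_that("subject normalization: zero channel means, unit pooled variance, scale invariance", {
  set.seed(81)
  x <- matrix(rnorm(5 * 400, mean = 3, sd = 2), 5)
  z <- normalize_subject(x)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
  expect_equal(normalize_subject(5 * x), z, tolerance = 1e-12)
  expect_error(normalize_subject(matrix(1, 2, 10)), "zero global variance")
})

test_that("group PCA prewhitening is lossless at full order and matches an eigensolver", {
  set.seed(82)
  envs <- lapply(1:3, function(i) normalize_subject(matrix(rnorm(6 * 300), 6)))
  pca <- concat_pca_prewhiten(envs, n_pcs = 6)
  # components have unit variance
  expect_lt(max(abs(apply(pca$scores, 2, var) - 1)), 1e-10)
  # back-projection reconstructs the input
  X <- do.call(cbind, envs)
  C <- tcrossprod(X) / (ncol(X) - 1)
  back <- C %*% pca$weights %*% t(pca$scores)  # inverse of the whitening map
  expect_lt(max(abs(back - X)), 1e-8)
  # eigen oracle: explained variance ordering matches eigen() directly
  expect_equal(pca$evals, eigen(C, symmetric = TRUE)$values, tolerance = 1e-10)
  # boundaries partition the concatenation
  expect_equal(pca$boundaries$end - pca$boundaries$start + 1, rep(300L, 3))
  # rank capping with warning
  rank_def <- lapply(envs, function(e) rbind(e, e[1, ] * 2))
  expect_warning(p2 <- concat_pca_prewhiten(rank_def, n_pcs = 7), "rank")
  expect_equal(ncol(p2$scores), 6)
})

test_that("HMM fitting: degenerate K=1, planted 2-state recovery, determinism, restarts", {
  # K = 1: moments match the sample
  set.seed(83)
  x1 <- matrix(rnorm(500 * 2), 500)
  f1 <- fit_hmm(x1, K = 1)
  expect_equal(drop(f1$means), colMeans(x1), tolerance = 1e-8)
  expect_equal(f1$covs[, , 1], cov(x1) * 499 / 500, tolerance = 1e-8)
  # planted 2-state chain with means +-3
  plan <- two_state_plan(0.95)
  s <- sample_state_sequence(plan, 2000, seed = 84)
  x <- matrix(rnorm(2000, mean = c(-3, 3)[s]), ncol = 1)
  fit <- fit_hmm(x, K = 2, n_restarts = 3, seed = 1)
  expect_lt(max(abs(sort(drop(fit$means)) - c(-3, 3))), 0.2)
  # selected restart has the best objective
  expect_gte(fit$loglik, max(fit$restart_logliks) - 1e-9)
  # determinism
  fit2 <- fit_hmm(x, K = 2, n_restarts = 3, seed = 1)
  expect_identical(fit$means, fit2$means)
  expect_identical(fit$loglik, fit2$loglik)
  # transition rows stochastic, covariances positive definite
  expect_equal(rowSums(fit$trans), c(1, 1), tolerance = 1e-10)
  expect_true(all(apply(fit$covs, 3, function(S) min(eigen(S)$values) > 0)))
})

test_that("Viterbi decoding is exclusive and recovers planted states", {
  plan <- two_state_plan(0.95)
  s <- sample_state_sequence(plan, 4000, seed = 85)
  x <- matrix(rnorm(4000, mean = c(-3, 3)[s]), ncol = 1)
  fit <- fit_hmm(x, K = 2, n_restarts = 3, seed = 2)
  v <- predict(fit, x, type = "viterbi")
  agree <- max(mean(v == s), mean(v == 3 - s))
  expect_gte(agree, 0.95)
  # binary path form: one active state per sample
  paths <- viterbi_path(fit, x,
                        data.frame(subject = c("a", "b"),
                                   start = c(1L, 2001L), end = c(2000L, 4000L)))
  expect_equal(length(paths), 2)
  for (p in paths) expect_true(all(colSums(p) == 1))
  # K = 1: all-ones path
  f1 <- fit_hmm(x, K = 1)
  p1 <- viterbi_path(f1, x)[[1]]
  expect_true(all(p1 == 1))
  # posterior probabilities sum to one
  post <- predict(fit, x[1:100, , drop = FALSE], type = "posterior")
  expect_equal(rowSums(post), rep(1, 100), tolerance = 1e-8)
})

test_that("model object methods: print, summary, coef, logLik, simulate round-trip", {
  plan <- two_state_plan(0.9)
  s <- sample_state_sequence(plan, 1500, seed = 86)
  x <- matrix(rnorm(1500, mean = c(-2, 2)[s], sd = 0.5), ncol = 1)
  fit <- fit_hmm(x, K = 2, n_restarts = 2, seed = 3)
  expect_output(print(fit), "2-state Gaussian HMM")
  sm <- summary(fit)
  expect_equal(nrow(sm$states), 2)
  cf <- coef(fit)
  expect_named(cf, c("means", "covs", "trans", "init"))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$loglik)
  # simulate from the fit and re-decode: parameters are self-consistent
  sim <- simulate(fit, nsim = 3000, seed = 87)
  v <- predict(fit, sim$observations)
  expect_gte(mean(v == sim$states), 0.95)
  # plot methods draw without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off(), add = TRUE)
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, type = "transition"))
})

test_that("relabeling states permutes metrics and maps consistently", {
  plan <- markov_plan(matrix(c(.9, .05, .05,
                               .05, .9, .05,
                               .05, .05, .9), 3, byrow = TRUE),
                      n_regions = 1)
  s <- sample_state_sequence(plan, 3000, seed = 88)
  K <- 3
  path <- matrix(0L, K, length(s))
  path[cbind(s, seq_along(s))] <- 1L
  set.seed(89)
  env <- matrix(rnorm(2 * length(s)), 2) + rbind(path[1, ], path[3, ])
  perm <- c(3, 1, 2)
  met <- temporal_metrics(path, fs_states = 40)
  met_p <- temporal_metrics(path[perm, ], fs_states = 40)
  expect_equal(met_p$MLT_s, met$MLT_s[perm])
  expect_equal(met_p$FO, met$FO[perm])
  expect_equal(met_p$MIL_s, met$MIL_s[perm])
  maps <- state_power_maps(path, env)
  maps_p <- state_power_maps(path[perm, ], env)
  expect_equal(unname(maps_p), unname(maps[perm, ]), tolerance = 1e-12)
})

test_that("temporal metrics: hand-counted example, edge cases, occupancy identity", {
  # [0,0,1,1,1,0,1,0,0,0] at 40 Hz: runs (3,1), gap (1)
  p <- rbind(c(0, 0, 1, 1, 1, 0, 1, 0, 0, 0),
             c(1, 1, 0, 0, 0, 1, 0, 1, 1, 1))
  m <- temporal_metrics(p, fs_states = 40)
  expect_equal(m$MLT_s[1], 0.050)
  expect_equal(m$FO[1], 0.4)
  expect_equal(m$MIL_s[1], 0.025)
  expect_equal(m$n_visits[1], 2L)
  # all-active state: FO 1, MIL missing
  pa <- rbind(rep(1, 20), rep(0, 20))
  ma <- temporal_metrics(pa, fs_states = 40)
  expect_equal(ma$FO, c(1, 0))
  expect_true(is.na(ma$MIL_s[1]))
  expect_true(is.na(ma$MLT_s[2]))
  # FO sums to 1 and FO = MLT * n_visits / T on random exclusive paths
  for (seed in 1:5) {
    s <- sample_state_sequence(two_state_plan(0.8), 500, seed = seed)
    pp <- matrix(0L, 2, 500)
    pp[cbind(s, 1:500)] <- 1L
    mm <- temporal_metrics(pp, fs_states = 40)
    expect_equal(sum(mm$FO), 1, tolerance = 1e-12)
    expect_equal(mm$FO, mm$MLT_s * 40 * mm$n_visits / 500, tolerance = 1e-12)
  }
})

test_that("renewal identity FO ~ MLT/(MLT+MIL) holds on long paths", {
  s <- sample_state_sequence(two_state_plan(0.9), 2e4, seed = 90)
  p <- matrix(0L, 2, length(s))
  p[cbind(s, seq_along(s))] <- 1L
  m <- temporal_metrics(p, fs_states = 40)
  expect_gt(min(m$n_visits), 50)
  for (k in 1:2)
    expect_lt(abs(m$FO[k] - m$MLT_s[k] / (m$MLT_s[k] + m$MIL_s[k])), 0.05)
})

test_that("state power maps: perfect coupling, null bound, planted modulation", {
  plan <- markov_plan(matrix(c(.9, .05, .05,
                               .05, .9, .05,
                               .05, .05, .9), 3, byrow = TRUE),
                      n_regions = 1)
  s <- sample_state_sequence(plan, 1e5, seed = 91)
  K <- 3
  path <- matrix(0L, K, length(s))
  path[cbind(s, seq_along(s))] <- 1L
  set.seed(92)
  noise <- matrix(rnorm(3 * length(s)), 3)
  # channel 1 = state 2's indicator (demeaned), channels 2-3 independent noise
  env <- rbind(path[2, ] - mean(path[2, ]), noise[2, ], noise[3, ])
  maps <- state_power_maps(path, env)
  expect_gt(maps[2, 1], 0.99)
  expect_lt(max(abs(maps[, 2:3])), 0.05)
  # planted positive modulation: g = 0.5 on channel 1 during state 2;
  # envelopes are positive-mean so the gain shifts the level
  base_env <- 1 + 0.2 * noise
  env2 <- base_env * (1 + 0.5 * rbind(path[2, ], 0, 0))
  maps2 <- state_power_maps(path, env2)
  expect_gt(maps2[2, 1], max(maps2[2, 2:3]))
  # misaligned inputs rejected
  expect_error(state_power_maps(path, env[, 1:10]), "aligned")
})
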