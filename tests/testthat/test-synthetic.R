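test_that("state sequences follow the chain: absorbing, dwell time, determinism", {
  # absorbing chain stays in state 1
  plan1 <- markov_plan(diag(2), initial = c(1, 0), n_regions = 1)
  expect_equal(sample_state_sequence(plan1, 100, seed = 1), rep(1L, 100))
  # geometric dwell: mean run length 1/(1 - p_stay) = 10
  s <- sample_state_sequence(two_state_plan(0.9), 1e5, seed = 2)
  expect_lt(abs(mean(rle(s)$lengths) - 10) / 10, 0.05)
  # determinism
  expect_identical(sample_state_sequence(two_state_plan(), 500, seed = 3),
                   sample_state_sequence(two_state_plan(), 500, seed = 3))
  # invalid transition rows are named
  bad <- matrix(c(0.5, 0.4, 0.1, 0.9), 2, byrow = TRUE)
  expect_error(markov_plan(bad, n_regions = 1), "row")
})

test_that("empirical transition frequencies converge to the plan", {
  trans <- matrix(c(0.85, 0.10, 0.05,
                    0.05, 0.90, 0.05,
                    0.10, 0.10, 0.80), 3, byrow = TRUE)
  plan <- markov_plan(trans, n_regions = 1)
  s <- sample_state_sequence(plan, 1e6, seed = 4)
  emp <- prop.table(table(factor(s[-length(s)], 1:3),
                          factor(s[-1], 1:3)), 1)
  kl <- sum(trans * log(trans / as.matrix(emp)))
  expect_lt(kl, 0.01)
})

test_that("synthetic envelopes match the planted correlation and stay positive", {
  fs <- 250
  n <- 300 * fs
  mod0 <- matrix(0, 1, 3)
  # identity target: mean |r| small over 28 pairs of a long recording
  # (single-pair r has sampling SE ~ 1/sqrt(2 * bandwidth * duration))
  env0 <- synth_envelopes(diag(8), rep(1L, 2 * n), matrix(0, 1, 8), fs,
                          seed = 5)
  C0 <- cor(t(env0))
  expect_lt(mean(abs(C0[upper.tri(C0)])), 0.05)
  # planted r = 0.8 recovered within 0.1
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.8
  env8 <- synth_envelopes(R, rep(1L, n), mod0, fs, seed = 6)
  expect_lt(abs(cor(env8[1, ], env8[2, ]) - 0.8), 0.1)
  # positivity for valid modulations, including strong deactivation
  plan <- two_state_plan(0.95, n_regions = 3,
                         modulation = rbind(c(1, 0, 0), c(-0.9, 0, 0)))
  s <- sample_state_sequence(plan, 10 * fs, seed = 7)
  envm <- synth_envelopes(diag(3), s, plan$modulation, fs, seed = 7)
  expect_gt(min(envm), 0)
  # zero modulation leaves envelopes independent of the state sequence
  e_a <- synth_envelopes(diag(3), rep(1L, 10 * fs), mod0, fs, seed = 8)
  e_b <- synth_envelopes(diag(3), s, matrix(0, 2, 3), fs, seed = 8)
  expect_equal(e_a, e_b)
  # invalid modulation rejected
  expect_error(synth_envelopes(diag(3), s, rbind(c(-1, 0, 0), 0), fs),
               "> -1")
})

test_that("synthetic recordings are band-limited with unit-variance carriers", {
  fs <- 250
  n <- 60 * fs
  # constant envelope -> unit variance per region
  x <- synth_recording(matrix(1, 2, n), "alpha", fs, seed = 9)
  expect_lt(max(abs(apply(x, 1, var) - 1)), 0.02)
  # >= 90% of spectral power inside the alpha band
  spec <- abs(fft(x[1, ] - mean(x[1, ])))^2
  f <- (seq_len(n) - 1) / n * fs
  inband <- (f >= 8 & f <= 12) | (f >= fs - 12 & f <= fs - 8)
  expect_gte(sum(spec[inband]) / sum(spec[-1]), 0.9)
  expect_error(synth_recording(matrix(1, 1, n), band_spec("x", 100, 130), fs),
               "Nyquist")
})

test_that("the planted envelope is recoverable from the synthesized signal", {
  fs <- 250
  n <- 300 * fs
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0.8
  env <- synth_envelopes(R, rep(1L, n), matrix(0, 1, 2), fs, seed = 3)
  x <- synth_recording(env, "alpha", fs, seed = 4)
  rec_env <- lowpass_envelope(Mod(analytic_of(x, fs, "alpha")), 1, fs = fs)
  keep <- fs:(n - fs)
  planted_lp <- lowpass_envelope(env, 1, fs = fs)
  expect_gt(cor(rec_env[1, keep], planted_lp[1, keep]), 0.8)
})

test_that("instantaneous mixing behaves as a linear map", {
  fs <- 250
  x <- synth_recording(matrix(1, 3, 10 * fs), "alpha", fs, seed = 10)
  expect_equal(apply_mixing(x, diag(3)), x)
  P <- diag(3)[c(2, 3, 1), ]
  expect_equal(apply_mixing(x, P), x[c(2, 3, 1), ])
  expect_error(apply_mixing(x, diag(4)), "columns")
})

test_that("leakage mixing inflates raw envelope correlation; orthogonalization nulls it", {
  fs <- 250
  n <- 300 * fs
  x <- synth_recording(matrix(1, 2, n), "alpha", fs, seed = 11)
  xm <- apply_mixing(x, matrix(c(1, 0.3, 0.3, 1), 2))
  a <- analytic_of(xm, fs, "alpha")
  lp <- lowpass_envelope(Mod(a), 1, fs = fs)
  keep <- fs:(n - fs)
  expect_gt(cor(lp[1, keep], lp[2, keep]), 0.2)
  expect_lt(abs(envelope_correlation_pair(a[1, ], a[2, ], fs)), 0.05)
})

test_that("cohorts have the right size, covariates, planted power effect and determinism", {
  # reference-study group sizes: 32 + 38 + 35 = 105 subjects (structure only)
  parc <- rsn_parcellation()
  tiny <- default_cohort_configs(n_per_group = 1, duration_s = 8, parc = parc)
  sizes <- c(32, 38, 35)
  for (i in 1:3) tiny[[i]]$n_subjects <- sizes[i]
  counts <- vapply(tiny, function(g) g$n_subjects, numeric(1))
  expect_equal(sum(counts), 105)
  # generated small cohort: counts, covariate scheme, determinism
  cfgs <- default_cohort_configs(n_per_group = 2, duration_s = 8)
  cohort <- make_cohort(cfgs, seed = 21)
  man <- attr(cohort, "manifest")
  expect_equal(nrow(man), 6)
  expect_equal(man$sex, rep(c("M", "F"), 3))
  # system alternates in pairs with a per-group offset (never aliased to sex)
  expect_equal(man$system, c("triux", "triux", "vectorview", "vectorview",
                             "triux", "triux"))
  # sex and system stay linearly independent even at n = 2 per group
  X <- stats::model.matrix(~ sex + system, man)
  expect_equal(qr(X)$rank, 3L)
  cohort2 <- make_cohort(cfgs, seed = 21)
  expect_identical(cohort[[1]]$data, cohort2[[1]]$data)
  expect_identical(cohort[[6]]$data, cohort2[[6]]$data)
  # children theta power is planted higher (scale 2 vs 1)
  th_child <- mean(apply(bandpass(cohort[[1]]$data, 250, "theta"), 1, var))
  th_young <- mean(apply(bandpass(cohort[[3]]$data, 250, "theta"), 1, var))
  expect_gt(th_child, th_young)
  # n = 0 drops the group, others unaffected
  cfgs0 <- cfgs
  cfgs0[[2]]$n_subjects <- 0L
  cohort0 <- make_cohort(cfgs0, seed = 21)
  expect_equal(unique(attr(cohort0, "manifest")$group), c("children", "elders"))
  expect_identical(cohort0[["children_01"]]$data, cohort[["children_01"]]$data)
  # duplicate names rejected
  dup <- cfgs
  dup[[2]]$name <- "children"
  expect_error(make_cohort(dup, seed = 1), "duplicate")
})
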