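test_that("pairwise orthogonalization: self-nulling, quadrature passing, direct values", {
  x <- complex(real = c(1, 0, 1, 2), imaginary = c(0, 1, 1, 0))
  y <- complex(real = c(0, 1, 1, 0), imaginary = c(1, 0, 0, 1))
  # direct evaluation of imag(y * conj(x) / |x|)
  expect_equal(orthogonalize_pair(x, y), c(1, -1, -1 / sqrt(2), 1),
               tolerance = 1e-6)
  # y = x -> identically zero
  expect_equal(orthogonalize_pair(x, x), rep(0, 4))
  # y = i x -> |x| (the quadrature component passes untouched)
  expect_equal(orthogonalize_pair(x, 1i * x), Mod(x))
  # linearity in y
  z <- complex(real = rnorm(4), imaginary = rnorm(4))
  expect_equal(orthogonalize_pair(x, 2 * y + z),
               2 * orthogonalize_pair(x, y) + orthogonalize_pair(x, z))
})

test_that("envelope correlation: collinear convention, null bound, monotone recovery", {
  fs <- 250
  a <- analytic_of(make_pair_recording(0, dur_s = 60, seed = 31), fs)
  # collinear pair -> 0 by convention (both directions degenerate)
  expect_equal(envelope_correlation_pair(a[1, ], 2 * a[1, ], fs), 0)
  # independent sources: small correlation (300 s)
  a0 <- analytic_of(make_pair_recording(0, dur_s = 300, seed = 32), fs)
  expect_lt(abs(envelope_correlation_pair(a0[1, ], a0[2, ], fs)), 0.05)
  # monotone recovery: planted 0.8 recovered above planted 0.2
  r_planted <- function(r, seed) {
    a <- analytic_of(make_pair_recording(r, dur_s = 300, seed = seed), fs)
    envelope_correlation_pair(a[1, ], a[2, ], fs)
  }
  expect_gt(r_planted(0.8, 33), r_planted(0.2, 33))
  expect_error(envelope_correlation_pair(a[1, 1:100], a[2, 1:100], fs),
               "10 s")
})

test_that("recovered correlation is strictly increasing in the planted correlation", {
  # monotone recovery across {0, .2, .4, .6, .8}, rank correlation 1
  fs <- 250
  planted <- c(0, 0.2, 0.4, 0.6, 0.8)
  rec <- vapply(seq_along(planted), function(i) {
    a <- analytic_of(make_pair_recording(planted[i], dur_s = 120,
                                         seed = 40 + i), fs)
    envelope_correlation_pair(a[1, ], a[2, ], fs)
  }, numeric(1))
  expect_equal(cor(rec, planted, method = "spearman"), 1)
})

test_that("connectome matrices keep the symmetry and diagonal conventions", {
  fs <- 250
  parc <- rsn_parcellation()
  cfgs <- default_cohort_configs(n_per_group = 1, duration_s = 20)
  rec <- make_cohort(cfgs, seed = 51)[[1]]
  conn <- build_connectome(rec, "alpha", parc)
  expect_equal(dim(conn), c(32, 32))
  expect_identical(unclass(conn), t(unclass(conn)))
  expect_true(all(diag(conn) == 0))
  expect_true(all(abs(conn) <= 1))
  # 496 unique connections
  expect_equal(sum(upper.tri(conn)), 496)
  # permutation equivariance
  perm <- c(5:32, 1:4)
  rec_p <- recording(rec$data[perm, ], rec$fs, subject = rec$subject)
  parc_p <- parc
  parc_p$label <- parc$label[perm]
  parc_p$network <- parc$network[perm]
  conn_p <- build_connectome(rec_p, "alpha", parc_p)
  expect_equal(unclass(conn_p), unclass(conn)[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(build_connectome(recording(rec$data[1:10, ], fs), "alpha", parc),
               "channels")
})

test_that("node power measures band-limited variance", {
  fs <- 250
  n <- 60 * fs
  rec <- recording(synth_recording(matrix(1, 2, n), "alpha", fs, seed = 61),
                   fs)
  pw <- node_power(rec, "alpha")
  # variance of a ~4-Hz-bandwidth process over 58 s has sampling SE ~ 0.07
  expect_lt(max(abs(pw - 1)), 0.2)
  # quadratic scaling (floating-point rounding differs through the filter)
  rec3 <- recording(3 * rec$data, fs)
  expect_equal(node_power(rec3, "alpha"), 9 * pw, tolerance = 1e-6)
  # theta-band power of a pure alpha recording is negligible
  expect_lt(max(node_power(rec, "theta") / pw), 0.05)
})

test_that("summaries are means over the right entries", {
  parc <- rsn_parcellation()
  p <- nrow(parc)
  # constant off-diagonal matrix: every mean equals the constant
  conn <- matrix(0.3, p, p); diag(conn) <- 0
  pow <- rep(2, p)
  s <- summarize_connectome(conn, pow, parc)
  expect_equal(s$connectivity, rep(0.3, 7), tolerance = 1e-12)
  expect_equal(s$power, rep(2, 7), tolerance = 1e-12)
  # pVIS mean is exactly the single V1-V1 entry
  conn2 <- conn
  iv <- which(parc$network == "pVIS")
  conn2[iv[1], iv[2]] <- conn2[iv[2], iv[1]] <- 0.77
  s2 <- summarize_connectome(conn2, pow, parc)
  expect_equal(s2$connectivity[s2$scope == "pVIS"], 0.77)
  # combinatorics: 77 within- and 419 cross-network pairs; global recomputable
  pairs <- connection_pairs(parc)
  expect_equal(nrow(pairs), 496)
  expect_equal(sum(pairs$within), 77)
  expect_equal(sum(!pairs$within), 419)
  expect_equal(as.vector(table(pairs$network[pairs$within])[levels(parc$network)]),
               choose(c(6, 5, 7, 2, 6, 6), 2))
  expect_equal(s2$connectivity[s2$scope == "global"],
               mean(conn2[upper.tri(conn2)]), tolerance = 1e-12)
  # single-node networks are rejected
  parc_bad <- rsn_parcellation(list(A = as.character(1:31), B = "32"))
  expect_error(summarize_connectome(conn, pow, parc_bad), "fewer than 2")
})

test_that("confound regression removes covariates but keeps group structure", {
  set.seed(71)
  n <- 60
  # orthogonal covariate leaves the feature untouched
  f <- rnorm(n)
  cov_orth <- residuals(lm(rnorm(n) ~ f))
  f0 <- f - mean(f)
  out <- regress_confounds(matrix(f, ncol = 1),
                           data.frame(x = cov_orth - mean(cov_orth)))
  # sample correlation zero by construction -> slope 0, output = input
  expect_lt(max(abs(out - matrix(f, ncol = 1))), 1e-8)
  # perfect fit -> residual ~ 0, output ~ intercept
  xx <- rnorm(n)
  feat <- 2 + 3 * xx
  out2 <- regress_confounds(matrix(feat, ncol = 1), data.frame(x = xx))
  expect_lt(max(abs(out2 - 2)), 1e-10)
  # power confound removed, planted group difference preserved
  grp <- rep(c(0, 1), each = n / 2)
  pw <- rnorm(n, 10, 2)
  feat3 <- 2 * pw + 1.5 * grp + rnorm(n, sd = 0.1)
  out3 <- regress_confounds(matrix(feat3, ncol = 1), data.frame(power = pw))
  expect_lt(abs(cor(out3[, 1], residuals(lm(pw ~ 1)))), 1e-10)
  diff_planted <- 1.5
  diff_obs <- mean(out3[grp == 1, 1]) - mean(out3[grp == 0, 1])
  expect_lt(abs(diff_obs - diff_planted) / diff_planted, 0.1)
  # rank-deficient designs are named
  expect_error(regress_confounds(matrix(f, ncol = 1),
                                 data.frame(a = xx, b = 2 * xx)),
               "collinear")
})
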