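# Shared fixtures, built in code at test time.

fs_default <- 250

# A two-region recording with a planted envelope correlation.
make_pair_recording <- function(r, dur_s = 300, fs = fs_default, band = "alpha",
                                seed = 1) {
  n <- fs * dur_s
  R <- diag(2); R[1, 2] <- R[2, 1] <- r
  env <- synth_envelopes(R, rep(1L, n), matrix(0, 1, 2), fs, seed = seed)
  synth_recording(env, band, fs, seed = seed + 1000)
}

# Analytic signals of a recording matrix in a band.
analytic_of <- function(x, fs = fs_default, band = "alpha") {
  analytic_signal(bandpass(x, fs, band))
}

# Tiny two-state plan with symmetric switching.
two_state_plan <- function(p_stay = 0.9, n_regions = 1, modulation = NULL) {
  trans <- matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, byrow = TRUE)
  markov_plan(trans, modulation = modulation, n_regions = n_regions)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))

# Wrap a bare matrix as an envelope_set (internal constructor).
envelope_set_for_test <- function(values, fs) {
  envdyn:::envelope_set(values, fs)
}

# Best label-permutation agreement between a planted and a decoded state
# sequence (exact search over permutations; K <= 8).
align_agreement <- function(s, v, K) {
  C <- as.matrix(table(factor(s, 1:K), factor(v, 1:K)))
  best <- 0
  rec <- function(k, used, acc) {
    if (k > K) {
      best <<- max(best, acc)
      return(invisible())
    }
    for (j in which(!used)) {
      used[j] <- TRUE
      rec(k + 1, used, acc + C[k, j])
      used[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, K), 0)
  best / length(s)
}
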