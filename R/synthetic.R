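#' Markov plan for transient state dynamics
#'
#' A Markov plan specifies the hidden state process a synthetic cohort is
#' generated from: a row-stochastic transition matrix at the recording rate,
#' an initial distribution, and a per-state regional envelope modulation.
#' While state `k` is active, the envelope of region `j` is multiplied by
#' `1 + modulation[k, j]`; negative entries (down to, but excluding, -1)
#' model deactivation.
#'
#' @param transition K x K row-stochastic matrix.
#' @param initial length-K probability vector (default uniform).
#' @param modulation K x n_regions matrix of fractional envelope gains,
#'   entries > -1 (default all zero).
#' @param n_regions number of regions when `modulation` is not supplied.
#' @return A `markov_plan` object.
#' @examples
#' markov_plan(matrix(c(.9, .1, .1, .9), 2, byrow = TRUE), n_regions = 4)
#' @export
markov_plan <- function(transition, initial = NULL, modulation = NULL,
                        n_regions = NULL) {
  check_matrix(transition, "transition")
  K <- nrow(transition)
  if (ncol(transition) != K) stop_envdyn("`transition` must be square")
  if (any(transition < 0) || any(transition > 1))
    stop_envdyn("transition probabilities must lie in [0, 1]")
  bad <- which(abs(rowSums(transition) - 1) > 1e-12)
  if (length(bad))
    stop_envdyn("transition row%s %s do%s not sum to 1",
                if (length(bad) > 1) "s" else "",
                paste(bad, collapse = ", "),
                if (length(bad) > 1) "" else "es")
  initial <- initial %||% rep(1 / K, K)
  if (length(initial) != K || any(initial < 0) || abs(sum(initial) - 1) > 1e-12)
    stop_envdyn("`initial` must be a length-%d probability vector", K)
  if (is.null(modulation)) {
    if (is.null(n_regions))
      stop_envdyn("supply `modulation` or `n_regions`")
    modulation <- matrix(0, K, n_regions)
  }
  check_matrix(modulation, "modulation")
  if (nrow(modulation) != K)
    stop_envdyn("`modulation` must have K = %d rows", K)
  if (any(modulation <= -1))
    stop_envdyn("modulation entries must be > -1 (envelopes stay positive)")
  structure(list(K = K, transition = transition, initial = initial,
                 modulation = modulation),
            class = "markov_plan")
}

#' @export
print.markov_plan <- function(x, ...) {
  cat(sprintf("<markov_plan> K = %d states, %d regions, mean p_stay = %.3f\n",
              x$K, ncol(x$modulation), mean(diag(x$transition))))
  invisible(x)
}

#' Sample a hidden state sequence
#'
#' Draws a state sequence from the Markov chain of a plan: the first state
#' from the initial distribution, then row-wise transitions.
#'
#' @param plan a [markov_plan()].
#' @param n_samples sequence length (>= 1).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return Integer vector of length `n_samples` with labels `1..K`.
#' @export
sample_state_sequence <- function(plan, n_samples, seed = NULL) {
  stopifnot(inherits(plan, "markov_plan"))
  check_scalar(n_samples, "n_samples", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  as.integer(markov_sample_cpp(plan$transition, plan$initial,
                               as.integer(n_samples)))
}

#' Synthesize correlated, state-modulated power envelopes
#'
#' Baseline envelopes are slow positive processes with a target cross-region
#' correlation structure: white Gaussian noise is low-pass filtered below
#' `lp_cutoff` Hz, linearly mixed to the target correlation, shifted to mean
#' `mu` with standard deviation `sigma`, and floored at `floor_at` to
#' guarantee positivity (the shift keeps the clipping probability, and hence
#' the correlation bias, negligible). While state `k` is active the envelope
#' of region `j` is multiplied by `1 + modulation[k, j]`.
#'
#' @param base_corr positive semi-definite correlation target (regions x
#'   regions, unit diagonal).
#' @param states integer state sequence (length = number of samples).
#' @param modulation K x regions gain matrix, entries > -1.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param lp_cutoff envelope bandwidth in Hz (must stay below 1; default 0.7).
#' @param mu,sigma,floor_at baseline envelope mean, SD and positivity floor.
#' @return regions x samples matrix of strictly positive envelopes.
#' @export
synth_envelopes <- function(base_corr, states, modulation, fs, seed = NULL,
                            lp_cutoff = 0.7, mu = 1, sigma = 0.7,
                            floor_at = 0.05) {
  check_matrix(base_corr, "base_corr")
  p <- nrow(base_corr)
  if (ncol(base_corr) != p || any(abs(base_corr - t(base_corr)) > 1e-10))
    stop_envdyn("`base_corr` must be symmetric")
  ev <- eigen(base_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop_envdyn("`base_corr` is not positive semi-definite (min eigenvalue %g)",
                min(ev$values))
  if (any(modulation <= -1))
    stop_envdyn("modulation entries must be > -1")
  if (nrow(modulation) < max(states))
    stop_envdyn("modulation has fewer rows than the largest state label")
  n <- length(states)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(p * n), p, n)
  Zf <- lowpass_envelope(Z, cutoff = lp_cutoff, fs = fs)
  Zf <- Zf / apply(Zf, 1, sd)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  E <- L %*% Zf
  env <- pmax(mu + sigma * E, floor_at)
  gain <- 1 + t(modulation[states, , drop = FALSE])
  env * gain
}

#' Synthesize a band-limited oscillatory recording from envelopes
#'
#' Each region's signal is the product of its (slow, positive) envelope and
#' an independent unit-variance narrowband carrier obtained by band-pass
#' filtering white Gaussian noise. Carriers are noise rather than sinusoids
#' so that the Hilbert envelope of the output is non-degenerate.
#'
#' @param envelopes regions x samples positive matrix.
#' @param band [band_spec()] or canonical band name; must lie below Nyquist.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return regions x samples matrix; at least 90% of each region's spectral
#'   power lies inside the band.
#' @export
synth_recording <- function(envelopes, band, fs, seed = NULL) {
  check_matrix(envelopes, "envelopes")
  band <- as_band(band)
  if (band$hi >= fs / 2)
    stop_envdyn("band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
                band$lo, band$hi, fs / 2)
  p <- nrow(envelopes); n <- ncol(envelopes)
  if (!is.null(seed)) set.seed(seed)
  carrier <- bandpass(matrix(rnorm(p * n), p, n), fs, band)
  carrier <- carrier / apply(carrier, 1, sd)
  envelopes * carrier
}

#' Instantaneous linear mixing of a recording
#'
#' Applies a fixed real mixing matrix to the region signals at every time
#' point: output channel m is `sum_j mixing[m, j] * input[j, t]`. This
#' zero-lag mixing is the stand-in for source leakage that pairwise
#' orthogonalization is designed to suppress.
#'
#' @param rec a [recording()] or a regions x samples matrix.
#' @param mixing M x regions real matrix.
#' @return Same type as `rec` with M channels.
#' @export
apply_mixing <- function(rec, mixing) {
  check_matrix(mixing, "mixing")
  if (inherits(rec, "recording")) {
    rec$data <- apply_mixing(rec$data, mixing)
    return(rec)
  }
  check_matrix(rec, "rec")
  if (ncol(mixing) != nrow(rec))
    stop_envdyn("mixing has %d columns but the recording has %d regions",
                ncol(mixing), nrow(rec))
  mixing %*% rec
}

#' Single-subject recording container
#'
#' @param data regions x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param subject subject identifier.
#' @param group,sex,system optional covariates.
#' @return A `recording` object.
#' @export
recording <- function(data, fs, subject = NA_character_, group = NA_character_,
                      sex = NA_character_, system = NA_character_) {
  check_matrix(data, "data")
  check_scalar(fs, "fs", lower = 1e-12)
  structure(list(data = data, fs = fs, subject = subject, group = group,
                 sex = sex, system = system),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d regions x %d samples at %g Hz (%.1f s)%s\n",
              x$subject, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs,
              if (!is.na(x$group)) paste0(", group ", x$group) else ""))
  invisible(x)
}

#' Group configuration for cohort synthesis
#'
#' Bundles everything needed to generate one group's recordings: per-band
#' power scales and envelope correlation targets, the hidden Markov plan,
#' an optional leakage mixing matrix, and recording geometry.
#'
#' @param name group name (e.g. `"children"`).
#' @param n_subjects number of subjects.
#' @param band_power named numeric vector, band -> variance scale.
#' @param base_corr named list, band -> correlation target matrix (symmetric,
#'   unit diagonal, positive semi-definite).
#' @param plan a [markov_plan()].
#' @param mixing optional M x regions mixing matrix.
#' @param duration_s recording duration in seconds (default 60).
#' @param fs sampling rate in Hz (default 250); must be at least four times
#'   the highest band edge.
#' @return A `group_config` object.
#' @export
group_config <- function(name, n_subjects, band_power, base_corr, plan,
                         mixing = NULL, duration_s = 60, fs = 250) {
  stopifnot(inherits(plan, "markov_plan"))
  if (!is.character(name) || length(name) != 1L)
    stop_envdyn("`name` must be a single string")
  check_scalar(n_subjects, "n_subjects", lower = 0)
  if (is.null(names(band_power)) || !setequal(names(band_power), names(base_corr)))
    stop_envdyn("`band_power` and `base_corr` must be named by the same bands")
  for (b in names(base_corr)) {
    m <- base_corr[[b]]
    check_matrix(m, paste0("base_corr$", b))
    if (any(abs(diag(m) - 1) > 1e-10))
      stop_envdyn("base_corr for band '%s' must have unit diagonal", b)
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop_envdyn("base_corr for band '%s' is not positive semi-definite", b)
    hi <- as_band(b)$hi
    if (fs < 4 * hi)
      stop_envdyn("fs = %g Hz is below 4x the highest band edge (%g Hz)", fs, hi)
  }
  if (!is.null(mixing)) check_matrix(mixing, "mixing")
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 band_power = band_power, base_corr = base_corr, plan = plan,
                 mixing = mixing, duration_s = duration_s, fs = fs),
            class = "group_config")
}

#' Generate a synthetic cohort
#'
#' Generates `n_subjects` recordings per group, each the sum over bands of
#' envelope-modulated narrowband signals sharing one hidden state sequence,
#' optionally passed through the group's leakage mixing matrix. Subject
#' seeds are derived deterministically from the master seed. Covariates are
#' assigned deterministically: sex alternates within each group (M, F, M,
#' ...) and the acquisition-system tag ("vectorview"/"triux") alternates in
#' pairs with a per-group offset, giving a near 50/50 split within each
#' group while staying linearly independent of the sex assignment even for
#' very small groups.
#'
#' @param configs list of [group_config()] objects with unique names.
#' @param seed master integer seed.
#' @return List of [recording()] objects with a `manifest` attribute (data
#'   frame: subject, group, sex, system, fs, duration_s).
#' @examples
#' cfg <- default_cohort_configs(n_per_group = 1, duration_s = 8)
#' cohort <- make_cohort(cfg, seed = 1)
#' attr(cohort, "manifest")
#' @export
make_cohort <- function(configs, seed = 1) {
  if (!length(configs)) stop_envdyn("`configs` must be non-empty")
  nms <- vapply(configs, function(g) g$name, character(1))
  if (anyDuplicated(nms))
    stop_envdyn("duplicate group names: %s",
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  group_seeds <- derive_seeds(seed, length(configs))
  recs <- list()
  rows <- list()
  for (gi in seq_along(configs)) {
    cfg <- configs[[gi]]
    if (cfg$n_subjects == 0) next
    subj_seeds <- derive_seeds(group_seeds[gi], cfg$n_subjects)
    n <- round(cfg$duration_s * cfg$fs)
    bands <- names(cfg$band_power)
    for (si in seq_len(cfg$n_subjects)) {
      ss <- derive_seeds(subj_seeds[si], 1 + 2 * length(bands))
      states <- sample_state_sequence(cfg$plan, n, seed = ss[1])
      p <- ncol(cfg$plan$modulation)
      x <- matrix(0, p, n)
      for (bi in seq_along(bands)) {
        b <- bands[bi]
        env <- synth_envelopes(cfg$base_corr[[b]], states,
                               cfg$plan$modulation, cfg$fs,
                               seed = ss[2 * bi])
        x <- x + sqrt(cfg$band_power[[b]]) *
          synth_recording(env, b, cfg$fs, seed = ss[2 * bi + 1])
      }
      if (!is.null(cfg$mixing)) x <- apply_mixing(x, cfg$mixing)
      id <- sprintf("%s_%02d", cfg$name, si)
      sex <- if (si %% 2 == 1) "M" else "F"
      # paired alternation with a per-group offset: near-50/50 within each
      # group without aliasing the alternating sex assignment
      system <- if (((si - 1) %/% 2 + gi) %% 2 == 0) "vectorview" else "triux"
      recs[[id]] <- recording(x, cfg$fs, subject = id, group = cfg$name,
                              sex = sex, system = system)
      rows[[id]] <- data.frame(subject = id, group = cfg$name, sex = sex,
                               system = system, fs = cfg$fs,
                               duration_s = cfg$duration_s,
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  attr(recs, "manifest") <- manifest
  recs
}

#' Block-structured envelope correlation target
#'
#' Builds a correlation matrix with one background value everywhere, an
#' elevated value inside each network block, and optional per-network
#' overrides; the diagonal is 1.
#'
#' @param parc a [rsn_parcellation()].
#' @param within within-network correlation (scalar, recycled) or named
#'   vector per network.
#' @param background cross-network correlation.
#' @return regions x regions correlation matrix.
#' @export
block_corr <- function(parc, within, background = 0.05) {
  p <- nrow(parc)
  nets <- levels(parc$network)
  if (is.null(names(within))) {
    within <- stats::setNames(rep(within, length(nets))[seq_along(nets)], nets)
  }
  R <- matrix(background, p, p)
  for (nw in nets) {
    idx <- which(parc$network == nw)
    R[idx, idx] <- within[[nw]]
  }
  diag(R) <- 1
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10)
    stop_envdyn("requested block structure is not positive semi-definite")
  R
}

#' Default study-like cohort configurations
#'
#' Three groups (children, young adults, elders) with planted effects that
#' mirror the qualitative findings the analysis is designed to detect:
#' children have twice the theta-band power of adults; alpha- and beta-band
#' envelope correlations are weaker in children than in adults; the primary
#' visual inter-hemispheric beta correlation rises from childhood (0.2) to
#' early adulthood (0.8) and falls back in elders (0.2); and the visual
#' transient state is destabilized in elders (mean dwell 0.12 s vs 0.30 s).
#' Hidden states are one per network, each amplifying its own network's
#' envelopes (gain 0.8; 1.2 for the visual state).
#'
#' @param n_per_group subjects per group (default 15).
#' @param duration_s recording length in seconds (default 60).
#' @param fs sampling rate in Hz (default 250).
#' @param parc parcellation (default [rsn_parcellation()]).
#' @param mixing optional leakage mixing matrix shared by all groups.
#' @return List of three [group_config()] objects.
#' @export
default_cohort_configs <- function(n_per_group = 15, duration_s = 60,
                                   fs = 250, parc = rsn_parcellation(),
                                   mixing = NULL) {
  nets <- levels(parc$network)
  plan_for <- function(visual_dwell_s) {
    dwell <- stats::setNames(rep(0.30, length(nets)), nets)
    dwell["pVIS"] <- visual_dwell_s
    K <- length(nets)
    p_stay <- 1 - 1 / (dwell * fs)
    trans <- matrix(0, K, K)
    for (k in seq_len(K)) {
      trans[k, ] <- (1 - p_stay[k]) / (K - 1)
      trans[k, k] <- p_stay[k]
    }
    g <- matrix(0, K, nrow(parc))
    for (k in seq_len(K)) {
      gain <- if (nets[k] == "pVIS") 1.2 else 0.8
      g[k, parc$network == nets[k]] <- gain
    }
    markov_plan(trans, modulation = g)
  }
  corr_children <- list(
    theta = block_corr(parc, 0.30, 0.10),
    alpha = block_corr(parc, 0.10, 0.05),
    beta  = block_corr(parc, c(DAN = 0.10, VAN = 0.10, DMN = 0.10,
                               pVIS = 0.20, MOT = 0.10, LAN = 0.10), 0.05)
  )
  corr_young <- list(
    theta = block_corr(parc, 0.30, 0.10),
    alpha = block_corr(parc, 0.50, 0.20),
    beta  = block_corr(parc, c(DAN = 0.50, VAN = 0.50, DMN = 0.50,
                               pVIS = 0.80, MOT = 0.50, LAN = 0.50), 0.20)
  )
  corr_elder <- corr_young
  corr_elder$beta <- block_corr(parc, c(DAN = 0.50, VAN = 0.50, DMN = 0.50,
                                        pVIS = 0.20, MOT = 0.50, LAN = 0.50),
                                0.20)
  power_child <- c(theta = 2, alpha = 1, beta = 1)
  power_adult <- c(theta = 1, alpha = 1, beta = 1)
  list(
    group_config("children", n_per_group, power_child, corr_children,
                 plan_for(0.30), mixing, duration_s, fs),
    group_config("young_adults", n_per_group, power_adult, corr_young,
                 plan_for(0.30), mixing, duration_s, fs),
    group_config("elders", n_per_group, power_adult, corr_elder,
                 plan_for(0.12), mixing, duration_s, fs)
  )
}

#' Banded leakage mixing matrix
#'
#' A simple stand-in for source leakage: each channel receives its own
#' region plus a fraction `coef` of its immediate neighbours in node order
#' (and `coef^2` of second neighbours).
#'
#' @param p number of regions.
#' @param coef leakage coefficient (default 0.3).
#' @return p x p mixing matrix.
#' @export
leakage_mixing <- function(p, coef = 0.3) {
  M <- diag(p)
  for (d in 1:2) {
    val <- coef^d
    for (i in seq_len(p - d)) {
      M[i, i + d] <- val
      M[i + d, i] <- val
    }
  }
  M
}
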