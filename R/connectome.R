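#' Pairwise orthogonalization of analytic signals
#'
#' Removes, at every time point, the component of the analytic signal `y`
#' that is collinear with `x`:
#' \deqn{y_{\perp x}(t) = \mathrm{Im}\left( y(t)\,\overline{x(t)} / |x(t)| \right)}
#' The result is the real quadrature component of `y` relative to `x`; it is
#' linear in `y`, and identically zero when `y` is proportional to `x`.
#' This suppresses the artificial zero-lag coupling that instantaneous
#' source leakage induces.
#'
#' Samples where `|x| = 0` are set to 0 and counted; if more than 1% of
#' samples are degenerate this is reported through the package log.
#'
#' @param x,y complex analytic series of equal length.
#' @return Real numeric vector, the leakage-orthogonal component of `y`.
#' @examples
#' x <- complex(real = c(1, 0, 1, 2), imaginary = c(0, 1, 1, 0))
#' y <- complex(real = c(0, 1, 1, 0), imaginary = c(1, 0, 0, 1))
#' orthogonalize_pair(x, y)
#' @export
orthogonalize_pair <- function(x, y) {
  if (length(x) != length(y))
    stop_envdyn("`x` and `y` must have equal length")
  mx <- Mod(x)
  zero <- mx == 0
  if (any(zero)) {
    if (mean(zero) > 0.01)
      log_envdyn("orthogonalize_pair: %.1f%% zero-magnitude reference samples",
                 100 * mean(zero))
    mx[zero] <- 1
  }
  out <- Im(y * Conj(x) / mx)
  out[zero] <- 0
  out
}

#' Leakage-corrected envelope correlation of one pair
#'
#' The symmetrized, orthogonalized envelope correlation
#' \deqn{r = \tfrac{1}{2}\left[\mathrm{corr}(lp|x|, lp|y_{\perp x}|) +
#'          \mathrm{corr}(lp|y|, lp|x_{\perp y}|)\right]}
#' where `lp` is a zero-phase low-pass (default 1 Hz) and the correlation is
#' computed over edge-trimmed samples. A degenerate direction (the
#' orthogonalized envelope has no variance, e.g. for collinear signals)
#' contributes 0 to the average, so collinear pairs return exactly 0.
#'
#' @param x,y complex analytic series (at least 10 s of data).
#' @param fs sampling rate in Hz.
#' @param cutoff envelope low-pass cutoff in Hz (default 1).
#' @param edge_s edge margin excluded from the correlation (default 1 s).
#' @return Correlation in `[-1, 1]`.
#' @export
envelope_correlation_pair <- function(x, y, fs, cutoff = 1, edge_s = 1) {
  if (length(x) != length(y))
    stop_envdyn("`x` and `y` must have equal length")
  if (length(x) < 10 * fs)
    stop_envdyn("need at least 10 s of data (%d samples), got %d",
                ceiling(10 * fs), length(x))
  keep <- edge_keep_idx(length(x), fs, edge_s)
  lp <- function(v) drop(lowpass_envelope(matrix(v, 1), cutoff, fs))
  ex <- lp(Mod(x))[keep]
  ey <- lp(Mod(y))[keep]
  eyx <- lp(abs(orthogonalize_pair(x, y)))[keep]
  exy <- lp(abs(orthogonalize_pair(y, x)))[keep]
  dir_cor <- function(a, b) {
    if (sd(a) < 1e-12 || sd(b) < 1e-12) {
      log_envdyn("envelope_correlation_pair: degenerate direction set to 0")
      return(0)
    }
    cor(a, b)
  }
  (dir_cor(ex, eyx) + dir_cor(ey, exy)) / 2
}

#' Leakage-corrected envelope correlation connectome
#'
#' Computes the full matrix of pairwise-orthogonalized envelope correlations
#' for one subject and band. For every reference region the analytic signals
#' of all other regions are orthogonalized against it in one pass, their
#' envelope magnitudes low-pass filtered, edge-trimmed and correlated with
#' the reference envelope; the slightly asymmetric result is symmetrized by
#' averaging with its transpose and the diagonal is fixed at 0.
#'
#' @param rec a [recording()] whose channels match `parc`.
#' @param band [band_spec()] or canonical band name.
#' @param parc a [rsn_parcellation()].
#' @param cutoff envelope low-pass cutoff in Hz (default 1).
#' @param edge_s edge margin in seconds (default 1).
#' @return regions x regions symmetric matrix of class `connectome` with
#'   `band` and `subject` attributes; off-diagonal entries in `[-1, 1]`,
#'   diagonal 0.
#' @export
build_connectome <- function(rec, band, parc = rsn_parcellation(),
                             cutoff = 1, edge_s = 1) {
  stopifnot(inherits(rec, "recording"))
  band <- as_band(band)
  p <- nrow(rec$data)
  if (p != nrow(parc))
    stop_envdyn("recording has %d channels but the parcellation has %d nodes",
                p, nrow(parc))
  A <- analytic_signal(bandpass(rec$data, rec$fs, band))
  RE <- Re(A); IM <- Im(A)
  MA <- sqrt(RE^2 + IM^2)
  zero <- MA == 0
  if (any(zero)) MA[zero] <- 1
  keep <- edge_keep_idx(ncol(A), rec$fs, edge_s)
  lpE <- lowpass_envelope(Mod(A), cutoff, rec$fs)[, keep, drop = FALSE]
  flt <- signal::butter(4, cutoff / (rec$fs / 2), type = "low")
  R <- matrix(0, p, p)
  n_degenerate <- 0L
  for (i in seq_len(p)) {
    # y_perp_x for all y at once, x = region i (real arithmetic)
    u_re <- RE[i, ] / MA[i, ]
    u_im <- -IM[i, ] / MA[i, ]
    O <- abs(IM * rep(u_re, each = p) + RE * rep(u_im, each = p))
    if (any(zero[i, ])) O[, zero[i, ]] <- 0
    lpO <- zero_phase_filter(O, flt)[, keep, drop = FALSE]
    Yc <- lpO - rowMeans(lpO)
    sy <- sqrt(rowSums(Yc^2))
    refc <- lpE[i, ] - mean(lpE[i, ])
    sx <- sqrt(sum(refc^2))
    tiny <- 1e-12 * sqrt(length(refc) - 1)
    if (sx < tiny) {
      n_degenerate <- n_degenerate + p - 1L
      next
    }
    r <- as.vector(Yc %*% refc) / (sy * sx)
    degen <- sy < tiny | !is.finite(r)
    n_degenerate <- n_degenerate + sum(degen[-i])
    r[degen] <- 0
    R[i, ] <- r
  }
  if (n_degenerate > 0)
    log_envdyn("build_connectome: %d degenerate directions set to 0",
               n_degenerate)
  conn <- (R + t(R)) / 2
  diag(conn) <- 0
  dimnames(conn) <- list(parc$label, parc$label)
  structure(conn, class = c("connectome", "matrix", "array"),
            band = band$name, subject = rec$subject)
}

#' Band-limited node power
#'
#' Power is the variance of the band-passed, edge-trimmed signal at each
#' node.
#'
#' @inheritParams build_connectome
#' @return Named non-negative vector of length `nrow(rec$data)`.
#' @export
node_power <- function(rec, band, edge_s = 1) {
  stopifnot(inherits(rec, "recording"))
  xb <- bandpass(rec$data, rec$fs, band)
  keep <- edge_keep_idx(ncol(xb), rec$fs, edge_s)
  apply(xb[, keep, drop = FALSE], 1, var)
}

#' Global and network summaries of a connectome
#'
#' Global connectivity is the mean over all unordered off-diagonal pairs
#' (496 for the default parcellation); network connectivity is the mean over
#' within-network pairs (for the two-node primary visual network this is the
#' single V1-V1 entry); global and network power are the corresponding node
#' means.
#'
#' @param conn connectome matrix from [build_connectome()].
#' @param pow power vector from [node_power()].
#' @param parc a [rsn_parcellation()]; every network must have at least two
#'   nodes.
#' @return Data frame with columns `scope` ("global" or a network name),
#'   `connectivity`, `power`, plus `band`/`subject` carried from `conn`.
#' @export
summarize_connectome <- function(conn, pow, parc = rsn_parcellation()) {
  p <- nrow(parc)
  if (!all(dim(conn) == p) || length(pow) != p)
    stop_envdyn("connectome/power dimensions do not match the parcellation")
  counts <- table(parc$network)
  if (any(counts < 2))
    stop_envdyn("network%s %s ha%s fewer than 2 nodes",
                if (sum(counts < 2) > 1) "s" else "",
                paste(names(counts)[counts < 2], collapse = ", "),
                if (sum(counts < 2) > 1) "ve" else "s")
  ut <- upper.tri(conn)
  rows <- data.frame(scope = "global",
                     connectivity = mean(conn[ut]),
                     power = mean(pow),
                     stringsAsFactors = FALSE)
  for (nw in levels(parc$network)) {
    idx <- which(parc$network == nw)
    sub <- conn[idx, idx, drop = FALSE]
    rows <- rbind(rows, data.frame(
      scope = nw,
      connectivity = mean(sub[upper.tri(sub)]),
      power = mean(pow[idx]),
      stringsAsFactors = FALSE))
  }
  rows$band <- attr(conn, "band") %||% NA_character_
  rows$subject <- attr(conn, "subject") %||% NA_character_
  rows
}

#' Residualize features on confounds
#'
#' Ordinary least squares of each feature on an intercept plus the supplied
#' covariates; the returned value is the residual plus the fitted intercept,
#' so the grand level of each feature is preserved. For connectivity
#' features the covariates are band-specific global power, sex and system;
#' for power and state temporal metrics, sex and system only.
#'
#' @param values subjects x features numeric matrix.
#' @param covariates data frame (one row per subject) of numeric or factor
#'   covariates.
#' @return Matrix of the same shape as `values`.
#' @export
regress_confounds <- function(values, covariates) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  check_matrix(values, "values")
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(values))
    stop_envdyn("covariates have %d rows but values have %d subjects",
                nrow(covariates), nrow(values))
  X <- stats::model.matrix(~ ., data = covariates)
  if (nrow(X) < ncol(X) + 2)
    stop_envdyn("need at least 2 more subjects than covariate columns")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop_envdyn("rank-deficient confound design; collinear column(s): %s",
                paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(X, values)
  resid <- as.matrix(fit$residuals)
  icept <- matrix(as.matrix(fit$coefficients)[1, ], nrow(values),
                  ncol(values), byrow = TRUE)
  out <- resid + icept
  dimnames(out) <- dimnames(values)
  out
}
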