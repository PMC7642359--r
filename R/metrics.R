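#' State temporal metrics
#'
#' Summarizes a binary state path into the three canonical dynamic
#' quantities, per state:
#' * MLT (mean lifetime): mean duration in seconds of maximal runs of
#'   activation, including runs truncated by the recording edges;
#' * FO (fractional occupancy): fraction of samples the state is active
#'   (occupancies sum to 1 across states);
#' * MIL (mean interval length): mean duration of complete gaps between the
#'   end of one visit and the start of the next (edge-truncated gaps are
#'   censored).
#'
#' States never visited get FO = 0 and `NA` MLT/MIL; a state active
#' throughout has FO = 1 and `NA` MIL.
#'
#' @param path a `state_path` (K x T binary matrix with column sums 1) from
#'   [viterbi_path()], or any such matrix.
#' @param fs_states sampling rate in Hz of the path (taken from the
#'   `fs_states` attribute if present).
#' @return Data frame with columns `state`, `MLT_s`, `FO`, `MIL_s`,
#'   `n_visits`.
#' @examples
#' p <- rbind(c(0, 0, 1, 1, 1, 0, 1, 0, 0, 0),
#'            c(1, 1, 0, 0, 0, 1, 0, 1, 1, 1))
#' temporal_metrics(p, fs_states = 40)
#' @export
temporal_metrics <- function(path, fs_states = NULL) {
  fs_states <- fs_states %||% attr(path, "fs_states") %||%
    stop_envdyn("`fs_states` required")
  m <- unclass(path)
  if (!all(colSums(m) == 1))
    stop_envdyn("state path must have exactly one active state per sample")
  K <- nrow(m); Tn <- ncol(m)
  out <- lapply(seq_len(K), function(k) {
    r <- rle(m[k, ])
    act <- r$lengths[r$values == 1]
    n_visits <- length(act)
    if (n_visits == 0)
      return(data.frame(state = k, MLT_s = NA_real_, FO = 0,
                        MIL_s = NA_real_, n_visits = 0L))
    # complete gaps only: drop inactive runs touching either edge
    gaps <- r$lengths[r$values == 0]
    if (length(gaps) && r$values[1] == 0) gaps <- gaps[-1]
    if (length(gaps) && r$values[length(r$values)] == 0)
      gaps <- gaps[-length(gaps)]
    data.frame(state = k,
               MLT_s = mean(act) / fs_states,
               FO = sum(act) / Tn,
               MIL_s = if (length(gaps)) mean(gaps) / fs_states else NA_real_,
               n_visits = n_visits)
  })
  do.call(rbind, out)
}

#' State power maps by partial correlation
#'
#' Maps, for every state and region, the degree of envelope power increase
#' (positive) or decrease (negative) during state visits: the partial
#' correlation between the state's binary activation series and the region's
#' normalized envelope, controlling for the other K-1 state series.
#'
#' Because the K exclusive indicators sum to a constant, demeaning all of
#' them makes the naive "control for all others" recipe exactly collinear.
#' The construction used here residualizes both the raw (non-demeaned)
#' binary series and the demeaned envelope on the other K-1 raw indicators
#' without an intercept, then correlates the residuals; the mutual
#' orthogonality of exclusive indicators makes this both well-posed and
#' cheap (the envelope residual subtracts per-state means).
#'
#' @param paths a `state_path` (or list of them, concatenated in order).
#' @param envelopes channels x samples matrix of normalized envelopes
#'   aligned with the concatenated path.
#' @return K x channels matrix of partial correlations in `[-1, 1]`; rows of
#'   never-active states are `NA`.
#' @export
state_power_maps <- function(paths, envelopes) {
  if (is.list(paths)) paths <- do.call(cbind, lapply(paths, unclass))
  S <- unclass(paths)
  E <- as_ts_matrix(envelopes)
  if (ncol(S) != ncol(E))
    stop_envdyn("paths (%d samples) and envelopes (%d) are not aligned",
                ncol(S), ncol(E))
  K <- nrow(S); Tn <- ncol(S)
  E <- E - rowMeans(E)
  # per-state means of each envelope channel
  n_k <- rowSums(S)
  M <- (E %*% t(S)) / rep(pmax(n_k, 1), each = nrow(E))  # channels x K
  out <- matrix(NA_real_, K, nrow(E))
  rownames(out) <- paste0("state", seq_len(K))
  colnames(out) <- rownames(E)
  for (k in seq_len(K)) {
    if (n_k[k] == 0) {
      log_envdyn("state_power_maps: state %d never active; row left missing", k)
      next
    }
    s <- S[k, ]
    # residual of s on the other indicators (no intercept) is s itself
    # (disjoint supports); residual of e subtracts the within-state means
    # of the other states' samples.
    Eres <- E
    for (j in seq_len(K)) {
      if (j == k || n_k[j] == 0) next
      idx <- S[j, ] == 1
      Eres[, idx] <- E[, idx] - M[, j]
    }
    s_c <- s - mean(s)
    denom <- sqrt(sum(s_c^2) * rowSums((Eres - rowMeans(Eres))^2))
    num <- as.vector((Eres - rowMeans(Eres)) %*% s_c)
    out[k, ] <- ifelse(denom > 0, num / denom, 0)
  }
  out
}
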