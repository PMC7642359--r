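#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way test across groups: midranks over the pooled sample,
#' tie-corrected H statistic, and a chi-square p-value with (number of
#' groups - 1) degrees of freedom. Delegates to [stats::kruskal.test()];
#' the degenerate all-identical case is mapped to the convention H = 0,
#' p = 1.
#'
#' @param groups list of numeric vectors, one per group (each non-empty).
#' @return List with `H`, `p`, `df`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_envdyn("`groups` must be a list of at least 2 value vectors")
  if (any(lengths(groups) == 0)) stop_envdyn("groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 5)
    warn_envdyn("fewer than 5 observations; chi-square approximation is crude")
  if (max(pooled) == min(pooled)) {
    log_envdyn("kruskal_wallis: all values identical; H = 0, p = 1")
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Post-hoc Tukey's range test on ranks
#'
#' Tukey-Kramer pairwise comparisons on pooled midranks: for groups i, j
#' with mean ranks \eqn{\bar R_i, \bar R_j},
#' \deqn{q = |\bar R_i - \bar R_j| \big/
#'   \sqrt{\tfrac{N(N+1)}{24}\left(\tfrac{1}{n_i} + \tfrac{1}{n_j}\right)}}
#' referred to the studentized range distribution with the number of groups
#' and infinite error degrees of freedom (the rank variance N(N+1)/12 is
#' known, not estimated). P-values are invariant under strictly monotone
#' transforms of the data.
#'
#' @param groups list of (>= 3) numeric vectors.
#' @return Data frame with one row per unordered pair: `group_i`, `group_j`,
#'   `q`, `p`.
#' @export
tukey_ranks_posthoc <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop_envdyn("need at least 3 groups for a range test")
  if (any(lengths(groups) == 0)) stop_envdyn("groups must be non-empty")
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  pooled_ranks <- rank(unlist(groups, use.names = FALSE))
  grp <- rep(seq_len(k), n)
  rbar <- tapply(pooled_ranks, grp, mean)
  nms <- names(groups) %||% paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(N * (N + 1) / 24 * (1 / n[i] + 1 / n[j]))
    q <- abs(rbar[i] - rbar[j]) / se
    p <- if (q == 0) 1 else ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    data.frame(group_i = nms[i], group_j = nms[j], q = unname(q),
               p = unname(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Spatial degrees of freedom of a mixing (leadfield) matrix
#'
#' The numerical rank: the number of singular values exceeding
#' `tol * max(singular value) * max(dim)`. In the synthetic setting the
#' matrix is the cohort's mixing matrix, standing in for the leadfield whose
#' rank sets the effective spatial dimensionality of the data.
#'
#' @param m channels x sources real matrix.
#' @param tol relative tolerance (default machine epsilon).
#' @return Integer rank `rho` (0 for the zero matrix).
#' @export
spatial_dof <- function(m, tol = .Machine$double.eps) {
  check_matrix(m, "m")
  sv <- svd(m, nu = 0, nv = 0)$d
  if (max(sv) == 0) return(0L)
  sum(sv > tol * max(sv) * max(dim(m)))
}

#' Effective number of comparisons for connectome-level correction
#'
#' From the spatial degrees of freedom `rho`, the effective number of
#' band-specific connections is
#' \deqn{N_{eff} = n_{bands} \cdot \rho(\rho - 1)/2}
#' rounded to the nearest integer (e.g. rho = 19 with 3 bands gives 513).
#' The Bonferroni factor actually applied to connectome tests is
#' `min(N_eff, raw number of band-specific connections)`, so the correction
#' never exceeds raw Bonferroni.
#'
#' @param rho spatial degrees of freedom (>= 2).
#' @param n_bands number of frequency bands (default 3).
#' @return List with `rho`, `n_bands`, `n_eff`.
#' @export
effective_comparisons <- function(rho, n_bands = 3) {
  check_scalar(rho, "rho")
  if (rho < 2) stop_envdyn("`rho` must be at least 2")
  list(rho = rho, n_bands = n_bands,
       n_eff = as.integer(round(n_bands * rho * (rho - 1) / 2)))
}

#' Bonferroni factor for a test family
#'
#' * `global`: the number of frequency bands (3 for theta/alpha/beta);
#' * `network`: bands x networks (3 x 6 = 18 by default);
#' * `connectome`: `min(N_eff, n_bands * n_connections)`;
#' * `hmm_states`: K - 1 (temporal exclusivity removes one degree of
#'   freedom).
#'
#' @param family one of `"global"`, `"network"`, `"connectome"`,
#'   `"hmm_states"`.
#' @param n_bands,n_networks,n_connections,K,n_eff family-specific counts;
#'   only those needed by `family` are used.
#' @return Integer Bonferroni factor.
#' @examples
#' bonferroni_factor("network")            # 18
#' bonferroni_factor("hmm_states", K = 8)  # 7
#' @export
bonferroni_factor <- function(family, n_bands = 3, n_networks = 6,
                              n_connections = 496, K = 8, n_eff = NULL) {
  switch(family,
    global = as.integer(n_bands),
    network = as.integer(n_bands * n_networks),
    connectome = {
      raw <- as.integer(n_bands * n_connections)
      if (is.null(n_eff)) raw else as.integer(min(n_eff, raw))
    },
    hmm_states = as.integer(K - 1),
    stop_envdyn("unknown family '%s'", family)
  )
}

#' Family-wise group comparison
#'
#' Runs the full inferential recipe for one family of features: optional
#' confound regression (see [regress_confounds()]), a Kruskal-Wallis omnibus
#' test per feature, post-hoc Tukey's range test on ranks for every group
#' pair, and Bonferroni correction at the family's factor. A pair is flagged
#' significant when `p * factor < 0.05`.
#'
#' @param values subjects x features numeric matrix (feature names kept).
#' @param groups factor or character vector of group labels per subject.
#' @param family family label passed to [bonferroni_factor()], or skip by
#'   supplying `factor` directly.
#' @param covariates optional data frame of confounds, regressed out before
#'   testing.
#' @param factor Bonferroni factor; computed from `family` and `...` when
#'   missing.
#' @param alpha significance level before correction (default 0.05).
#' @param ... passed to [bonferroni_factor()].
#' @return Data frame with one row per feature x group pair: `feature`, `H`,
#'   `p_omnibus`, `group_i`, `group_j`, `p_posthoc`, `factor`,
#'   `significant`.
#' @export
run_family <- function(values, groups, family, covariates = NULL,
                       factor = NULL, alpha = 0.05, ...) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  groups <- as.factor(groups)
  if (length(groups) != nrow(values))
    stop_envdyn("`groups` must have one label per subject (row)")
  factor <- factor %||% bonferroni_factor(family, ...)
  feats <- colnames(values) %||% paste0("feature", seq_len(ncol(values)))
  if (!is.null(covariates)) {
    if (all(is.finite(values))) {
      values <- regress_confounds(values, covariates)
    } else {
      # residualize feature-wise on complete cases, keeping NAs in place
      values <- vapply(seq_len(ncol(values)), function(f) {
        v <- values[, f]
        ok <- is.finite(v)
        out <- rep(NA_real_, length(v))
        cv <- as.data.frame(covariates)[ok, , drop = FALSE]
        out[ok] <- tryCatch(
          regress_confounds(matrix(v[ok], ncol = 1), cv)[, 1],
          error = function(e) v[ok])
        out
      }, numeric(nrow(values)))
    }
  }
  pair_grid <- utils::combn(levels(groups), 2)
  res <- lapply(seq_len(ncol(values)), function(f) {
    ok <- is.finite(values[, f])
    by_group <- split(values[ok, f], groups[ok])
    if (any(lengths(by_group) < 2)) {
      # a metric undefined for most of a group (e.g. MIL of an unvisited
      # state) cannot be tested; report missing rather than fail
      log_envdyn("run_family: feature %d untestable (empty group after NA removal)", f)
      return(data.frame(feature = feats[f], H = NA_real_,
                        p_omnibus = NA_real_, group_i = pair_grid[1, ],
                        group_j = pair_grid[2, ], p_posthoc = NA_real_,
                        factor = factor, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    kw <- kruskal_wallis(by_group)
    ph <- tukey_ranks_posthoc(by_group)
    data.frame(feature = feats[f], H = kw$H, p_omnibus = kw$p,
               group_i = ph$group_i, group_j = ph$group_j,
               p_posthoc = ph$p, factor = factor,
               significant = ph$p * factor < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Proportions of significant within- and cross-network links
#'
#' Divides the number of significant within-network (respectively
#' cross-network) connections by the total number of possible such
#' connections (77 and 419 for the default parcellation).
#'
#' @param flags logical vector over all unordered connections, in the order
#'   of [connection_pairs()], or a symmetric logical matrix.
#' @param parc a [rsn_parcellation()].
#' @return Named numeric vector `c(within = ..., cross = ...)`.
#' @export
link_proportions <- function(flags, parc = rsn_parcellation()) {
  pairs <- connection_pairs(parc)
  if (is.matrix(flags)) flags <- flags[upper.tri(flags)]
  if (length(flags) != nrow(pairs))
    stop_envdyn("`flags` must cover all %d connections", nrow(pairs))
  c(within = sum(flags & pairs$within) / sum(pairs$within),
    cross = sum(flags & !pairs$within) / sum(!pairs$within))
}
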