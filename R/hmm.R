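#' Per-subject envelope normalization
#'
#' Subtracts each channel's mean and divides the whole matrix by the
#' standard deviation pooled over all channels and samples, so that subjects
#' contribute comparably to the group-concatenated model regardless of their
#' overall signal scale.
#'
#' @param env an `envelope_set` or channels x samples matrix.
#' @return Same type as `env`; channel means 0, pooled variance 1.
#' @export
normalize_subject <- function(env) {
  if (inherits(env, "envelope_set")) {
    out <- env
    v <- normalize_subject(env$values)
    out$values <- v
    class(out) <- c("normalized_envelope_set", "envelope_set")
    return(out)
  }
  env <- as_ts_matrix(env)
  if (ncol(env) < 2) stop_envdyn("need at least 2 samples")
  centered <- env - rowMeans(env)
  pooled_sd <- sqrt(mean(centered^2))
  if (pooled_sd < 1e-300) stop_envdyn("zero global variance")
  centered / pooled_sd
}

#' Concatenate subjects and prewhiten by PCA
#'
#' Temporally concatenates normalized subject envelopes, extracts the
#' leading principal axes of the channel covariance, and scales each
#' retained component to unit variance (prewhitening). Subject boundaries
#' are recorded so decoded state paths can be split per subject.
#'
#' @param envs list of normalized `envelope_set`s or channels x samples
#'   matrices with equal channel counts.
#' @param n_pcs number of components to retain (default 40); capped at the
#'   numerical rank of the data with a warning.
#' @return List with `scores` (samples x n_pcs, unit variance columns),
#'   `weights` (channels x n_pcs projection matrix), `boundaries` (per
#'   subject start/end rows), `evals` (all eigenvalues) and `channels`.
#' @export
concat_pca_prewhiten <- function(envs, n_pcs = 40) {
  mats <- lapply(envs, function(e)
    if (inherits(e, "envelope_set")) e$values else as_ts_matrix(e))
  p <- unique(vapply(mats, nrow, integer(1)))
  if (length(p) != 1L) stop_envdyn("subjects have unequal channel counts")
  X <- do.call(cbind, mats)  # channels x total samples
  Tn <- ncol(X)
  C <- tcrossprod(X) / (Tn - 1)
  ev <- eigen(C, symmetric = TRUE)
  tol <- max(ev$values) * p * .Machine$double.eps
  rank <- sum(ev$values > tol)
  if (n_pcs > rank) {
    warn_envdyn("n_pcs = %d exceeds the data rank %d; capped", n_pcs, rank)
    n_pcs <- rank
  }
  lambda <- ev$values[seq_len(n_pcs)]
  W <- ev$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(1 / sqrt(lambda), n_pcs)
  scores <- crossprod(W, X)  # n_pcs x T, unit variance rows
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens)
  boundaries <- data.frame(subject = names(envs) %||% seq_along(envs),
                           start = c(1L, head(ends, -1) + 1L), end = ends)
  list(scores = t(scores), weights = W, boundaries = boundaries,
       evals = ev$values, channels = p)
}

#' Fit a Gaussian-observation hidden Markov model
#'
#' Maximum-likelihood EM (Baum-Welch) for a K-state HMM with full state
#' covariances on a (typically PCA-prewhitened, group-concatenated)
#' multivariate series. The EM is restarted `n_restarts` times from
#' k-means-based state assignments with distinct seeds; the restart with the
#' highest final log-likelihood is kept. Covariance collapse during EM is
#' handled by diagonal loading (counted and reported through the package
#' log).
#'
#' @param data samples x dims numeric matrix, or the list returned by
#'   [concat_pca_prewhiten()] (its scores and boundaries are then used).
#' @param K number of states (default 8).
#' @param n_restarts number of seeded EM restarts (default 10).
#' @param max_iter maximum EM iterations per restart (default 100).
#' @param tol convergence tolerance on the per-sample log-likelihood
#'   increase (default 1e-5).
#' @param seed integer seed controlling all restart initializations.
#' @param fs_states sampling rate of the modelled series in Hz (carried to
#'   decoded paths; default 40).
#' @return An object of class `envhmm` with state `means`, `covs`,
#'   row-stochastic `trans`, `init`, the selected restart's `loglik`, all
#'   `restart_logliks`, and bookkeeping fields. Methods: `print`, `summary`,
#'   `coef`, `logLik`, `predict` (Viterbi or posterior), `simulate`.
#' @examples
#' set.seed(1)
#' x <- matrix(c(rnorm(300, -2), rnorm(300, 2)), ncol = 1)
#' fit <- fit_hmm(x, K = 2, n_restarts = 2, seed = 1)
#' fit
#' @export
fit_hmm <- function(data, K = 8, n_restarts = 10, max_iter = 100,
                    tol = 1e-5, seed = 1, fs_states = 40) {
  boundaries <- NULL
  if (is.list(data) && !is.null(data$scores)) {
    boundaries <- data$boundaries
    data <- data$scores
  }
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  Tn <- nrow(X); d <- ncol(X)
  check_scalar(K, "K", lower = 1)
  check_scalar(n_restarts, "n_restarts", lower = 1)
  if (Tn < 10 * K * d)
    warn_envdyn("only %d samples for K = %d states in %d dims; %d recommended",
                Tn, K, d, 10 * K * d)
  if (K == 1) {
    mu <- colMeans(X)
    S <- cov(X) * (Tn - 1) / Tn
    ll <- sum(dmvnorm_log(X, mu, S))
    fit <- list(means = matrix(mu, 1), covs = array(S, c(d, d, 1)),
                trans = matrix(1, 1, 1), init = 1, loglik = ll,
                restart_logliks = ll, selected_restart = 1L,
                n_iter = 1L, converged = TRUE, n_regularized = 0L)
  } else {
    restart_seeds <- derive_seeds(seed, n_restarts)
    best <- NULL
    logliks <- numeric(n_restarts)
    for (r in seq_len(n_restarts)) {
      init <- init_from_kmeans(X, K, restart_seeds[r])
      em <- hmm_em(X, init$means, init$covs, init$trans, init$init,
                   as.integer(max_iter), tol, 1e-6)
      logliks[r] <- em$loglik
      if (is.null(best) || em$loglik > best$loglik) {
        best <- em
        best$selected_restart <- r
      }
    }
    if (best$n_regularized > 0)
      log_envdyn("fit_hmm: %d covariance regularizations by diagonal loading",
                 best$n_regularized)
    if (!best$converged)
      warn_envdyn("EM did not converge in %d iterations; best iterate returned",
                  max_iter)
    fit <- list(means = best$means, covs = best$covs, trans = best$trans,
                init = as.vector(best$init), loglik = best$loglik,
                restart_logliks = logliks,
                selected_restart = best$selected_restart,
                n_iter = best$n_iter, converged = best$converged,
                n_regularized = best$n_regularized)
  }
  fit$K <- as.integer(K)
  fit$d <- d
  fit$n_obs <- Tn
  fit$fs_states <- fs_states
  fit$boundaries <- boundaries
  fit$call <- match.call()
  class(fit) <- "envhmm"
  fit
}

init_from_kmeans <- function(X, K, seed) {
  set.seed(seed)
  km <- tryCatch(
    suppressWarnings(kmeans(X, centers = K, nstart = 1, iter.max = 100)),
    error = function(e) {
      ctr <- X[sample.int(nrow(X), K), , drop = FALSE]
      suppressWarnings(
        kmeans(X, centers = ctr + rnorm(length(ctr), sd = 1e-8),
               iter.max = 100))
    })
  d <- ncol(X)
  covs <- array(0, c(d, d, K))
  global <- cov(X) + diag(1e-6, d)
  for (k in seq_len(K)) {
    idx <- which(km$cluster == k)
    covs[, , k] <- if (length(idx) > d + 1) {
      cov(X[idx, , drop = FALSE]) + diag(1e-8, d)
    } else global
  }
  trans <- matrix(0.1 / (K - 1), K, K)
  diag(trans) <- 0.9
  prop <- tabulate(km$cluster, K) / nrow(X)
  list(means = km$centers, covs = covs, trans = trans,
       init = pmax(prop, 1e-6) / sum(pmax(prop, 1e-6)))
}

dmvnorm_log <- function(X, mu, S) {
  L <- chol(S)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(z^2))
}

#' @export
print.envhmm <- function(x, ...) {
  cat(sprintf("<envhmm> %d-state Gaussian HMM in %d dims, %d obs\n",
              x$K, x$d, x$n_obs))
  cat(sprintf("  log-likelihood %.2f (restart %d of %d%s)\n", x$loglik,
              x$selected_restart, length(x$restart_logliks),
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' @export
summary.envhmm <- function(object, ...) {
  p_stay <- diag(object$trans)
  dwell_s <- 1 / pmax(1 - p_stay, 1e-12) / object$fs_states
  out <- data.frame(state = seq_len(object$K), p_stay = p_stay,
                    expected_dwell_s = dwell_s)
  structure(list(fit = object, states = out), class = "summary.envhmm")
}

#' @export
print.summary.envhmm <- function(x, ...) {
  print(x$fit)
  print(x$states, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.envhmm <- function(object, ...) {
  list(means = object$means, covs = object$covs, trans = object$trans,
       init = object$init)
}

#' @export
logLik.envhmm <- function(object, ...) {
  npar <- object$K * object$d +
    object$K * object$d * (object$d + 1) / 2 +
    object$K * (object$K - 1) + (object$K - 1)
  structure(object$loglik, df = npar, nobs = object$n_obs, class = "logLik")
}

#' Plot a fitted envelope HMM
#'
#' `type = "means"` draws the state mean vectors across dimensions (one line
#' per state); `type = "transition"` draws the transition matrix as an
#' image with darker cells for higher probabilities.
#'
#' @param x an `envhmm` fit.
#' @param type what to draw.
#' @param ... passed to the underlying base graphics call.
#' @return `x`, invisibly.
#' @export
plot.envhmm <- function(x, type = c("means", "transition"), ...) {
  type <- match.arg(type)
  if (type == "means") {
    graphics::matplot(t(x$means), type = "l", lty = 1,
                      xlab = "dimension", ylab = "state mean",
                      main = sprintf("%d-state HMM: state means", x$K), ...)
    graphics::legend("topright", legend = paste("state", seq_len(x$K)),
                     col = seq_len(x$K), lty = 1, cex = 0.7, bty = "n")
  } else {
    graphics::image(seq_len(x$K), seq_len(x$K),
                    t(x$trans)[, rev(seq_len(x$K)), drop = FALSE],
                    col = grDevices::grey.colors(64, start = 1, end = 0),
                    xlab = "to state", ylab = "from state",
                    main = "transition probabilities", axes = FALSE, ...)
    graphics::axis(1, at = seq_len(x$K))
    graphics::axis(2, at = seq_len(x$K), labels = rev(seq_len(x$K)))
  }
  invisible(x)
}

#' Decode states for new data
#'
#' @param object an `envhmm` fit.
#' @param newdata samples x dims matrix (defaults to nothing; supply data).
#' @param type `"viterbi"` for the most probable state sequence (integer
#'   labels), `"posterior"` for smoothed state probabilities.
#' @param ... unused.
#' @export
predict.envhmm <- function(object, newdata, type = c("viterbi", "posterior"),
                           ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$d)
    stop_envdyn("newdata has %d dims but the model expects %d",
                ncol(X), object$d)
  if (type == "viterbi") {
    as.integer(hmm_viterbi(X, object$means, object$covs, object$trans,
                           object$init, 1e-6))
  } else {
    em <- hmm_em(X, object$means, object$covs, object$trans, object$init,
                 1L, Inf, 1e-6)  # one E pass, no parameter update kept
    g <- em$gamma
    colnames(g) <- paste0("state", seq_len(object$K))
    g
  }
}

#' Simulate from a fitted envelope HMM
#'
#' @param object an `envhmm` fit.
#' @param nsim number of samples to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return List with `states` (integer sequence) and `observations`
#'   (nsim x dims matrix).
#' @export
simulate.envhmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  states <- as.integer(markov_sample_cpp(object$trans, object$init,
                                         as.integer(nsim)))
  d <- object$d
  obs <- matrix(0, nsim, d)
  chols <- lapply(seq_len(object$K),
                  function(k) chol(object$covs[, , k]))
  for (k in unique(states)) {
    idx <- which(states == k)
    Z <- matrix(rnorm(length(idx) * d), length(idx), d)
    obs[idx, ] <- Z %*% chols[[k]] +
      matrix(object$means[k, ], length(idx), d, byrow = TRUE)
  }
  list(states = states, observations = obs)
}

#' Viterbi state paths per subject
#'
#' Decodes the most probable state sequence for concatenated data and splits
#' it at subject boundaries into mutually exclusive binary state activation
#' matrices.
#'
#' @param fit an `envhmm` from [fit_hmm()].
#' @param data samples x dims matrix (defaults to none; pass the
#'   concatenated scores the model was fitted to).
#' @param boundaries data frame with `subject`, `start`, `end` rows
#'   (defaults to the boundaries stored in the fit, or one pseudo-subject).
#' @return Named list of `state_path` objects: K x T binary matrices with
#'   exactly one active state per sample and an `fs_states` attribute.
#' @export
viterbi_path <- function(fit, data, boundaries = NULL) {
  stopifnot(inherits(fit, "envhmm"))
  X <- as.matrix(data)
  boundaries <- boundaries %||% fit$boundaries %||%
    data.frame(subject = "all", start = 1L, end = nrow(X))
  states <- predict(fit, X, type = "viterbi")
  out <- lapply(seq_len(nrow(boundaries)), function(i) {
    s <- states[boundaries$start[i]:boundaries$end[i]]
    m <- matrix(0L, fit$K, length(s))
    m[cbind(s, seq_along(s))] <- 1L
    structure(m, class = c("state_path", "matrix", "array"),
              fs_states = fit$fs_states)
  })
  names(out) <- boundaries$subject
  out
}
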