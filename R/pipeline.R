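#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Unknown
#' keys (top-level or nested) are rejected before any computation, and band
#' names are resolved against [canonical_bands()] at validation time so that
#' a misspelled band fails fast.
#'
#' @param bands character vector of band names for the static analysis.
#' @param hmm_band band for the dynamic (HMM) analysis (default `"wide"`).
#' @param cohort list: `configs` (a list of [group_config()]s), or
#'   `manifest` (path to a cohort written by [write_cohort()]), or the
#'   scalar fields `n_per_group`, `duration_s`, `fs` for the default
#'   synthetic cohort.
#' @param spectral list: `filter_order`, `lp_cutoff` (Hz), `edge_s` (s),
#'   `window_width_s`, `window_step_s`.
#' @param hmm list: `K`, `n_pcs`, `n_restarts`, `max_iter`, `tol`,
#'   `grouping` (`"pooled"` or `"per_group"`).
#' @param stats list: `alpha`, optional `n_eff` override for the connectome
#'   family.
#' @param seed master seed for all randomness.
#' @param write_recordings write raw synthetic recordings to disk (large;
#'   default FALSE).
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(bands = c("theta", "alpha", "beta"),
                            hmm_band = "wide",
                            cohort = list(),
                            spectral = list(),
                            hmm = list(),
                            stats = list(),
                            seed = 1,
                            write_recordings = FALSE) {
  cohort_defaults <- list(configs = NULL, manifest = NULL, n_per_group = 15,
                          duration_s = 60, fs = 250)
  spectral_defaults <- list(filter_order = 4, lp_cutoff = 1, edge_s = 1,
                            window_width_s = 0.100, window_step_s = 0.025)
  hmm_defaults <- list(K = 8, n_pcs = 40, n_restarts = 10, max_iter = 100,
                       tol = 1e-5, grouping = "pooled")
  stats_defaults <- list(alpha = 0.05, n_eff = NULL)
  merge_checked <- function(defaults, user, where) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop_envdyn("unknown %s key(s): %s", where,
                  paste(unknown, collapse = ", "))
    modifyList(defaults, user)
  }
  cfg <- list(
    bands = vapply(bands, function(b) as_band(b)$name, character(1)),
    hmm_band = as_band(hmm_band)$name,
    cohort = merge_checked(cohort_defaults, cohort, "cohort"),
    spectral = merge_checked(spectral_defaults, spectral, "spectral"),
    hmm = merge_checked(hmm_defaults, hmm, "hmm"),
    stats = merge_checked(stats_defaults, stats, "stats"),
    seed = as.integer(seed),
    write_recordings = isTRUE(write_recordings)
  )
  if (!cfg$hmm$grouping %in% c("pooled", "per_group"))
    stop_envdyn("hmm$grouping must be 'pooled' or 'per_group'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path path to a YAML configuration file whose keys mirror the
#'   arguments of `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_envdyn("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort synthesis (or reuse of supplied recordings),
#' band-limited static connectomics (leakage-corrected envelope correlation
#' connectomes, node power, global/network summaries), the envelope HMM
#' chain (windowed downsampling, normalization, concatenation, PCA
#' prewhitening, K-state HMM with restarts, Viterbi decoding, temporal
#' metrics, state power maps), and the group statistics families with their
#' Bonferroni factors. All tables are written as tab-delimited text under
#' `out_dir` together with a run manifest (config hash, seed, versions);
#' rerunning with the same configuration and seed reproduces the outputs
#' bit for bit.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param recordings optional list of [recording()]s to analyse instead of
#'   synthesizing a cohort.
#' @return Invisibly, a list with the in-memory results: `manifest`,
#'   `summaries`, `connectomes`, `power`, `hmm`, `state_metrics`,
#'   `state_maps` and the `stats` tables.
#' @export
run_pipeline <- function(config, out_dir, recordings = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  parc <- rsn_parcellation()
  sp <- config$spectral

  # --- stage 1: cohort ------------------------------------------------
  if (is.null(recordings) && !is.null(config$cohort$manifest)) {
    recordings <- read_cohort(config$cohort$manifest)
  }
  if (is.null(recordings)) {
    configs <- config$cohort$configs %||%
      default_cohort_configs(config$cohort$n_per_group,
                             config$cohort$duration_s, config$cohort$fs,
                             parc = parc)
    recordings <- make_cohort(configs, seed = config$seed)
  }
  manifest <- attr(recordings, "manifest") %||% data.frame(
    subject = vapply(recordings, `[[`, character(1), "subject"),
    group = vapply(recordings, `[[`, character(1), "group"),
    sex = vapply(recordings, `[[`, character(1), "sex"),
    system = vapply(recordings, `[[`, character(1), "system"),
    fs = vapply(recordings, `[[`, numeric(1), "fs"),
    duration_s = vapply(recordings, function(r) ncol(r$data) / r$fs,
                        numeric(1)),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  if (config$write_recordings) {
    rec_dir <- file.path(out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
    for (r in recordings)
      write_tsv(as.data.frame(signif(r$data, 6)),
                file.path(rec_dir, paste0(r$subject, ".tsv")), col_names = FALSE)
  }
  groups <- factor(manifest$group, levels = unique(manifest$group))
  n_sub <- length(recordings)

  # --- stage 2: static connectomics ----------------------------------
  conn_dir <- file.path(out_dir, "connectomes")
  dir.create(conn_dir, showWarnings = FALSE)
  connectomes <- list()
  power <- list()
  summaries <- list()
  long_rows <- list()
  pairs <- connection_pairs(parc)
  for (b in config$bands) {
    for (si in seq_len(n_sub)) {
      rec <- recordings[[si]]
      conn <- build_connectome(rec, b, parc, cutoff = sp$lp_cutoff,
                               edge_s = sp$edge_s)
      pw <- node_power(rec, b, edge_s = sp$edge_s)
      key <- paste(rec$subject, b, sep = ".")
      connectomes[[key]] <- conn
      power[[key]] <- pw
      summaries[[key]] <- summarize_connectome(conn, pw, parc)
      write_tsv(as.data.frame(signif(unclass(conn), 6)),
                file.path(conn_dir, paste0(key, ".tsv")))
      long_rows[[key]] <- data.frame(
        subject = rec$subject, band = b,
        node_i = parc$label[pairs$i], node_j = parc$label[pairs$j],
        r = signif(conn[cbind(pairs$i, pairs$j)], 6),
        stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  write_tsv(num6(summaries), file.path(out_dir, "summaries.tsv"))
  write_tsv(do.call(rbind, long_rows), file.path(out_dir, "connectome_long.tsv"))
  power_tab <- do.call(rbind, lapply(names(power), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(subject = parts[1], band = parts[2], node = parc$label,
               power = signif(power[[k]], 6), stringsAsFactors = FALSE)
  }))
  write_tsv(power_tab, file.path(out_dir, "power.tsv"))

  # --- stage 3: envelope HMM -----------------------------------------
  hmm_envs <- lapply(recordings, function(rec) {
    env <- envelope(bandpass(rec$data, rec$fs, config$hmm_band,
                             order = sp$filter_order),
                    rec$fs, band = config$hmm_band, subject = rec$subject,
                    edge_s = sp$edge_s)
    trimmed <- env$values[, keep_idx(env), drop = FALSE]
    window_average_downsample(trimmed, sp$window_width_s, sp$window_step_s,
                              fs = rec$fs)
  })
  fs_states <- 1 / sp$window_step_s
  run_hmm_chain <- function(env_list) {
    norm <- lapply(env_list, normalize_subject)
    pca <- concat_pca_prewhiten(norm, n_pcs = config$hmm$n_pcs)
    fit <- fit_hmm(pca, K = config$hmm$K, n_restarts = config$hmm$n_restarts,
                   max_iter = config$hmm$max_iter, tol = config$hmm$tol,
                   seed = config$seed, fs_states = fs_states)
    paths <- viterbi_path(fit, pca$scores, pca$boundaries)
    metrics <- do.call(rbind, lapply(names(paths), function(s) {
      cbind(subject = s, temporal_metrics(paths[[s]]))
    }))
    maps <- state_power_maps(paths, do.call(cbind, norm))
    list(fit = fit, paths = paths, metrics = metrics, maps = maps)
  }
  if (config$hmm$grouping == "pooled") {
    hmm_res <- run_hmm_chain(hmm_envs)
  } else {
    hmm_res <- lapply(split(seq_len(n_sub), groups),
                      function(idx) run_hmm_chain(hmm_envs[idx]))
  }
  hmm_dir <- file.path(out_dir, "hmm")
  dir.create(hmm_dir, showWarnings = FALSE)
  flatten_hmm <- function(res, tag = NULL) {
    metrics <- res$metrics
    maps_tab <- data.frame(
      state = rep(seq_len(nrow(res$maps)), ncol(res$maps)),
      node = rep(parc$label, each = nrow(res$maps)),
      partial_r = signif(as.vector(res$maps), 6), stringsAsFactors = FALSE)
    if (!is.null(tag)) {
      metrics$group <- tag
      maps_tab$group <- tag
    }
    for (s in names(res$paths))
      write_tsv(as.data.frame(unclass(res$paths[[s]])),
                file.path(hmm_dir, paste0("path_", s, ".tsv")),
                col_names = FALSE)
    list(metrics = metrics, maps = maps_tab)
  }
  if (config$hmm$grouping == "pooled") {
    flat <- flatten_hmm(hmm_res)
    state_metrics <- flat$metrics
    state_maps <- flat$maps
  } else {
    flats <- Map(flatten_hmm, hmm_res, names(hmm_res))
    state_metrics <- do.call(rbind, lapply(flats, `[[`, "metrics"))
    state_maps <- do.call(rbind, lapply(flats, `[[`, "maps"))
  }
  write_tsv(num6(state_metrics), file.path(out_dir, "state_metrics.tsv"))
  write_tsv(state_maps, file.path(out_dir, "state_maps.tsv"))

  # --- stage 4: group statistics -------------------------------------
  covar_base <- manifest[, c("sex", "system")]
  global_power <- vapply(config$bands, function(b) {
    vapply(manifest$subject, function(s)
      mean(power[[paste(s, b, sep = ".")]]), numeric(1))
  }, numeric(n_sub))
  stats_out <- list()
  feat_mat <- function(scope_filter, col) {
    sub <- summaries[summaries$scope %in% scope_filter, ]
    out <- sapply(split(sub, list(sub$scope, sub$band), drop = TRUE),
                  function(d) d[[col]][match(manifest$subject, d$subject)])
    matrix(out, nrow = n_sub,
           dimnames = list(manifest$subject, colnames(out)))
  }
  run_conn_family <- function(values, family, factor = NULL) {
    # band-specific global power as the power confound, per feature band
    res <- lapply(colnames(values), function(f) {
      b <- sub(".*\\.", "", f)
      cov_f <- cbind(covar_base, power = global_power[, b])
      run_family(values[, f, drop = FALSE], groups, family,
                 covariates = cov_f, factor = factor,
                 alpha = config$stats$alpha)
    })
    do.call(rbind, res)
  }
  nets <- levels(parc$network)
  stats_out$global_connectivity <-
    run_conn_family(feat_mat("global", "connectivity"), "global")
  stats_out$global_power <-
    run_family(feat_mat("global", "power"), groups, "global",
               covariates = covar_base, alpha = config$stats$alpha)
  stats_out$network_connectivity <-
    run_conn_family(feat_mat(nets, "connectivity"), "network")
  stats_out$network_power <-
    run_family(feat_mat(nets, "power"), groups, "network",
               covariates = covar_base, alpha = config$stats$alpha)
  conn_feats <- sapply(config$bands, function(b) {
    sapply(seq_len(nrow(pairs)), function(pi) {
      vapply(manifest$subject, function(s)
        connectomes[[paste(s, b, sep = ".")]][pairs$i[pi], pairs$j[pi]],
        numeric(1))
    })
  })
  conn_feats <- matrix(conn_feats, nrow = n_sub)
  colnames(conn_feats) <- as.vector(outer(
    paste(parc$label[pairs$i], parc$label[pairs$j], sep = "-"),
    config$bands, paste, sep = "."))
  n_eff <- config$stats$n_eff
  conn_factor <- bonferroni_factor("connectome", n_bands = length(config$bands),
                                   n_connections = nrow(pairs), n_eff = n_eff)
  stats_out$connectome <- run_conn_family(conn_feats, "connectome",
                                          factor = conn_factor)
  if (config$hmm$grouping == "pooled") {
    sm <- state_metrics
    hmm_feats <- do.call(cbind, lapply(c("MLT_s", "FO", "MIL_s"), function(m) {
      out <- sapply(seq_len(config$hmm$K), function(k) {
        d <- sm[sm$state == k, ]
        d[[m]][match(manifest$subject, d$subject)]
      })
      colnames(out) <- paste0(m, ".state", seq_len(config$hmm$K))
      out
    }))
    stats_out$hmm <- run_family(hmm_feats, groups, "hmm_states",
                                covariates = covar_base, K = config$hmm$K,
                                alpha = config$stats$alpha)
  }
  for (nm in names(stats_out))
    write_tsv(num6(stats_out[[nm]]),
              file.path(out_dir, paste0("stats_", nm, ".tsv")))

  # --- run manifest ---------------------------------------------------
  tf <- tempfile()
  saveRDS(config, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  yaml::write_yaml(list(config_md5 = hash, seed = config$seed,
                        package = as.character(utils::packageVersion("envdyn")),
                        r_version = paste(R.version$major, R.version$minor,
                                          sep = ".")),
                   file.path(out_dir, "run_manifest.yaml"))
  invisible(list(manifest = manifest, summaries = summaries,
                 connectomes = connectomes, power = power, hmm = hmm_res,
                 state_metrics = state_metrics, state_maps = state_maps,
                 stats = stats_out, config = config))
}

write_tsv <- function(df, path, col_names = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col_names)
}

num6 <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}
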