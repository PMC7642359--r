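#' Write and read cohorts as delimited text
#'
#' A cohort on disk is one tab-delimited regions x samples matrix per
#' subject (no header) plus a `manifest.tsv` table with columns `subject`,
#' `group`, `sex`, `system`, `fs`, `duration_s`, `file`.
#'
#' @param recordings list of [recording()]s, e.g. from [make_cohort()].
#' @param dir output directory (created if needed).
#' @param digits significant digits written (default 6).
#' @return `write_cohort()` returns the manifest invisibly; `read_cohort()`
#'   returns a list of recordings with the manifest attached as an
#'   attribute, ready for [run_pipeline()].
#' @export
write_cohort <- function(recordings, dir, digits = 6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- attr(recordings, "manifest")
  if (is.null(manifest)) {
    manifest <- do.call(rbind, lapply(recordings, function(r) {
      data.frame(subject = r$subject, group = r$group, sex = r$sex,
                 system = r$system, fs = r$fs,
                 duration_s = ncol(r$data) / r$fs, stringsAsFactors = FALSE)
    }))
    rownames(manifest) <- NULL
  }
  manifest$file <- paste0(manifest$subject, ".tsv")
  for (r in recordings)
    write.table(signif(r$data, digits),
                file.path(dir, paste0(r$subject, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @param manifest_path path to a cohort `manifest.tsv` (subject files are
#'   resolved relative to its directory).
#' @export
read_cohort <- function(manifest_path) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, "manifest.tsv")
  if (!file.exists(manifest_path))
    stop_envdyn("manifest not found: %s", manifest_path)
  manifest <- read.table(manifest_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("subject", "group", "sex", "system", "fs", "file")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop_envdyn("manifest lacks column(s): %s", paste(missing, collapse = ", "))
  base <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    x <- as.matrix(read.table(file.path(base, m$file), sep = "\t"))
    dimnames(x) <- NULL
    recording(x, m$fs, subject = m$subject, group = m$group, sex = m$sex,
              system = m$system)
  })
  names(recs) <- manifest$subject
  attr(recs, "manifest") <- manifest[, setdiff(names(manifest), "file")]
  recs
}
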