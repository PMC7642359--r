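#' Frequency band specification
#'
#' A band is a named frequency interval in Hz. The canonical resting-state
#' bands used throughout the package are theta (4-8 Hz), alpha (8-12 Hz),
#' beta (12-30 Hz) and the wide 4-30 Hz band that spans them.
#'
#' @param name band label, e.g. `"alpha"`.
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return An object of class `band_spec`: a list with `name`, `lo`, `hi`.
#' @examples
#' band_spec("alpha", 8, 12)
#' canonical_bands()$theta
#' @export
band_spec <- function(name, lo, hi) {
  if (!is.character(name) || length(name) != 1L)
    stop_envdyn("band name must be a single string")
  check_scalar(lo, "lo")
  check_scalar(hi, "hi")
  if (!(lo > 0 && hi > lo))
    stop_envdyn("band edges must satisfy 0 < lo < hi (got [%g, %g])", lo, hi)
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' @rdname band_spec
#' @export
canonical_bands <- function() {
  list(
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 12),
    beta  = band_spec("beta", 12, 30),
    wide  = band_spec("wide", 4, 30)
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1L) {
    cb <- canonical_bands()
    if (band %in% names(cb)) return(cb[[band]])
    stop_envdyn("unknown band name '%s' (known: %s)", band,
                paste(names(cb), collapse = ", "))
  }
  stop_envdyn("`band` must be a band_spec or a canonical band name")
}
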