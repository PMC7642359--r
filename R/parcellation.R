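#' Resting-state network parcellation
#'
#' The default parcellation covers 32 regions of interest drawn from six
#' canonical resting-state networks: dorsal attention (DAN, 6 nodes), ventral
#' attention (VAN, 5), default-mode (DMN, 7), primary visual (pVIS, 2 nodes:
#' left and right V1), sensorimotor (MOT, 6) and language (LAN, 6). Only node
#' labels and network membership are carried; no anatomical coordinates.
#'
#' @param networks named list mapping network name to a character vector of
#'   unique node labels. Defaults to the 32-node / 6-network parcellation.
#' @return An object of class `parcellation`: a data frame with columns
#'   `node` (1-based index), `label` and `network` (factor, network order
#'   preserved).
#' @examples
#' parc <- rsn_parcellation()
#' table(parc$network)
#' @export
rsn_parcellation <- function(networks = default_networks()) {
  if (!is.list(networks) || is.null(names(networks)) || any(names(networks) == ""))
    stop_envdyn("`networks` must be a named list of node-label vectors")
  if (anyDuplicated(names(networks)))
    stop_envdyn("duplicate network names")
  labels <- unlist(networks, use.names = FALSE)
  if (anyDuplicated(labels))
    stop_envdyn("node labels must be unique across networks")
  parc <- data.frame(
    node = seq_along(labels),
    label = labels,
    network = factor(rep(names(networks), lengths(networks)),
                     levels = names(networks)),
    stringsAsFactors = FALSE
  )
  class(parc) <- c("parcellation", "data.frame")
  parc
}

#' @rdname rsn_parcellation
#' @export
default_networks <- function() {
  list(
    DAN  = c("lFEF", "rFEF", "lIPS", "rIPS", "lMT", "rMT"),
    VAN  = c("rTPJ", "rVFC", "rSMG", "rIFGop", "rMFG"),
    DMN  = c("mPFC", "PCC", "Prec", "lAG", "rAG", "lLTC", "rLTC"),
    pVIS = c("lV1", "rV1"),
    MOT  = c("lM1", "rM1", "lS1", "rS1", "SMA", "preSMA"),
    LAN  = c("lIFG", "rIFG", "lpSTG", "rpSTG", "lMTG", "rMTG")
  )
}

#' Enumerate unordered node pairs of a parcellation
#'
#' @param parc a [rsn_parcellation()] object.
#' @return Data frame with one row per unordered node pair (columns `i`, `j`
#'   with `i < j`), a logical `within` flag and, for within-network pairs,
#'   the `network` name (`NA` for cross-network pairs). For the default
#'   parcellation this has 496 rows, 77 within-network and 419 cross-network.
#' @examples
#' nrow(connection_pairs(rsn_parcellation()))
#' @export
connection_pairs <- function(parc) {
  n <- nrow(parc)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same <- as.character(parc$network[i]) == as.character(parc$network[j])
  data.frame(
    i = i, j = j, within = same,
    network = ifelse(same, as.character(parc$network[i]), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' @export
print.parcellation <- function(x, ...) {
  counts <- table(x$network)
  cat(sprintf("<parcellation> %d nodes, %d networks (%s)\n", nrow(x),
              nlevels(x$network),
              paste(sprintf("%s:%d", names(counts), counts), collapse = ", ")))
  invisible(x)
}
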