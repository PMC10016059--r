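#' Default reduced EEG montage
#'
#' A 16-channel montage laid out on a schematic 10-10 grid, with named
#' fronto-central and posterior channel groups.  The full 61-channel cap used
#' in typical recordings is reduced to a desk-scale set that preserves the
#' topography the analysis cares about: a fronto-central region where theta
#' synchronization is maximal and a parieto-occipital region where alpha/beta
#' desynchronization is maximal.
#'
#' @return A data frame with columns `channel`, `x`, `y` (schematic scalp
#'   coordinates, arbitrary units) and `region` (one of `"frontocentral"`,
#'   `"central"`, `"posterior"`).
#' @seealso [channel_neighbors()] for the neighborhood graph derived from the
#'   coordinates.
#' @export
#' @examples
#' m <- default_montage()
#' table(m$region)
default_montage <- function() {
  data.frame(
    channel = c("F3", "Fz", "F4", "FC1", "FCz", "FC2",
                "C3", "Cz", "C4", "P3", "Pz", "P4",
                "PO3", "POz", "PO4", "Oz"),
    x = c(-1, 0, 1, -0.5, 0, 0.5,
          -1, 0, 1, -1, 0, 1,
          -0.5, 0, 0.5, 0),
    y = c(3, 3, 3, 2, 2, 2,
          1, 1, 1, 0, 0, 0,
          -1, -1, -1, -2),
    region = c(rep("frontocentral", 6),
               "central", "frontocentral", "central",
               rep("posterior", 7)),
    stringsAsFactors = FALSE
  )
}

#' Build a channel neighborhood graph from montage coordinates
#'
#' Two channels are neighbors when their schematic scalp distance is at most
#' `max_dist`.  The resulting adjacency is symmetric and has no self-loops;
#' it plays the role of the sensor-neighborhood template used by
#' cluster-based permutation statistics.
#'
#' @param montage Data frame as returned by [default_montage()].
#' @param max_dist Distance cutoff in montage units.
#' @return Named list mapping each channel to a character vector of neighbors.
#' @export
channel_neighbors <- function(montage = default_montage(), max_dist = 1.3) {
  stopifnot(is.data.frame(montage), all(c("channel", "x", "y") %in% names(montage)))
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  adj <- lapply(seq_len(nrow(montage)), function(i) {
    montage$channel[d[i, ] > 0 & d[i, ] <= max_dist]
  })
  names(adj) <- montage$channel
  validate_neighbors(adj)
  adj
}

#' Validate a neighborhood graph
#'
#' Checks symmetry and the absence of self-loops; stops with an informative
#' error otherwise.
#'
#' @param adj Named list: channel -> character vector of neighbor channels.
#' @return `adj`, invisibly.
#' @export
validate_neighbors <- function(adj) {
  stopifnot(is.list(adj), !is.null(names(adj)))
  for (ch in names(adj)) {
    nb <- adj[[ch]]
    if (ch %in% nb)
      stop("neighborhood graph has a self-loop at channel ", ch)
    for (other in nb) {
      if (!other %in% names(adj) || !ch %in% adj[[other]])
        stop("neighborhood graph is not symmetric: ", ch, " -> ", other)
    }
  }
  invisible(adj)
}

#' Read and write neighborhood graphs as JSON adjacency
#'
#' The on-disk format is a single JSON object mapping each channel label to an
#' array of neighbor labels.
#'
#' @param adj Named list adjacency (see [channel_neighbors()]).
#' @param path File path.
#' @return `read_neighbors()` returns the validated adjacency list.
#' @export
write_neighbors <- function(adj, path) {
  validate_neighbors(adj)
  jsonlite::write_json(adj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_neighbors
#' @export
read_neighbors <- function(path) {
  adj <- jsonlite::read_json(path, simplifyVector = TRUE)
  adj <- lapply(adj, as.character)
  validate_neighbors(adj)
  adj
}
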