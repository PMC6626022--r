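#' Morphometry of labelled regions
#'
#' Area (pixel count) plus length and width defined as the major and minor
#' axis lengths of the second-moment ellipse of the mask -- the standard
#' region-property convention (`4 * sqrt(eigenvalue)` of the coordinate
#' covariance), rotation-invariant by construction.
#'
#' @param labels Integer label matrix.
#' @return Data frame: `label`, `area`, `length`, `width`, `centroid_r`,
#'   `centroid_c`.
#' @export
mm_measure_regions <- function(labels) {
  n <- max(labels)
  out <- data.frame(label = seq_len(n), area = NA_real_,
                    length = NA_real_, width = NA_real_,
                    centroid_r = NA_real_, centroid_c = NA_real_)
  for (id in seq_len(n)) {
    px <- label_pixels(labels, id)
    m <- nrow(px)
    if (m == 0) next
    mu <- colMeans(px)
    if (m == 1) {
      out[id, -1] <- c(1, 1, 1, mu)
      next
    }
    d <- sweep(px, 2, mu)
    cov <- crossprod(d) / m
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    ev[ev < 0] <- 0
    out[id, -1] <- c(m, 4 * sqrt(ev[1]), 4 * sqrt(ev[2]), mu)
  }
  out
}

#' Background-subtracted fluorescence per bacterium
#'
#' The background of each channel is the mean fluorescence over the empty
#' parts of the channel (channel mask minus all bacteria masks); every
#' bacterium's reported value is its mean fluorescence minus that
#' background. A fully occupied channel borrows the mean background of the
#' frame's other channels, with a warning.
#'
#' @param bacteria_labels Integer label matrix for one channel (crop).
#' @param channel_mask Logical matrix, the channel pixels in the same crop.
#' @param fluo_image Numeric matrix, the fluorescence crop.
#' @param fallback_background Frame-level background used when the channel
#'   has no empty pixels (`NA` to error instead).
#' @return Data frame: `label`, `mean` (background-subtracted), `total`
#'   (background-subtracted summed intensity), `background`.
#' @export
mm_measure_fluorescence <- function(bacteria_labels, channel_mask, fluo_image,
                                    fallback_background = NA_real_) {
  stopifnot(identical(dim(bacteria_labels), dim(fluo_image)))
  empty <- channel_mask & bacteria_labels == 0L
  if (any(empty)) {
    bg <- mean(fluo_image[empty])
  } else if (!is.na(fallback_background)) {
    warning("channel fully occupied; using background from other channels")
    bg <- fallback_background
  } else {
    stop("channel fully occupied and no fallback background available")
  }
  n <- max(bacteria_labels)
  out <- data.frame(label = seq_len(n), mean = NA_real_, total = NA_real_,
                    background = bg)
  for (id in seq_len(n)) {
    v <- fluo_image[bacteria_labels == id]
    out$mean[id] <- mean(v) - bg
    out$total[id] <- sum(v - bg)
  }
  out
}

#' Assemble the lineage-resolved measurement table
#'
#' Joins the track graph with the per-frame measurements into one row per
#' bacterium per time point, ordered by lineage id then frame, with
#' `parent_id` and `event` taken from the graph edges. Data bifurcations in
#' the resulting per-lineage time series are divisions.
#'
#' @param graph An `mm_track_graph` (see [mm_analyze()]).
#' @param measurements Data frame with one row per (frame, channel, label)
#'   and measurement columns.
#' @return Data frame of measurement records.
#' @export
mm_build_lineage_table <- function(graph, measurements) {
  nodes <- graph$nodes
  key_n <- paste(nodes$frame, nodes$channel_id, nodes$label)
  key_m <- paste(measurements$frame_index, measurements$channel_id,
                 measurements$bacterium_label)
  if (!all(key_m %in% key_n)) {
    stop("orphan measurement: no matching track-graph node")
  }
  idx <- match(key_m, key_n)
  out <- cbind(measurements,
               nodes[idx, c("global_id", "parent_id", "event", "fate")])
  out <- out[order(out$global_id, out$frame_index), ]
  rownames(out) <- NULL
  out
}
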