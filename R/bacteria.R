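#' Invert a channel image and subtract its background
#'
#' Bacteria appear darker than the background in both brightfield and phase
#' contrast, so the channel crop is inverted to make them bright, and the
#' slowly varying background of the inverted image -- estimated with a
#' rolling-ball (grayscale opening) filter -- is subtracted. After this step
#' the cells sit on an approximately zero background wherever they are along
#' the channel profile, so one segmentation recipe works for the whole
#' channel.
#'
#' @param channel_image Numeric matrix: crop of the detection plane around
#'   one channel.
#' @param mask Logical matrix marking the channel pixels within the crop
#'   (`NULL` = all pixels). Pixels outside are replaced by the in-mask median
#'   before inversion so that walls do not leak into the background estimate.
#' @param cfg An [mm_config()].
#' @return Matrix of background-subtracted, inverted intensities (>= 0).
#' @export
mm_subtract_background <- function(channel_image, mask = NULL,
                                   cfg = mm_config()) {
  x <- channel_image
  if (!is.null(mask)) {
    med <- stats::median(x[mask])
    x[!mask] <- med
  }
  inv <- max(x) - x
  bg <- gray_open(inv, cfg$rolling_ball_radius)
  out <- inv - bg
  out[out < 0] <- 0
  out
}

#' Scale-space Laplacian-of-Gaussian filter
#'
#' Convolves the image with a scale-normalised Laplacian of Gaussian at each
#' scale and max-projects along the scale axis, so blobs and rods of
#' different sizes all reach their best response. The sign is chosen so
#' bright structures on a dark background score positive.
#'
#' @param image Numeric matrix (inverted, background-subtracted channel).
#' @param scales Gaussian sigmas, px.
#' @return Response matrix (max projection over scales).
#' @export
mm_scale_space_filter <- function(image, scales = mm_config()$log_scales) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  out <- NULL
  for (s in scales) {
    g <- gauss_blur(image, s)
    r <- -s^2 * conv2(g, lap) # scale-normalised, bright-positive
    out <- if (is.null(out)) r else pmax(out, r)
  }
  out
}

#' Initial bacteria segmentation of one channel
#'
#' Binarises the scale-space response at a frame-level threshold, generates
#' watershed markers from all pixels farther than `marker_distance` from the
#' mask background (distance transform), delineates touching cells with a
#' marker-controlled watershed on the response, and filters the resulting
#' regions by width and area.
#'
#' @param response Response from [mm_scale_space_filter()].
#' @param threshold Binarisation threshold; computed once per frame over the
#'   pooled channel responses (see [mm_detect_bacteria()]) so empty channels
#'   are not over-segmented.
#' @param cfg An [mm_config()].
#' @return Integer label matrix (0 = background).
#' @export
mm_segment_initial <- function(response, threshold, cfg = mm_config()) {
  mask <- response > threshold
  if (!any(mask)) return(matrix(0L, nrow(response), ncol(response)))
  # specks below the minimum bacterium area never seed nor join a region
  comp <- label_components(mask)
  areas <- label_areas(comp)
  mask <- mask & areas[pmax(comp, 1L)] >= cfg$bacteria_area_range[1] & comp > 0L
  if (!any(mask)) return(matrix(0L, nrow(response), ncol(response)))
  dt <- dist_transform(mask)
  markers <- label_components(dt >= cfg$marker_distance)
  if (max(markers) == 0L) return(matrix(0L, nrow(response), ncol(response)))
  lab <- as.matrix(EBImage::propagate(response, seeds = markers, mask = mask))
  storage.mode(lab) <- "integer"
  filter_regions(lab, cfg)
}

# width/area filter; width = 2 x max inscribed-disc radius of the region
filter_regions <- function(lab, cfg) {
  n <- max(lab)
  if (n == 0L) return(lab)
  areas <- label_areas(lab)
  dt <- dist_transform(lab > 0L)
  keep <- integer(0)
  for (id in seq_len(n)) {
    if (areas[id] < cfg$bacteria_area_range[1] ||
        areas[id] > cfg$bacteria_area_range[2]) next
    wid <- 2 * max(dt[lab == id])
    if (wid < cfg$bacteria_width_range[1] ||
        wid > cfg$bacteria_width_range[2]) next
    keep <- c(keep, id)
  }
  relabel_keep(lab, keep)
}

#' Robust split thresholds from all initially detected bacteria
#'
#' Median and median absolute deviation of the skeleton-local widths and
#' intensities pooled over every initially detected bacterium of the frame.
#' A split is declared only where the local width falls below
#' `median_width - k * mad_width` *and* the local intensity below
#' `median_intensity - k * mad_intensity`.
#'
#' @param skeleton_stats Data frame with columns `width`, `intensity`
#'   (one row per skeleton pixel, pooled across the frame's bacteria).
#' @param k MAD multiplier.
#' @return List of class `mm_split_thresholds`.
#' @export
mm_split_thresholds <- function(skeleton_stats, k = 2) {
  med_w <- stats::median(skeleton_stats$width)
  mad_w <- stats::mad(skeleton_stats$width, constant = 1)
  med_i <- stats::median(skeleton_stats$intensity)
  mad_i <- stats::mad(skeleton_stats$intensity, constant = 1)
  # floor the MADs: on a homogeneous population the raw MAD collapses
  # towards zero, which would turn "below median - k*MAD" into "below
  # median" and cut cells at every noise dip or illumination difference
  # between channels. A genuine division neck constricts and dims to about
  # half the body values, far below a 15%-of-median floor.
  mad_w_eff <- max(mad_w, 0.15 * med_w)
  mad_i_eff <- max(mad_i, 0.15 * abs(med_i))
  structure(list(median_width = med_w, mad_width = mad_w,
                 median_intensity = med_i, mad_intensity = mad_i, k = k,
                 width_cut = med_w - k * mad_w_eff,
                 intensity_cut = med_i - k * mad_i_eff),
            class = "mm_split_thresholds")
}

#' Merge over-segmented fragments across bright interfaces
#'
#' The dual of the splitting criterion: a genuine boundary between two
#' cells passes through a dim gap, so the intensity profile across it shows
#' a valley. Two nearby regions whose interface zone has no dim valley --
#' its minimum (locally smoothed) intensity stays above the frame-level
#' intensity cut -- are fragments of one cell (a watershed boundary placed
#' inside a cell body, or a cap severed by a response dip) and are merged.
#' The skeleton-based splitting stage afterwards re-cuts merged regions at
#' any true gap they may span.
#'
#' @param labels Integer label matrix (one channel).
#' @param intensity_image Background-subtracted inverted channel image.
#' @param intensity_cut Frame-level dim-neck threshold (see
#'   [mm_split_thresholds()]).
#' @param channel_mask Logical matrix restricting the interface zone to the
#'   channel (`NULL` = everywhere).
#' @return Integer label matrix with fragments merged and labels compacted.
#' @export
mm_merge_fragments <- function(labels, intensity_image, intensity_cut,
                               channel_mask = NULL) {
  n <- max(labels)
  if (n < 2L) return(labels)
  smoothed <- conv2(intensity_image, matrix(1 / 9, 3, 3))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  masks <- lapply(seq_len(n), function(id) labels == id)
  dil <- lapply(masks, dilate_mask, radius = 2)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      zone <- dil[[i]] & dil[[j]]
      if (!is.null(channel_mask)) zone <- zone & channel_mask
      if (!any(zone)) next
      if (min(smoothed[zone]) > intensity_cut) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  new_id <- match(root, unique(root))
  out <- labels
  pos <- labels > 0L
  out[pos] <- new_id[labels[pos]]
  out
}

#' Split adjacent bacteria along skeleton constrictions
#'
#' Each region is skeletonised and traversed; where the distance-transform
#' width and the local intensity both fall below their robust thresholds
#' (constriction *and* dim neck), the region is cut transversally and the
#' children receive fresh labels. Child regions partition the parent exactly.
#'
#' @param labels Integer label matrix (one channel).
#' @param intensity_image Background-subtracted inverted channel image used
#'   for the intensity criterion.
#' @param thresholds An [mm_split_thresholds()] computed over the whole
#'   frame; `NULL` computes them from this channel alone.
#' @param cfg An [mm_config()].
#' @return Refined integer label matrix.
#' @export
mm_split_adjacent <- function(labels, intensity_image, thresholds = NULL,
                              cfg = mm_config()) {
  n <- max(labels)
  if (n == 0L) return(labels)
  if (is.null(thresholds)) {
    st <- skeleton_stats_frame(list(labels), list(intensity_image))
    if (nrow(st) == 0) return(labels)
    thresholds <- mm_split_thresholds(st, cfg$split_k)
  }
  dt <- dist_transform(labels > 0L)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 1L
  for (id in seq_len(n)) {
    mask <- labels == id
    path <- skeleton_path(mask)
    pieces <- list(mask)
    if (!is.null(path) && nrow(path) >= 5) {
      wid <- 2 * dt[path]
      inten <- smooth_along(intensity_image[path], cfg$split_window)
      hit <- wid < thresholds$width_cut & inten < thresholds$intensity_cut
      hit[seq_len(min(2, length(hit)))] <- FALSE # never split at the caps
      hit[seq(max(1, length(hit) - 1), length(hit))] <- FALSE
      if (any(hit)) {
        runs <- rle(hit)
        ends <- cumsum(runs$lengths)
        cutpts <- integer(0)
        for (ri in which(runs$values & runs$lengths >= 2)) {
          cutpts <- c(cutpts, ends[ri] - runs$lengths[ri] %/% 2)
        }
        if (length(cutpts)) {
          pieces <- cut_region(mask, path, cutpts)
          # a genuine division separates two cell bodies: every child needs
          # some interior core, otherwise the "cut" only removed a thin
          # appendage and is merged back. One pixel of slack tolerates a
          # cut landing slightly inside a small cell's cap.
          pieces <- merge_invalid_pieces(pieces, dt, cfg$marker_distance - 1)
        }
      }
    }
    for (p in pieces) {
      out[p] <- nxt
      nxt <- nxt + 1L
    }
  }
  out
}

merge_invalid_pieces <- function(pieces, dt, core_width) {
  repeat {
    if (length(pieces) == 1L) break
    bad <- which(vapply(pieces, function(p) max(dt[p]) < core_width,
                        logical(1)))
    if (!length(bad)) break
    i <- bad[1]
    j <- if (i < length(pieces)) i + 1L else i - 1L
    pieces[[j]] <- pieces[[j]] | pieces[[i]]
    pieces[[i]] <- NULL
  }
  pieces
}

# assign region pixels to skeleton segments separated at `cutpts`
cut_region <- function(mask, path, cutpts) {
  seg_of <- findInterval(seq_len(nrow(path)), cutpts + 1L) + 1L
  px <- which(mask, arr.ind = TRUE)
  # nearest skeleton pixel decides the segment
  d2 <- outer(px[, 1], path[, 1], "-")^2 + outer(px[, 2], path[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  lapply(seq_len(max(seg_of)), function(sg) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    sel <- px[seg_of[nearest] == sg, , drop = FALSE]
    m[sel] <- TRUE
    m
  })
}

smooth_along <- function(x, w) {
  if (length(x) < w) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) -> y
  y[is.na(y)] <- x[is.na(y)]
  y
}

# pooled skeleton statistics over all channels of a frame
skeleton_stats_frame <- function(label_list, image_list) {
  rows <- list()
  for (i in seq_along(label_list)) {
    lab <- label_list[[i]]
    dt <- dist_transform(lab > 0L)
    for (id in seq_len(max(lab, 0L))) {
      path <- skeleton_path(lab == id)
      if (is.null(path)) next
      rows[[length(rows) + 1L]] <- data.frame(
        width = 2 * dt[path],
        intensity = image_list[[i]][path]
      )
    }
  }
  if (!length(rows)) return(data.frame(width = numeric(0),
                                       intensity = numeric(0)))
  do.call(rbind, rows)
}

#' Detect bacteria in every channel of a frame
#'
#' Per channel: background subtraction and inversion, scale-space filtering,
#' binarisation at a single frame-level minimum cross-entropy threshold
#' (pooled over all channel responses, which keeps empty channels empty),
#' marker-controlled watershed, width/area filtering, then skeleton-based
#' splitting of adjacent cells using frame-level robust thresholds.
#'
#' @param frame An `mm_frame` (or plain matrix, the detection plane).
#' @param channels An `mm_channel_set` for the same frame.
#' @param cfg An [mm_config()].
#' @return An object of class `mm_bacteria_set`: `bacteria` data frame
#'   (channel_id, label, centroid_r, centroid_c, area), `channel_labels`
#'   list of per-channel label matrices in crop coordinates with their
#'   `bbox`, and `labels`, a frame-sized matrix of per-frame unique labels.
#' @export
mm_detect_bacteria <- function(frame, channels, cfg = mm_config()) {
  img <- if (inherits(frame, "mm_frame")) frame$primary else frame
  ids <- channels$channels$id
  crops <- list(); resps <- list(); invs <- list(); boxes <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    px <- label_pixels(channels$labels, id)
    bbox <- c(max(1, min(px[, 1]) - 2), min(nrow(img), max(px[, 1]) + 2),
              max(1, min(px[, 2]) - 2), min(ncol(img), max(px[, 2]) + 2))
    crop <- img[bbox[1]:bbox[2], bbox[3]:bbox[4], drop = FALSE]
    cmask <- channels$labels[bbox[1]:bbox[2], bbox[3]:bbox[4],
                             drop = FALSE] == id
    inv <- mm_subtract_background(crop, cmask, cfg)
    inv[!cmask] <- 0
    # the channel mask is deliberately oversized and reaches onto the dark
    # walls; cells sit centred, so the mask margin holds only wall signal
    inv[dist_transform(cmask) < cfg$marker_distance] <- 0
    resp <- mm_scale_space_filter(inv, cfg$log_scales)
    resp[!cmask] <- min(resp[cmask])
    crops[[i]] <- crop; invs[[i]] <- inv; resps[[i]] <- resp
    boxes[[i]] <- bbox
  }
  masksel <- Map(function(i) {
    b <- boxes[[i]]
    channels$labels[b[1]:b[2], b[3]:b[4], drop = FALSE] == ids[i]
  }, seq_along(ids))
  pooled <- unlist(Map(function(r, m) r[m], resps, masksel))
  th <- tryCatch(mm_threshold_li(pooled), error = function(e) Inf)

  labs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    labs[[i]] <- mm_segment_initial(resps[[i]], th, cfg)
  }
  st <- skeleton_stats_frame(labs, invs)
  thr <- if (nrow(st) >= 5) mm_split_thresholds(st, cfg$split_k) else NULL
  rows <- list()
  frame_labels <- matrix(0L, nrow(img), ncol(img))
  offset <- 0L
  for (i in seq_along(ids)) {
    if (!is.null(thr)) {
      labs[[i]] <- mm_merge_fragments(labs[[i]], invs[[i]],
                                      thr$intensity_cut, masksel[[i]])
      labs[[i]] <- mm_split_adjacent(labs[[i]], invs[[i]], thr, cfg)
      labs[[i]] <- filter_regions(labs[[i]], cfg)
    }
    # channel masks are deliberately oversized and can include the dark
    # walls; wall strips segment as thin regions hugging the mask border
    # while true cells sit centred in the channel
    cdt <- dist_transform(masksel[[i]])
    keep <- integer(0)
    for (b in seq_len(max(labs[[i]]))) {
      if (stats::median(cdt[labs[[i]] == b]) >= cfg$marker_distance) {
        keep <- c(keep, b)
      }
    }
    labs[[i]] <- relabel_keep(labs[[i]], keep)
    lab <- labs[[i]]
    nb <- max(lab)
    if (nb > 0) {
      meas <- mm_measure_regions(lab)
      b <- boxes[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        channel_id = ids[i], label = seq_len(nb),
        frame_label = seq_len(nb) + offset,
        centroid_r = meas$centroid_r + b[1] - 1,
        centroid_c = meas$centroid_c + b[3] - 1,
        area = meas$area, length = meas$length, width = meas$width)
      sel <- lab > 0L
      sub <- frame_labels[b[1]:b[2], b[3]:b[4], drop = FALSE]
      sub[sel] <- lab[sel] + offset
      frame_labels[b[1]:b[2], b[3]:b[4]] <- sub
      offset <- offset + nb
    }
    labs[[i]] <- lab
  }
  bacteria <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel_id = integer(0), label = integer(0),
               frame_label = integer(0),
               centroid_r = numeric(0), centroid_c = numeric(0),
               area = numeric(0), length = numeric(0), width = numeric(0))
  rownames(bacteria) <- NULL
  structure(list(bacteria = bacteria,
                 channel_labels = Map(function(l, b) list(labels = l, bbox = b),
                                      labs, boxes),
                 channel_ids = ids,
                 labels = frame_labels,
                 inverted = Map(function(x, b) list(image = x, bbox = b),
                                invs, boxes)),
            class = "mm_bacteria_set")
}

#' @export
print.mm_bacteria_set <- function(x, ...) {
  cat(sprintf("mm_bacteria_set: %d bacteria in %d channel(s)\n",
              nrow(x$bacteria), length(x$channel_ids)))
  invisible(x)
}
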