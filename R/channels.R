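#' Ridge / edge filter for channel-wall enhancement
#'
#' Enhances the channel outlines prior to thresholding. Brightfield frames
#' use a multi-scale Frangi vesselness filter tuned to dark ridges (channel
#' walls are thin dark lines on a bright background); phase-contrast frames
#' use the Sobel gradient magnitude (walls are high-contrast edges).
#'
#' @param image Numeric matrix.
#' @param modality `"brightfield"` or `"phase"`.
#' @param cfg An [mm_config()].
#' @return Non-negative response matrix of the same size.
#' @export
mm_ridge_filter <- function(image, modality, cfg = mm_config()) {
  modality <- match.arg(modality, c("brightfield", "phase"))
  if (modality == "brightfield") {
    frangi_filter(image, scales = cfg$frangi_scales, beta = cfg$frangi_beta)
  } else {
    sobel_magnitude(image)
  }
}

# Frangi vesselness, dark-ridge polarity: per scale, the Hessian of the
# Gaussian-smoothed image is scale-normalised (x sigma^2); ridge pixels have
# a large positive cross-ridge eigenvalue. Responses are max-projected
# across scales.
frangi_filter <- function(image, scales, beta = 0.5) {
  k_rr <- matrix(c(1, -2, 1), ncol = 1)
  k_cc <- matrix(c(1, -2, 1), nrow = 1)
  k_rc <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3) / 4
  out <- matrix(0, nrow(image), ncol(image))
  for (s in scales) {
    g <- gauss_blur(image, s)
    drr <- conv2(g, k_rr) * s^2
    dcc <- conv2(g, k_cc) * s^2
    drc <- conv2(g, k_rc) * s^2
    s2 <- drr^2 + 2 * drc^2 + dcc^2 # squared Frobenius norm
    if (max(s2) <= 1e-20) next # flat image: nothing but numerical noise
    mu <- (drr + dcc) / 2
    sq <- sqrt(((drr - dcc) / 2)^2 + drc^2)
    l1 <- mu + sq # l1 >= l2
    l2 <- mu - sq
    # order by |.|: lam_big has larger magnitude
    swap <- abs(l2) > abs(l1)
    lam_big <- ifelse(swap, l2, l1)
    lam_sml <- ifelse(swap, l1, l2)
    rb2 <- (lam_sml / lam_big)^2
    cpar <- sqrt(max(s2)) / 2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cpar^2)))
    v[lam_big <= 0] <- 0 # dark ridges only
    v[!is.finite(v)] <- 0
    out <- pmax(out, v)
  }
  out
}

sobel_magnitude <- function(image) {
  kr <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) / 8
  gr <- conv2(image, kr)
  gc <- conv2(image, t(kr))
  sqrt(gr^2 + gc^2)
}

#' Li's minimum cross-entropy threshold
#'
#' Iterative fixed-point computation of the threshold minimising the cross
#' entropy between the image and its binarised version. The image is shifted
#' to a positive baseline before iterating, which makes the resulting
#' decision (`image > t`) invariant under affine intensity rescaling with
#' positive gain.
#'
#' @param image Numeric matrix or vector of intensities (non-constant).
#' @param tol Convergence tolerance as a fraction of the intensity range.
#' @return The threshold on the original intensity scale.
#' @export
mm_threshold_li <- function(image, tol = 1e-7) {
  x <- as.numeric(image)
  rng <- range(x)
  if (diff(rng) <= 0) stop("Li threshold undefined: image is constant")
  shift <- rng[1] - 1e-8 * diff(rng)
  y <- x - shift # strictly positive
  t_cur <- mean(y)
  eps <- tol * diff(rng)
  for (i in 1:200) {
    lo <- y[y <= t_cur]; hi <- y[y > t_cur]
    if (!length(lo) || !length(hi)) break
    m0 <- mean(lo); m1 <- mean(hi)
    t_new <- if (abs(m0 - m1) < .Machine$double.eps) {
      t_cur
    } else {
      (m0 - m1) / (log(m0) - log(m1))
    }
    if (abs(t_new - t_cur) < eps) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur + shift
}

#' Extract channel interiors from a thresholded ridge mask
#'
#' Connected components of the wall mask are filtered by area, dilated to
#' close small gaps in the outlines, hole-filled, and the interiors obtained
#' by subtracting the wall mask from the filled regions. The dilation is
#' undone after filling (morphological closing) so the interiors are not
#' biased inward, and holes left inside an interior by the ridge response of
#' the bacteria the channel hosts are re-filled: the interior must cover the
#' cells, which are segmented downstream within the channel mask.
#'
#' @param mask Logical matrix (wall/ridge mask).
#' @param cfg An [mm_config()].
#' @return Integer label matrix of candidate channel interiors.
#' @export
mm_extract_channel_regions <- function(mask, cfg = mm_config()) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  areas <- label_areas(lab)
  keep <- which(areas >= cfg$channel_area_range[1] &
                  areas <= cfg$channel_area_range[2])
  if (!length(keep)) return(matrix(0L, nrow(mask), ncol(mask)))
  outl <- matrix(FALSE, nrow(mask), ncol(mask))
  outl[lab %in% keep] <- TRUE
  dil <- dilate_mask(outl, cfg$dilation_radius)
  filled <- fill_holes(dil)
  core <- as.matrix(EBImage::erode(filled * 1, disc_brush(cfg$dilation_radius))) > 0
  interiors <- core & !outl
  # the ridge response of hosted bacteria can crack an interior into
  # fragments; a closing at just above the wall-gap scale reunites them
  r2 <- cfg$dilation_radius + 1L
  interiors <- fill_holes(dilate_mask(interiors, r2))
  interiors <- as.matrix(EBImage::erode(interiors * 1, disc_brush(r2))) > 0
  label_components(interiors)
}

#' Fit axis vectors to channel interiors and filter by geometry
#'
#' For each interior region the pair of boundary pixels farthest apart
#' defines the channel axis vector. Regions are kept when the vector length
#' falls in `channel_length_range` and the perpendicular extent in
#' `channel_width_range` (both already scale-adjusted by [mm_config()]).
#'
#' @param interiors Integer label matrix from [mm_extract_channel_regions()].
#' @param cfg An [mm_config()].
#' @return List: `channels` data frame (id, centroid_r, centroid_c, axis_r,
#'   axis_c, length, width), `labels` relabelled matrix matching the rows.
#' @export
mm_fit_channel_vectors <- function(interiors, cfg = mm_config()) {
  n <- max(interiors)
  rows <- list(); kept <- integer(0)
  for (id in seq_len(n)) {
    px <- label_pixels(interiors, id)
    if (nrow(px) < 4) next
    sub <- interiors[min(px[, 1]):max(px[, 1]), min(px[, 2]):max(px[, 2]),
                     drop = FALSE] == id
    bd <- which(mask_boundary(sub), arr.ind = TRUE)
    bd[, 1] <- bd[, 1] + min(px[, 1]) - 1L
    bd[, 2] <- bd[, 2] + min(px[, 2]) - 1L
    fp <- farthest_pair(bd)
    v <- fp$p2 - fp$p1
    len <- sqrt(sum(v^2))
    if (len < cfg$channel_length_range[1] || len > cfg$channel_length_range[2]) next
    u <- v / len
    if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
    o <- c(-u[2], u[1])
    proj <- bd %*% o
    wid <- diff(range(proj))
    if (wid < cfg$channel_width_range[1] || wid > cfg$channel_width_range[2]) next
    kept <- c(kept, id)
    rows[[length(rows) + 1L]] <- data.frame(
      centroid_r = mean(px[, 1]), centroid_c = mean(px[, 2]),
      axis_r = u[1] * len, axis_c = u[2] * len,
      length = len, width = wid
    )
  }
  if (!length(kept)) {
    return(list(channels = data.frame(), labels = matrix(0L, nrow(interiors),
                                                         ncol(interiors))))
  }
  df <- do.call(rbind, rows)
  df <- cbind(id = seq_len(nrow(df)), df)
  list(channels = df, labels = relabel_keep(interiors, kept))
}

farthest_pair <- function(pts) {
  # exact O(n^2) search on boundary pixels (regions are small)
  d2 <- as.matrix(stats::dist(pts))^2
  ij <- arrayInd(which.max(d2), dim(d2))
  list(p1 = pts[ij[1], ], p2 = pts[ij[2], ])
}

frame_rejected <- function(msg) {
  structure(class = c("mm_frame_rejected", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Interpolate missing channels and assemble the channel set
#'
#' Estimates the channel-to-channel spacing from the detected centroids,
#' fills interior gaps of approximately `m x` spacing with `m - 1` stamped
#' copies of the average detected channel shape, and renumbers all channels
#' left to right. Frames with fewer than `min_channels` detections are
#' rejected (a condition of class `mm_frame_rejected` is signalled) so a
#' batch run can skip them and continue.
#'
#' @param fit Result of [mm_fit_channel_vectors()].
#' @param dim_img Dimensions of the frame, `c(rows, cols)`.
#' @param cfg An [mm_config()].
#' @return An object of class `mm_channel_set`: `labels` (integer matrix),
#'   `channels` (data frame with `interpolated` flag), `mean_shape` (logical
#'   matrix stamp centred on its own centroid), `spacing_px`.
#' @export
mm_interpolate_channels <- function(fit, dim_img, cfg = mm_config()) {
  df <- fit$channels
  if (nrow(df) < cfg$min_channels) {
    stop(frame_rejected(sprintf(
      "unable to accurately detect channels: %d detected, need >= %d",
      nrow(df), cfg$min_channels)))
  }
  # common axis and cross-axis (ordering) directions
  u <- colMeans(df[, c("axis_r", "axis_c")] / df$length)
  u <- u / sqrt(sum(u^2))
  o <- c(-u[2], u[1])
  if (o[2] < 0 || (o[2] == 0 && o[1] < 0)) o <- -o
  s <- as.matrix(df[, c("centroid_r", "centroid_c")]) %*% o
  ord <- order(s)
  df <- df[ord, ]; s <- s[ord]
  labels <- fit$labels
  remap <- integer(nrow(df)); remap[ord] <- seq_len(nrow(df))
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  df$id <- seq_len(nrow(df))
  df$interpolated <- FALSE

  gaps <- diff(s)
  base <- min(gaps)
  mult <- pmax(1, round(gaps / base))
  spacing <- sum(gaps) / sum(mult)

  # average shape from well-detected channels only: interiors eaten by the
  # ridge response of crowded cells come out short and would truncate it
  good <- df$length >= 0.9 * stats::median(df$length)
  if (sum(good) < 2) good <- rep(TRUE, nrow(df))
  shape <- mean_channel_shape(labels, df[good, , drop = FALSE], u)

  # re-stamp truncated channels at their position predicted from the good
  # channels' centroids (collinear along the device), so the final region
  # covers the full channel wherever the interior was eaten
  if (any(!good)) {
    pred_r <- stats::lm(centroid_r ~ s_pos,
                        data = data.frame(centroid_r = df$centroid_r,
                                          s_pos = s)[good, ])
    pred_c <- stats::lm(centroid_c ~ s_pos,
                        data = data.frame(centroid_c = df$centroid_c,
                                          s_pos = s)[good, ])
    mean_len <- mean(df$length[good])
    mean_wid <- mean(df$width[good])
    for (i in which(!good)) {
      cen <- c(stats::predict(pred_r, data.frame(s_pos = s[i])),
               stats::predict(pred_c, data.frame(s_pos = s[i])))
      labels[labels == df$id[i]] <- 0L
      labels <- stamp_shape(labels, shape, cen, df$id[i])
      df$centroid_r[i] <- cen[1]; df$centroid_c[i] <- cen[2]
      df$axis_r[i] <- u[1] * mean_len; df$axis_c[i] <- u[2] * mean_len
      df$length[i] <- mean_len; df$width[i] <- mean_wid
    }
  }

  stamped <- list()
  for (i in seq_along(gaps)) {
    m <- round(gaps[i] / spacing)
    if (m >= 2 && abs(gaps[i] - m * spacing) <= cfg$spacing_tol * spacing) {
      for (q in seq_len(m - 1)) {
        frac <- q / m
        cen <- (1 - frac) * unlist(df[i, c("centroid_r", "centroid_c")]) +
          frac * unlist(df[i + 1, c("centroid_r", "centroid_c")])
        stamped[[length(stamped) + 1L]] <- cen
      }
    }
  }

  if (length(stamped)) {
    mean_len <- mean(df$length[!df$interpolated])
    mean_wid <- mean(df$width[!df$interpolated])
    for (cen in stamped) {
      id_new <- nrow(df) + 1L
      labels <- stamp_shape(labels, shape, cen, id_new)
      df <- rbind(df, data.frame(
        id = id_new, centroid_r = cen[1], centroid_c = cen[2],
        axis_r = u[1] * mean_len, axis_c = u[2] * mean_len,
        length = mean_len, width = mean_wid, interpolated = TRUE))
    }
    # renumber left-to-right including the stamped channels
    s_all <- as.matrix(df[, c("centroid_r", "centroid_c")]) %*% o
    ord <- order(s_all)
    remap <- integer(nrow(df)); remap[ord] <- seq_len(nrow(df))
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
    df <- df[ord, ]
    df$id <- seq_len(nrow(df))
  }
  rownames(df) <- NULL
  structure(list(labels = labels, channels = df, mean_shape = shape,
                 spacing_px = spacing, axis = u),
            class = "mm_channel_set")
}

# pixelwise-majority stamp of the detected interiors, each translated to a
# common centroid and rotated to the common axis direction
mean_channel_shape <- function(labels, df, u) {
  half <- 0L
  offs <- list()
  ang0 <- atan2(u[2], u[1])
  for (i in seq_len(nrow(df))) {
    px <- label_pixels(labels, df$id[i])
    ui <- c(df$axis_r[i], df$axis_c[i]) / df$length[i]
    da <- ang0 - atan2(ui[2], ui[1])
    rot <- matrix(c(cos(da), sin(da), -sin(da), cos(da)), 2, 2)
    rel <- sweep(px, 2, c(df$centroid_r[i], df$centroid_c[i]))
    rel <- round(rel %*% t(rot))
    offs[[i]] <- rel
    half <- max(half, max(abs(rel)))
  }
  sz <- 2L * half + 1L
  acc <- matrix(0L, sz, sz)
  for (rel in offs) {
    idx <- (rel[, 2] + half) * sz + rel[, 1] + half + 1L
    idx <- unique(idx)
    acc[idx] <- acc[idx] + 1L
  }
  acc > nrow(df) / 2
}

stamp_shape <- function(labels, shape, centre, id) {
  half <- (nrow(shape) - 1L) / 2L
  px <- which(shape, arr.ind = TRUE) - half - 1L # offsets about the centre
  rr <- round(centre[1]) + px[, 1]
  cc <- round(centre[2]) + px[, 2]
  ok <- rr >= 1 & rr <= nrow(labels) & cc >= 1 & cc <= ncol(labels)
  idx <- (cc[ok] - 1L) * nrow(labels) + rr[ok]
  idx <- idx[labels[idx] == 0L] # never overwrite detected channels
  labels[idx] <- id
  labels
}

#' Detect all microfluidic channels in a frame
#'
#' Full channel-detection pipeline: ridge/edge filtering, minimum
#' cross-entropy thresholding, interior extraction, axis-vector fitting and
#' geometric filtering, then spacing-based interpolation of undetected
#' channels with average-shape stamping. Works for tilted devices: no
#' horizontal-alignment assumption is made.
#'
#' @param image Numeric matrix (detection plane).
#' @param modality `"brightfield"`, `"phase"`, or `NULL` to auto-classify.
#' @param cfg An [mm_config()].
#' @return An `mm_channel_set`; signals `mm_frame_rejected` when fewer than
#'   `cfg$min_channels` channels are found.
#' @export
mm_detect_channels <- function(image, modality = NULL, cfg = mm_config()) {
  if (is.null(modality)) {
    modality <- if (cfg$modality == "auto") mm_classify_modality(image)
                else cfg$modality
  }
  resp <- mm_ridge_filter(image, modality, cfg)
  th <- mm_threshold_li(resp)
  mask <- resp > th
  interiors <- mm_extract_channel_regions(mask, cfg)
  fit <- mm_fit_channel_vectors(interiors, cfg)
  cs <- mm_interpolate_channels(fit, dim(image), cfg)
  cs$modality <- modality
  cs
}

#' @export
print.mm_channel_set <- function(x, ...) {
  cat(sprintf("mm_channel_set: %d channel(s) (%d interpolated), spacing %.1f px\n",
              nrow(x$channels), sum(x$channels$interpolated), x$spacing_px))
  invisible(x)
}
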