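#' Analyse a mother-machine time series
#'
#' End-to-end pipeline over an ordered list of frames from one area:
#' modality classification (per frame, reconciled by majority vote),
#' channel detection per frame, channel tracking across frames (global
#' cross-correlation shift + mutual nearest neighbours, channel ids made
#' stable over time), bacteria detection per channel, multiple-hypothesis
#' bacteria tracking, and extraction of the lineage-resolved measurement
#' table. Frames whose channel detection is rejected (fewer than
#' `cfg$min_channels` channels) are skipped with a warning and the run
#' continues; tracking then links the surviving neighbours.
#'
#' @param frames List of `mm_frame` objects (see [mm_load_frame()]), in
#'   chronological order, or an `mm_fixture_series`.
#' @param cfg An [mm_config()].
#' @return An object of class `mm_result`:
#' \describe{
#'   \item{modality}{The modality used (after majority vote / override).}
#'   \item{channel_sets}{Per-frame `mm_channel_set` (NULL when rejected),
#'     with channel ids remapped to stable track ids.}
#'   \item{bacteria_sets}{Per-frame `mm_bacteria_set` (NULL when rejected).}
#'   \item{graph}{`mm_track_graph`: `nodes` data frame (frame, channel_id,
#'     label, global_id, parent_id, event, fate).}
#'   \item{measurements}{Lineage-resolved measurement table, one row per
#'     bacterium per frame.}
#'   \item{shifts}{Per-frame cumulative `(dy, dx)` relative to the first
#'     accepted frame.}
#'   \item{skipped}{Indices of rejected frames.}
#' }
#' @export
mm_analyze <- function(frames, cfg = mm_config()) {
  if (inherits(frames, "mm_fixture_series")) frames <- frames$frames
  stopifnot(length(frames) >= 1)
  n <- length(frames)

  modality <- cfg$modality
  if (modality == "auto") {
    per_frame <- vapply(frames, function(f)
      mm_classify_modality(f$primary), character(1))
    modality <- resolve_modality(per_frame)
  }

  channel_sets <- vector("list", n)
  skipped <- integer(0)
  for (t in seq_len(n)) {
    cs <- tryCatch(
      mm_detect_channels(frames[[t]]$primary, modality, cfg),
      mm_frame_rejected = function(e) {
        warning(sprintf("frame %d skipped: %s", t, conditionMessage(e)))
        NULL
      })
    if (is.null(cs)) skipped <- c(skipped, t)
    channel_sets[[t]] <- cs
  }
  accepted <- setdiff(seq_len(n), skipped)
  if (!length(accepted)) stop("no frame passed channel detection")

  # --- channel tracking: remap per-frame channel ids to stable ids -------
  shifts <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("dy", "dx")))
  shifts[accepted[1], ] <- c(0, 0)
  first <- accepted[1]
  next_chan_id <- max(channel_sets[[first]]$channels$id) + 1L
  for (k in seq_along(accepted)[-1]) {
    t_prev <- accepted[k - 1]; t_curr <- accepted[k]
    sh <- mm_estimate_frame_shift(frames[[t_prev]]$primary,
                                  frames[[t_curr]]$primary, cfg)
    shifts[t_curr, ] <- shifts[t_prev, ] + c(sh$dy, sh$dx)
    cmap <- mm_track_channels(channel_sets[[t_prev]],
                              channel_sets[[t_curr]], sh)
    # relabel current channels to the stable ids of their predecessors
    remap <- integer(0)
    for (r in seq_len(nrow(cmap$matches))) {
      remap[[as.character(cmap$matches$curr_id[r])]] <-
        cmap$matches$prev_id[r]
    }
    for (q in cmap$unmatched_curr) {
      remap[[as.character(q)]] <- next_chan_id
      next_chan_id <- next_chan_id + 1L
    }
    channel_sets[[t_curr]] <- remap_channel_ids(channel_sets[[t_curr]], remap)
    attr(channel_sets[[t_curr]], "shift_from_prev") <- sh
  }

  # --- bacteria detection -------------------------------------------------
  bacteria_sets <- vector("list", n)
  for (t in accepted) {
    bacteria_sets[[t]] <- mm_detect_bacteria(frames[[t]], channel_sets[[t]],
                                             cfg)
  }

  # --- bacteria tracking --------------------------------------------------
  nodes <- list()
  gids <- integer(0)
  next_gid <- 1L
  lysed_all <- integer(0)
  for (k in seq_along(accepted)) {
    t <- accepted[k]
    bs <- bacteria_sets[[t]]
    if (k == 1) {
      for (i in seq_len(nrow(bs$bacteria))) {
        key <- paste0(bs$bacteria$channel_id[i], ":", bs$bacteria$label[i])
        gids[[key]] <- next_gid
        nodes[[length(nodes) + 1L]] <- data.frame(
          frame = t, channel_id = bs$bacteria$channel_id[i],
          label = bs$bacteria$label[i], global_id = next_gid,
          parent_id = NA_integer_, event = "new")
        next_gid <- next_gid + 1L
      }
      next
    }
    t_prev <- accepted[k - 1]
    sh <- attr(channel_sets[[t]], "shift_from_prev")
    ids_prev <- channel_sets[[t_prev]]$channels$id
    ids_curr <- channel_sets[[t]]$channels$id
    common <- intersect(ids_prev, ids_curr)
    cmap <- list(matches = data.frame(prev_id = common, curr_id = common),
                 unmatched_prev = setdiff(ids_prev, common),
                 unmatched_curr = setdiff(ids_curr, common))
    tr <- mm_track_bacteria(bacteria_sets[[t_prev]], bs, cmap,
                            channel_sets[[t_prev]], channel_sets[[t]],
                            sh, cfg, gids, next_gid)
    gids <- tr$gids
    next_gid <- tr$next_gid
    lysed_all <- c(lysed_all, tr$lysed)
    if (nrow(tr$events)) {
      ev <- tr$events
      ev$frame <- t
      nodes[[length(nodes) + 1L]] <- data.frame(
        frame = ev$frame, channel_id = ev$channel, label = ev$label,
        global_id = ev$global_id, parent_id = ev$parent_id, event = ev$event)
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(frame = integer(0), channel_id = integer(0),
               label = integer(0), global_id = integer(0),
               parent_id = integer(0), event = character(0))
  nodes$fate <- NA_character_
  if (length(lysed_all)) {
    last <- !duplicated(nodes$global_id, fromLast = TRUE)
    nodes$fate[last & nodes$global_id %in% lysed_all] <- "lysis"
  }
  graph <- structure(list(nodes = nodes), class = "mm_track_graph")

  measurements <- collect_measurements(frames, channel_sets, bacteria_sets,
                                       accepted, cfg)
  measurements <- mm_build_lineage_table(graph, measurements)

  structure(list(modality = modality, channel_sets = channel_sets,
                 bacteria_sets = bacteria_sets, graph = graph,
                 measurements = measurements, shifts = shifts,
                 skipped = skipped),
            class = "mm_result")
}

remap_channel_ids <- function(cs, remap) {
  old <- cs$channels$id
  new <- vapply(as.character(old), function(k) remap[[k]], integer(1))
  labels <- cs$labels
  pos <- labels > 0L
  lut <- integer(max(old))
  lut[old] <- new
  labels[pos] <- lut[labels[pos]]
  cs$labels <- labels
  cs$channels$id <- new
  ord <- order(new)
  cs$channels <- cs$channels[ord, ]
  rownames(cs$channels) <- NULL
  cs
}

collect_measurements <- function(frames, channel_sets, bacteria_sets,
                                 accepted, cfg) {
  rows <- list()
  for (t in accepted) {
    fr <- frames[[t]]
    cs <- channel_sets[[t]]
    bs <- bacteria_sets[[t]]
    n_fluo <- length(fr$fluorescence)
    # frame-level fallback background per fluorophore
    fallback <- rep(NA_real_, n_fluo)
    if (n_fluo > 0) {
      for (q in seq_len(n_fluo)) {
        empty <- cs$labels > 0L & bs$labels == 0L
        if (any(empty)) fallback[q] <- mean(fr$fluorescence[[q]][empty])
      }
    }
    for (i in seq_along(bs$channel_ids)) {
      cid <- bs$channel_ids[i]
      lab <- bs$channel_labels[[i]]$labels
      b <- bs$channel_labels[[i]]$bbox
      if (max(lab) == 0L) next
      meas <- mm_measure_regions(lab)
      rec <- data.frame(
        area_id = fr$area_id, timestamp = fr$timestamp, frame_index = t,
        channel_id = cid, bacterium_label = meas$label,
        length_px = meas$length, width_px = meas$width, area_px = meas$area)
      if (n_fluo > 0) {
        cmask <- cs$labels[b[1]:b[2], b[3]:b[4], drop = FALSE] == cid
        for (q in seq_len(n_fluo)) {
          fcrop <- fr$fluorescence[[q]][b[1]:b[2], b[3]:b[4], drop = FALSE]
          fl <- mm_measure_fluorescence(lab, cmask, fcrop, fallback[q])
          rec[[sprintf("fluo%d_mean", q)]] <- fl$mean
          rec[[sprintf("fluo%d_background", q)]] <- fl$background
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (!length(rows)) {
    return(data.frame(area_id = character(0), timestamp = as.POSIXct(character(0)),
                      frame_index = integer(0), channel_id = integer(0),
                      bacterium_label = integer(0), length_px = numeric(0),
                      width_px = numeric(0), area_px = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mm_result <- function(x, ...) {
  acc <- sum(!vapply(x$channel_sets, is.null, logical(1)))
  cat(sprintf(
    "mm_result: %s, %d/%d frame(s) analysed, %d track(s), %d measurement row(s)\n",
    x$modality, acc, length(x$channel_sets),
    length(unique(x$graph$nodes$global_id)), nrow(x$measurements)))
  invisible(x)
}

#' Export an analysis result as a measurement CSV
#'
#' Convenience wrapper mapping an [mm_analyze()] result onto the fixed CSV
#' schema of [mm_write_measurements()].
#'
#' @param result An `mm_result`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
mm_export_csv <- function(result, path) {
  m <- result$measurements
  df <- data.frame(
    area_id = m$area_id, timestamp = format(m$timestamp, "%Y-%m-%d %H:%M:%S"),
    frame_index = m$frame_index, channel_id = m$channel_id,
    bacterium_id = m$global_id, parent_id = m$parent_id,
    event = ifelse(!is.na(m$fate) & m$fate == "lysis",
                   "lysis-terminal", m$event),
    length_px = m$length_px, width_px = m$width_px, area_px = m$area_px)
  for (col in grep("^fluo", names(m), value = TRUE)) df[[col]] <- m[[col]]
  mm_write_measurements(df, path)
}
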