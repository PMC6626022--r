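#' Precision, recall and Jaccard index of a detection mask
#'
#' Pixel-level comparison of a detection mask against a ground-truth mask:
#' precision is the overlap area divided by the detection mask, recall the
#' overlap divided by the truth mask, and the Jaccard index the overlap
#' divided by the combined area (intersection over union).
#'
#' @param detected,truth Logical matrices of identical size; both must be
#'   non-empty.
#' @return List of class `mm_mask_score`: `precision`, `recall`, `jaccard`.
#' @export
mm_mask_scores <- function(detected, truth) {
  stopifnot(identical(dim(detected), dim(truth)))
  nd <- sum(detected); nt <- sum(truth)
  if (nt == 0) stop("recall undefined: empty ground-truth mask")
  if (nd == 0) stop("precision undefined: empty detection mask")
  ov <- sum(detected & truth)
  structure(list(precision = ov / nd, recall = ov / nt,
                 jaccard = ov / (nd + nt - ov)),
            class = "mm_mask_score")
}

#' @export
print.mm_mask_score <- function(x, ...) {
  cat(sprintf("precision %.3f, recall %.3f, Jaccard %.3f\n",
              x$precision, x$recall, x$jaccard))
  invisible(x)
}

# per-truth-object overlap bookkeeping shared by efficiency and accuracy
object_overlaps <- function(pred_labels, truth_labels) {
  ids <- sort(setdiff(unique(as.vector(truth_labels)), 0))
  if (!length(ids)) stop("no ground-truth objects to evaluate")
  lapply(ids, function(id) {
    sel <- truth_labels == id
    labs <- pred_labels[sel]
    list(id = id, area = sum(sel),
         covered = sum(labs > 0),
         by_label = table(labs[labs > 0]))
  })
}

#' Detection efficiency
#'
#' Percentage of ground-truth objects detected: an object counts as
#' detected when at least `min_overlap` of its area is covered by detection
#' labels (splitting one object across several labels still counts).
#'
#' @param pred_labels Integer label matrix of detections (frame-level).
#' @param truth_labels Integer label matrix of ground-truth objects.
#' @param min_overlap Minimum covered fraction of the truth object.
#' @return Percentage in `[0, 100]`.
#' @export
mm_detection_efficiency <- function(pred_labels, truth_labels,
                                    min_overlap = 0.5) {
  ov <- object_overlaps(pred_labels, truth_labels)
  hit <- vapply(ov, function(o) o$covered >= min_overlap * o$area, logical(1))
  100 * mean(hit)
}

#' Detection accuracy
#'
#' Percentage of ground-truth objects correctly identified by a single
#' label: exactly one detection label overlaps the object, and that label
#' overlaps no other ground-truth object. Objects split over several
#' labels, or merged with a neighbour under one label, are not accurate
#' (though they may still count as detected).
#'
#' @inheritParams mm_detection_efficiency
#' @return Percentage in `[0, 100]`.
#' @export
mm_detection_accuracy <- function(pred_labels, truth_labels,
                                  min_overlap = 0.5) {
  ov <- object_overlaps(pred_labels, truth_labels)
  # sole overlapping label per truth object, NA when split over several
  main <- vapply(ov, function(o) {
    if (length(o$by_label) == 1) as.integer(names(o$by_label))
    else NA_integer_
  }, integer(1))
  ok <- !is.na(main)
  # a label claiming more than one truth object disqualifies them all
  dup <- main[ok][duplicated(main[ok]) | duplicated(main[ok], fromLast = TRUE)]
  ok[main %in% dup] <- FALSE
  100 * mean(ok)
}

#' Tracking efficiency against a ground-truth lineage
#'
#' Percentage of consecutive-frame ground-truth links reproduced by the
#' predicted track graph: a link is correct when the two objects, matched
#' to predictions by mask overlap, are connected in the prediction with the
#' same event type (persistence vs division). Only truth objects that were
#' correctly detected (one-to-one overlap match on both frames) enter the
#' denominator, decoupling tracking quality from detection quality.
#'
#' @param result An `mm_result` from [mm_analyze()].
#' @param truth Ground truth of an `mm_fixture_series` (`series$truth`).
#' @param min_overlap Overlap fraction for matching objects to predictions.
#' @return List: `efficiency` (percentage), `n_links` evaluated,
#'   `n_correct`.
#' @export
mm_tracking_efficiency <- function(result, truth, min_overlap = 0.5) {
  lin <- truth$lineage
  frames_an <- setdiff(seq_along(truth$bacteria_labels), result$skipped)
  # match truth cells to predicted global ids per frame
  match_frame <- function(t) {
    bs <- result$bacteria_sets[[t]]
    if (is.null(bs)) return(NULL)
    nodes <- result$graph$nodes[result$graph$nodes$frame == t, ]
    key <- paste0(nodes$channel_id, ":", nodes$label)
    tl <- truth$bacteria_labels[[t]]
    ids <- sort(setdiff(unique(as.vector(tl)), 0))
    out <- integer(0)
    for (id in ids) {
      sel <- tl == id
      labs <- bs$labels[sel]
      tb <- table(labs[labs > 0])
      big <- tb[tb >= min_overlap * sum(sel)]
      if (length(big) != 1) next
      flab <- as.integer(names(big))
      # frame-level label -> (channel, label) -> global id
      hit <- which(bs$bacteria$frame_label == flab)
      if (length(hit) != 1) next
      k <- paste0(bs$bacteria$channel_id[hit], ":", bs$bacteria$label[hit])
      g <- nodes$global_id[match(k, key)]
      if (!is.na(g)) out[[as.character(id)]] <- g
    }
    out
  }
  maps <- lapply(seq_along(truth$bacteria_labels), function(t)
    if (t %in% frames_an) match_frame(t) else NULL)

  n_links <- 0L; n_correct <- 0L
  nodes <- result$graph$nodes
  for (k in seq_along(frames_an)[-1]) {
    t0 <- frames_an[k - 1]; t1 <- frames_an[k]
    m0 <- maps[[t0]]; m1 <- maps[[t1]]
    cur <- lin[lin$frame == t1, ]
    for (i in seq_len(nrow(cur))) {
      gid_t <- cur$global_id[i]
      ev <- cur$event[i]
      if (ev == "new") next
      src <- if (ev == "division") cur$parent_id[i] else gid_t
      if (!(as.character(src) %in% names(m0)) ||
          !(as.character(gid_t) %in% names(m1))) next
      n_links <- n_links + 1L
      pg_prev <- m0[[as.character(src)]]
      pg_curr <- m1[[as.character(gid_t)]]
      node <- nodes[nodes$frame == t1 & nodes$global_id == pg_curr, ]
      if (nrow(node) != 1) next
      okay <- if (ev == "division") {
        node$event == "division" && !is.na(node$parent_id) &&
          node$parent_id == pg_prev
      } else {
        node$event == "no-change" && pg_curr == pg_prev
      }
      if (okay) n_correct <- n_correct + 1L
    }
  }
  if (n_links == 0L) stop("no evaluable tracking links")
  list(efficiency = 100 * n_correct / n_links, n_links = n_links,
       n_correct = n_correct)
}
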