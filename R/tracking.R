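#' Estimate the rigid shift between two frames
#'
#' Cross-correlation template matching over the whole image: the shift
#' `(dy, dx)` maximising the normalised cross-correlation of the
#' mean-subtracted frames, so that `curr(r, c) ~ prev(r - dy, c - dx)`.
#' When the correlation peak falls below `cfg$min_peak_correlation` (no
#' common structure) the shift falls back to `(0, 0)` with a warning.
#'
#' @param prev_image,curr_image Numeric matrices of identical size.
#' @param cfg An [mm_config()].
#' @return List of class `mm_frame_shift`: `dy`, `dx`, `peak_correlation`.
#' @export
mm_estimate_frame_shift <- function(prev_image, curr_image,
                                    cfg = mm_config()) {
  stopifnot(identical(dim(prev_image), dim(curr_image)))
  a <- prev_image - mean(prev_image)
  b <- curr_image - mean(curr_image)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("constant frame: no structure to register; using shift (0, 0)")
    return(structure(list(dy = 0, dx = 0, peak_correlation = 0),
                     class = "mm_frame_shift"))
  }
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    length(a)
  peak <- which.max(cc)
  ij <- arrayInd(peak, dim(cc)) - 1L
  dy <- ij[1]; dx <- ij[2]
  if (dy > nrow(cc) / 2) dy <- dy - nrow(cc)
  if (dx > ncol(cc) / 2) dx <- dx - ncol(cc)
  rho <- cc[peak] / (na * nb)
  if (rho < cfg$min_peak_correlation) {
    warning(sprintf(
      "cross-correlation peak %.3f below floor %.3f; using shift (0, 0)",
      rho, cfg$min_peak_correlation))
    return(structure(list(dy = 0, dx = 0, peak_correlation = rho),
                     class = "mm_frame_shift"))
  }
  structure(list(dy = dy, dx = dx, peak_correlation = rho),
            class = "mm_frame_shift")
}

#' @export
print.mm_frame_shift <- function(x, ...) {
  cat(sprintf("frame shift (dy, dx) = (%g, %g), peak correlation %.3f\n",
              x$dy, x$dx, x$peak_correlation))
  invisible(x)
}

#' Match channels between consecutive frames
#'
#' Shift-corrected channel centroids are linked by mutual nearest
#' neighbours: a previous channel and a current channel are matched only if
#' each is the other's closest counterpart. Unmatched channels on either
#' side are reported.
#'
#' @param prev,curr `mm_channel_set` objects (or data frames with columns
#'   `id`, `centroid_r`, `centroid_c`).
#' @param shift An `mm_frame_shift` (applied to the previous centroids).
#' @return List of class `mm_channel_map`: `matches` (data frame `prev_id`,
#'   `curr_id`), `unmatched_prev`, `unmatched_curr`.
#' @export
mm_track_channels <- function(prev, curr, shift = NULL) {
  pdf <- if (inherits(prev, "mm_channel_set")) prev$channels else prev
  cdf <- if (inherits(curr, "mm_channel_set")) curr$channels else curr
  if (is.null(shift)) shift <- list(dy = 0, dx = 0)
  if (nrow(pdf) == 0 || nrow(cdf) == 0) {
    return(structure(list(
      matches = data.frame(prev_id = integer(0), curr_id = integer(0)),
      unmatched_prev = pdf$id, unmatched_curr = cdf$id),
      class = "mm_channel_map"))
  }
  pc <- cbind(pdf$centroid_r + shift$dy, pdf$centroid_c + shift$dx)
  cc <- cbind(cdf$centroid_r, cdf$centroid_c)
  d <- outer(pc[, 1], cc[, 1], "-")^2 + outer(pc[, 2], cc[, 2], "-")^2
  nn_pc <- apply(d, 1, which.min)
  nn_cp <- apply(d, 2, which.min)
  mutual <- which(nn_cp[nn_pc] == seq_len(nrow(pdf)))
  matches <- data.frame(prev_id = pdf$id[mutual],
                        curr_id = cdf$id[nn_pc[mutual]])
  structure(list(
    matches = matches,
    unmatched_prev = setdiff(pdf$id, matches$prev_id),
    unmatched_curr = setdiff(cdf$id, matches$curr_id)),
    class = "mm_channel_map")
}

#' Enumerate event hypotheses for the bacteria of one channel
#'
#' Each previous bacterium either lyses (0 children), persists (1 child) or
#' undergoes `m` divisions (`2^m` children, `m <= division_cap`); leftover
#' current bacteria enter as new cells at the open end. Mother-machine
#' geometry forbids cells passing each other, so assignments are
#' order-preserving along the channel axis: each cell's children are a
#' contiguous block, blocks appear in cell order, and new cells sit at the
#' open end.
#'
#' @param n_prev,n_curr Cell counts in the previous / current frame.
#' @param division_cap Maximum divisions per cell per frame interval.
#' @return List of hypotheses, each a list with `counts` (children per
#'   previous cell), `divisions` (per-cell division count) and `n_new`.
#' @export
mm_enumerate_hypotheses <- function(n_prev, n_curr, division_cap = 2L) {
  opts_children <- 2^(0:division_cap) # 1, 2, 4, ... children
  opts_div <- 0:division_cap
  hyps <- list()
  recurse <- function(i, counts, divs, used) {
    if (used > n_curr) return()
    if (i > n_prev) {
      hyps[[length(hyps) + 1L]] <<- list(
        counts = counts, divisions = divs, n_new = n_curr - used)
      return()
    }
    recurse(i + 1L, c(counts, 0L), c(divs, 0L), used) # lysis
    for (j in seq_along(opts_children)) {
      recurse(i + 1L, c(counts, opts_children[j]), c(divs, opts_div[j]),
              used + opts_children[j])
    }
  }
  recurse(1L, integer(0), integer(0), 0L)
  hyps
}

#' Score one event hypothesis
#'
#' Per previous bacterium the hypothesis contributes the product of three
#' probabilities: a Gaussian penalty on the relative change in total area
#' between the cell and its offspring, a Gaussian penalty on the centroid
#' displacement (each division is expected to move the centroid by half an
#' average bacterium length), and the prior of the event type. The
#' per-bacterium terms, and a prior term for every new cell entering at the
#' open end, are multiplied into the hypothesis probability.
#'
#' @param h One hypothesis from [mm_enumerate_hypotheses()].
#' @param prev_pos,prev_area Ordered positions (px, along the channel axis,
#'   dead end first) and areas of the previous cells.
#' @param curr_pos,curr_area Same for the current cells.
#' @param params List with `p_no_change`, `p_division`, `p_lysis`,
#'   `area_sigma`, `centroid_sigma`, `mean_bacterium_length`.
#' @return The hypothesis probability in (0, 1].
#' @export
mm_score_hypothesis <- function(h, prev_pos, prev_area, curr_pos, curr_area,
                                params) {
  p <- 1
  j <- 0L
  for (i in seq_along(h$counts)) {
    k <- h$counts[i]
    if (k == 0L) {
      p <- p * params$p_lysis
      next
    }
    kids <- j + seq_len(k)
    j <- j + k
    a_ratio <- sum(curr_area[kids]) / prev_area[i]
    p_area <- exp(-((a_ratio - 1) / params$area_sigma)^2 / 2)
    d_obs <- abs(stats::weighted.mean(curr_pos[kids], curr_area[kids]) -
                   prev_pos[i])
    d_exp <- h$divisions[i] * params$mean_bacterium_length / 2
    p_cen <- exp(-((d_obs - d_exp) / params$centroid_sigma)^2 / 2)
    p_event <- if (h$divisions[i] == 0L) params$p_no_change
               else params$p_division^h$divisions[i]
    p <- p * p_area * p_cen * p_event
  }
  p * params$p_lysis^h$n_new
}

# deterministic choice of the best hypothesis: highest probability, ties
# broken by fewest total events, then fewest divisions, then
# lexicographically smallest child-count vector
best_hypothesis <- function(hyps, scores) {
  best <- max(scores)
  cand <- which(scores >= best * (1 - 1e-12))
  if (length(cand) > 1L) {
    events <- vapply(hyps[cand], function(h)
      sum(h$counts == 0L) + sum(h$divisions) + h$n_new, numeric(1))
    cand <- cand[events == min(events)]
    if (length(cand) > 1L) {
      divs <- vapply(hyps[cand], function(h) sum(h$divisions), numeric(1))
      cand <- cand[divs == min(divs)]
    }
    if (length(cand) > 1L) {
      keys <- vapply(hyps[cand], function(h)
        paste(h$counts, collapse = ","), character(1))
      cand <- cand[order(keys)]
    }
  }
  cand[1]
}

#' Track bacteria between two consecutive frames
#'
#' For every matched channel, enumerates all order-preserving event
#' combinations (no-change / division / lysis per previous cell, new cells
#' at the open end), scores them with [mm_score_hypothesis()] and applies
#' the most probable one. Cells that persist keep their global id; division
#' and new cells receive fresh ids.
#'
#' @param prev_bs,curr_bs `mm_bacteria_set` objects.
#' @param channel_map An `mm_channel_map` from [mm_track_channels()] (ids in
#'   frame-local channel numbering).
#' @param prev_channels,curr_channels The matching `mm_channel_set`s.
#' @param shift `mm_frame_shift` between the two frames.
#' @param cfg An [mm_config()].
#' @param prev_gids Named integer vector: previous frame's
#'   `"<channel>:<label>"` to global id.
#' @param next_gid Next unused global id.
#' @return List: `gids` (map for the current frame), `next_gid`, `events`
#'   (data frame: channel, label, global_id, parent_id, event), `lysed`
#'   (global ids of previous cells that lysed).
#' @export
mm_track_bacteria <- function(prev_bs, curr_bs, channel_map, prev_channels,
                              curr_channels, shift, cfg = mm_config(),
                              prev_gids, next_gid) {
  params <- list(p_no_change = cfg$p_no_change, p_division = cfg$p_division,
                 p_lysis = cfg$p_lysis, area_sigma = cfg$area_sigma,
                 centroid_sigma = cfg$centroid_sigma,
                 mean_bacterium_length = NA_real_)
  prev_len <- prev_bs$bacteria$length
  mlen <- if (length(prev_len) && any(is.finite(prev_len)))
    stats::median(prev_len, na.rm = TRUE) else 20
  params$mean_bacterium_length <- mlen
  if (is.null(params$centroid_sigma)) params$centroid_sigma <- mlen / 2

  events <- list()
  lysed <- integer(0)
  gids <- integer(0)

  handle_channel <- function(pid, qid) {
    pdfb <- prev_bs$bacteria[prev_bs$bacteria$channel_id == pid, , drop = FALSE]
    cdfb <- curr_bs$bacteria[curr_bs$bacteria$channel_id == qid, , drop = FALSE]
    ch <- curr_channels$channels[curr_channels$channels$id == qid, ]
    u <- c(ch$axis_r, ch$axis_c) / ch$length
    if (cfg$open_end == "low") u <- -u # dead end first along +u
    org <- c(ch$centroid_r, ch$centroid_c)
    pos_of <- function(df, dy = 0, dx = 0) {
      (df$centroid_r + dy - org[1]) * u[1] + (df$centroid_c + dx - org[2]) * u[2]
    }
    ppos <- pos_of(pdfb, shift$dy, shift$dx)
    cpos <- pos_of(cdfb)
    po <- order(ppos); co <- order(cpos)
    pdfb <- pdfb[po, ]; ppos <- ppos[po]
    cdfb <- cdfb[co, ]; cpos <- cpos[co]

    hyps <- mm_enumerate_hypotheses(nrow(pdfb), nrow(cdfb), cfg$division_cap)
    scores <- vapply(hyps, mm_score_hypothesis, numeric(1),
                     prev_pos = ppos, prev_area = pdfb$area,
                     curr_pos = cpos, curr_area = cdfb$area, params = params)
    h <- hyps[[best_hypothesis(hyps, scores)]]

    j <- 0L
    for (i in seq_len(nrow(pdfb))) {
      gid_prev <- prev_gids[[paste0(pid, ":", pdfb$label[i])]]
      k <- h$counts[i]
      if (k == 0L) {
        lysed <<- c(lysed, gid_prev)
        next
      }
      kids <- j + seq_len(k); j <- j + k
      for (ki in kids) {
        key <- paste0(qid, ":", cdfb$label[ki])
        if (h$divisions[i] == 0L) {
          gids[[key]] <<- gid_prev
          events[[length(events) + 1L]] <<- data.frame(
            channel = qid, label = cdfb$label[ki], global_id = gid_prev,
            parent_id = NA_integer_, event = "no-change")
        } else {
          gids[[key]] <<- next_gid
          events[[length(events) + 1L]] <<- data.frame(
            channel = qid, label = cdfb$label[ki], global_id = next_gid,
            parent_id = gid_prev, event = "division")
          next_gid <<- next_gid + 1L
        }
      }
    }
    if (h$n_new > 0L) {
      for (ki in j + seq_len(h$n_new)) {
        key <- paste0(qid, ":", cdfb$label[ki])
        gids[[key]] <<- next_gid
        events[[length(events) + 1L]] <<- data.frame(
          channel = qid, label = cdfb$label[ki], global_id = next_gid,
          parent_id = NA_integer_, event = "new")
        next_gid <<- next_gid + 1L
      }
    }
  }

  for (r in seq_len(nrow(channel_map$matches))) {
    handle_channel(channel_map$matches$prev_id[r],
                   channel_map$matches$curr_id[r])
  }
  # channels with no previous counterpart: all their cells are new
  for (qid in channel_map$unmatched_curr) {
    cdfb <- curr_bs$bacteria[curr_bs$bacteria$channel_id == qid, , drop = FALSE]
    for (i in seq_len(nrow(cdfb))) {
      key <- paste0(qid, ":", cdfb$label[i])
      gids[[key]] <- next_gid
      events[[length(events) + 1L]] <- data.frame(
        channel = qid, label = cdfb$label[i], global_id = next_gid,
        parent_id = NA_integer_, event = "new")
      next_gid <- next_gid + 1L
    }
  }
  # cells in channels that disappeared: their tracks simply end (no lysis
  # call; the channel was lost, not the cell)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(channel = integer(0), label = integer(0),
               global_id = integer(0), parent_id = integer(0),
               event = character(0))
  list(gids = gids, next_gid = next_gid, events = ev, lysed = lysed)
}
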