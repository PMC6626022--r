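# Zhang-Suen binary thinning and skeleton path tracing. Used by the
# bacteria-splitting stage: rod-shaped cells thin to a simple path whose
# local width (distance transform) and intensity locate division necks.

zhang_suen_thin <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      idx <- which(m == 1L)
      if (!length(idx)) break
      nr <- nrow(m)
      p2 <- m[idx - 1L];      p3 <- m[idx - 1L + nr]
      p4 <- m[idx + nr];      p5 <- m[idx + 1L + nr]
      p6 <- m[idx + 1L];      p7 <- m[idx + 1L - nr]
      p8 <- m[idx - nr];      p9 <- m[idx - 1L - nr]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- rowSums(seqs[, 1:8, drop = FALSE] == 0L &
                     seqs[, 2:9, drop = FALSE] == 1L)
      if (step == 1L) {
        cond <- b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p6) == 0L & (p4 * p6 * p8) == 0L
      } else {
        cond <- b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p8) == 0L & (p2 * p6 * p8) == 0L
      }
      if (any(cond)) {
        m[idx[cond]] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] > 0L
}

# Ordered (row, col) skeleton path of a mask, endpoint to endpoint.
# Returns NULL for degenerate skeletons (< 2 px). Branched skeletons are
# traced along their longest endpoint-to-endpoint walk, which for nearly
# rod-shaped regions is the medial axis with spurs dropped.
skeleton_path <- function(mask) {
  sk <- zhang_suen_thin(mask)
  pts <- which(sk, arr.ind = TRUE)
  if (nrow(pts) < 2) return(NULL)
  key <- paste(pts[, 1], pts[, 2])
  index <- seq_len(nrow(pts))
  names(index) <- key
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nbrs <- lapply(seq_len(nrow(pts)), function(i) {
    cand <- paste(pts[i, 1] + offs$dr, pts[i, 2] + offs$dc)
    unname(index[cand[cand %in% key]])
  })
  deg <- lengths(nbrs)
  ends <- which(deg == 1L)
  start <- if (length(ends)) ends[1] else 1L
  walk_from <- function(start) {
    visited <- rep(FALSE, nrow(pts))
    path <- integer(nrow(pts))
    path[1] <- start; visited[start] <- TRUE; n <- 1L
    repeat {
      nxt <- nbrs[[path[n]]]
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      # prefer continuing to low-degree pixels (stay on the main run)
      nxt <- nxt[order(deg[nxt])][1]
      n <- n + 1L
      path[n] <- nxt
      visited[nxt] <- TRUE
    }
    path[seq_len(n)]
  }
  p1 <- walk_from(start)
  # restart from the far end for a maximal endpoint-to-endpoint walk
  p2 <- walk_from(p1[length(p1)])
  best <- if (length(p2) >= length(p1)) p2 else p1
  pts[best, , drop = FALSE]
}
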