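#' Specification for a synthetic mother-machine time-lapse
#'
#' Describes the geometry, population dynamics, optics and noise of a
#' simulated mother-machine field of view. The device is a row of parallel
#' dead-end channels; rod-shaped cells (rectangles with semicircular caps)
#' sit inside the channels, grow linearly, divide at a length threshold or on
#' schedule, and lyse (vanish) on schedule. The whole scene can drift rigidly
#' between frames and the device can be tilted.
#'
#' @param n_channels Number of channels.
#' @param channel_length,channel_width Channel interior dimensions, px.
#' @param pitch Channel-to-channel spacing, px (centre to centre).
#' @param wall_width Thickness of the channel walls, px.
#' @param device_angle Tilt of the device, degrees (counter-clockwise).
#' @param modality `"brightfield"` (bright background, dark walls and cells)
#'   or `"phase"` (dark background, bright walls, dark cells with halo).
#' @param n_frames Number of time points.
#' @param drift Per-frame rigid shift: either a length-2 vector `(dy, dx)`
#'   applied at every frame transition, or an `(n_frames - 1) x 2` matrix.
#' @param n_cells_per_channel Integer vector (recycled) of initial cell
#'   counts, or `NULL` to draw counts in 1--3 at random.
#' @param init_length_range Range of initial cell lengths, px.
#' @param cell_width Cell width, px (must fit inside the channel).
#' @param growth_rate Length increase per frame, px.
#' @param division_length Length at which a cell divides spontaneously, px.
#' @param division_schedule,lysis_schedule Optional data frames with columns
#'   `channel`, `frame` (and `cell`, position from the dead end, defaulting
#'   to 1) forcing a division / a lysis at that frame.
#' @param noise_sigma Gaussian noise s.d. as a fraction of the
#'   background-to-cell contrast.
#' @param illum_gradient Amplitude of a linear illumination ramp across the
#'   field, as a fraction of the background level.
#' @param n_fluo Number of fluorescence planes to render.
#' @param fluo_cell_mean,fluo_cell_sd Per-cell fluorophore level distribution
#'   (a.u.); each cell keeps its level for life and passes it to daughters.
#' @param fluo_background,fluo_noise_sd Fluorescence background level and
#'   additive noise s.d. (a.u.).
#' @param seed Integer seed; identical spec (including seed) gives
#'   bit-identical output.
#' @return An object of class `mm_fixture_spec`.
#' @export
mm_fixture_spec <- function(n_channels = 8, channel_length = 150,
                            channel_width = 12, pitch = 40, wall_width = 2,
                            device_angle = 0, modality = "brightfield",
                            n_frames = 5, drift = c(0, 0),
                            n_cells_per_channel = NULL,
                            init_length_range = c(18, 28), cell_width = 7,
                            growth_rate = 2, division_length = 40,
                            division_schedule = NULL, lysis_schedule = NULL,
                            noise_sigma = 0.05, illum_gradient = 0.05,
                            n_fluo = 0, fluo_cell_mean = 100,
                            fluo_cell_sd = 20, fluo_background = 10,
                            fluo_noise_sd = 2, seed = 1) {
  modality <- match.arg(modality, c("brightfield", "phase"))
  stopifnot(pitch > channel_width, channel_length > 0, channel_width > 0,
            cell_width < channel_width, n_frames >= 1, n_channels >= 1)
  if (is.null(dim(drift))) {
    drift <- matrix(rep(drift, length.out = 2 * max(n_frames - 1, 1)),
                    ncol = 2, byrow = TRUE)
  }
  norm_sched <- function(s) {
    if (is.null(s) || nrow(s) == 0) return(NULL)
    if (is.null(s$cell)) s$cell <- 1L
    s
  }
  spec <- list(
    n_channels = n_channels, channel_length = channel_length,
    channel_width = channel_width, pitch = pitch, wall_width = wall_width,
    device_angle = device_angle, modality = modality, n_frames = n_frames,
    drift = drift, n_cells_per_channel = n_cells_per_channel,
    init_length_range = init_length_range, cell_width = cell_width,
    growth_rate = growth_rate, division_length = division_length,
    division_schedule = norm_sched(division_schedule),
    lysis_schedule = norm_sched(lysis_schedule),
    noise_sigma = noise_sigma, illum_gradient = illum_gradient,
    n_fluo = as.integer(n_fluo), fluo_cell_mean = fluo_cell_mean,
    fluo_cell_sd = fluo_cell_sd, fluo_background = fluo_background,
    fluo_noise_sd = fluo_noise_sd, seed = as.integer(seed)
  )
  class(spec) <- "mm_fixture_spec"
  spec
}

# rendering palettes per modality; intensities on [0, 1]
fixture_palette <- function(modality) {
  if (modality == "brightfield") {
    list(bg = 0.75, wall = 0.30, cell = 0.35, halo = NA)
  } else {
    list(bg = 0.22, wall = 0.85, cell = 0.08, halo = 0.45)
  }
}

#' Generate a synthetic time-lapse with full ground truth
#'
#' Renders the scene described by an [mm_fixture_spec()] and returns both the
#' image series and the exact ground truth it was rendered from: channel and
#' bacteria label images, the true lineage, and the true rigid shift of every
#' frame. This makes every stage of the analysis pipeline testable without
#' external microscopy data.
#'
#' @param spec An [mm_fixture_spec()].
#' @return A list of class `mm_fixture_series`:
#' \describe{
#'   \item{frames}{List of `mm_frame` objects (primary image plus
#'     fluorescence planes).}
#'   \item{truth}{List with per-frame `channel_labels` (interiors, ordered
#'     left-to-right), `bacteria_labels` (pixel value = stable global cell
#'     id), `lineage` (data frame: frame, channel, global_id, parent_id,
#'     event, fate, length, area), and `shifts` (cumulative `(dy, dx)` per
#'     frame).}
#'   \item{spec}{The input spec.}
#' }
#' @export
mm_generate_series <- function(spec) {
  stopifnot(inherits(spec, "mm_fixture_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- spec$n_channels
  L <- spec$channel_length; w <- spec$channel_width
  margin <- 40
  H <- ceiling(L + 2 * margin)
  W <- ceiling(n * spec$pitch + 2 * margin)
  if (abs(spec$device_angle) > 0) {
    ext <- ceiling(abs(sin(spec$device_angle * pi / 180)) * W / 2)
    H <- H + 2 * ext
  }

  # initial population
  counts <- spec$n_cells_per_channel
  if (is.null(counts)) {
    counts <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  } else {
    counts <- rep(counts, length.out = n)
  }
  next_id <- 1L
  cells <- vector("list", n) # per channel: data.frame(id, len, start, ...)
  for (k in seq_len(n)) {
    m <- counts[k]
    if (m == 0) { cells[[k]] <- empty_cells(spec$n_fluo); next }
    len <- stats::runif(m, spec$init_length_range[1], spec$init_length_range[2])
    fl <- matrix(stats::rnorm(m * max(spec$n_fluo, 1), spec$fluo_cell_mean,
                              spec$fluo_cell_sd),
                 nrow = m)[, seq_len(spec$n_fluo), drop = FALSE]
    fl[fl < 0] <- 0
    cells[[k]] <- data.frame(id = next_id:(next_id + m - 1L), len = len,
                             start = 2 + c(0, cumsum(len + 2))[seq_len(m)],
                             event = "new", parent = NA_integer_)
    cells[[k]]$fluo <- fl
    next_id <- next_id + m
  }

  lineage <- list()
  frames <- vector("list", spec$n_frames)
  ch_lab <- vector("list", spec$n_frames)
  bac_lab <- vector("list", spec$n_frames)
  shifts <- matrix(0, spec$n_frames, 2,
                   dimnames = list(NULL, c("dy", "dx")))
  fates <- list() # global_id -> fate
  t0 <- as.POSIXct("2017-10-16 12:00:00", tz = "UTC")

  for (t in seq_len(spec$n_frames)) {
    if (t > 1) {
      shifts[t, ] <- shifts[t - 1, ] + spec$drift[t - 1, ]
      # grow
      for (k in seq_len(n)) {
        if (nrow(cells[[k]])) {
          cells[[k]]$len <- cells[[k]]$len + spec$growth_rate
          cells[[k]]$event <- "no-change"
        }
      }
      # scheduled lysis (cell removed this frame)
      ls <- spec$lysis_schedule
      if (!is.null(ls)) {
        for (i in which(ls$frame == t)) {
          k <- ls$channel[i]; p <- ls$cell[i]
          if (p <= nrow(cells[[k]])) {
            fates[[as.character(cells[[k]]$id[p])]] <- "lysis"
            cells[[k]] <- cells[[k]][-p, , drop = FALSE]
          }
        }
      }
      # divisions: scheduled, then threshold-driven; children share the
      # parent's span
      ds <- spec$division_schedule
      for (k in seq_len(n)) {
        ck <- cells[[k]]
        if (!nrow(ck)) next
        forced <- rep(FALSE, nrow(ck))
        if (!is.null(ds)) {
          for (i in which(ds$frame == t & ds$channel == k)) {
            if (ds$cell[i] <= nrow(ck)) forced[ds$cell[i]] <- TRUE
          }
        }
        div <- forced | ck$len >= spec$division_length
        if (any(div)) {
          out <- empty_cells(spec$n_fluo)
          for (p in seq_len(nrow(ck))) {
            row <- ck[p, , drop = FALSE]
            if (div[p]) {
              child_len <- (row$len - 1) / 2
              kids <- row[c(1, 1), , drop = FALSE]
              kids$id <- next_id:(next_id + 1L)
              next_id <- next_id + 2L
              kids$len <- child_len
              kids$start <- c(row$start, row$start + child_len + 1)
              kids$event <- "division"
              kids$parent <- row$id
              out <- rbind(out, kids)
            } else {
              out <- rbind(out, row)
            }
          }
          cells[[k]] <- out
        }
      }
      # growth pushes cells towards the open end only (the dead end blocks
      # the other direction); gaps left by lysed cells persist
      for (k in seq_len(n)) {
        ck <- cells[[k]]
        if (!nrow(ck)) next
        for (p in seq_len(nrow(ck))[-1]) {
          ck$start[p] <- max(ck$start[p], ck$start[p - 1] + ck$len[p - 1] + 2)
        }
        gone <- ck$start > L - 4
        ck$len <- pmin(ck$len, L - 2 - ck$start) # clip at the open end
        if (any(gone)) {
          for (id in ck$id[gone]) fates[[as.character(id)]] <- "exited"
          ck <- ck[!gone, , drop = FALSE]
        }
        cells[[k]] <- ck
      }
    }

    rend <- render_frame(spec, cells, H, W, shifts[t, ])
    frames[[t]] <- new_mm_frame(rend$img, rend$fluo,
                                area_id = "Area01",
                                timestamp = t0 + (t - 1) * 3600)
    ch_lab[[t]] <- rend$channel_labels
    bac_lab[[t]] <- rend$bacteria_labels
    for (k in seq_len(n)) {
      ck <- cells[[k]]
      if (!nrow(ck)) next
      lineage[[length(lineage) + 1L]] <- data.frame(
        frame = t, channel = k, global_id = ck$id, parent_id = ck$parent,
        event = ck$event, length = ck$len,
        area = NA_real_
      )
    }
  }

  lin <- if (length(lineage)) do.call(rbind, lineage) else
    data.frame(frame = integer(0), channel = integer(0),
               global_id = integer(0), parent_id = integer(0),
               event = character(0), length = numeric(0), area = numeric(0))
  rownames(lin) <- NULL
  lin$fate <- rep(NA_character_, nrow(lin))
  for (id in names(fates)) lin$fate[lin$global_id == as.integer(id)] <- fates[[id]]
  # fate applies only to a track's final row
  last <- !duplicated(lin$global_id, fromLast = TRUE)
  lin$fate[!last] <- NA_character_
  # fill areas from the rendered label images
  for (i in seq_len(nrow(lin))) {
    lin$area[i] <- sum(bac_lab[[lin$frame[i]]] == lin$global_id[i])
  }

  structure(list(
    frames = frames,
    truth = list(channel_labels = ch_lab, bacteria_labels = bac_lab,
                 lineage = lin, shifts = shifts),
    spec = spec
  ), class = "mm_fixture_series")
}

empty_cells <- function(n_fluo) {
  d <- data.frame(id = integer(0), len = numeric(0), start = numeric(0),
                  event = character(0), parent = integer(0))
  d$fluo <- matrix(numeric(0), 0, n_fluo)
  d
}

# Render one frame. Device coordinates: u along the channel axis (u = -L/2 at
# the dead end, +L/2 at the open end), v across channels; the device is
# rotated by device_angle about the canvas centre and translated by `shift`.
render_frame <- function(spec, cells, H, W, shift) {
  pal <- fixture_palette(spec$modality)
  n <- spec$n_channels
  L <- spec$channel_length; w <- spec$channel_width; ww <- spec$wall_width
  a <- spec$device_angle * pi / 180
  cy <- (H + 1) / 2 + shift[1]
  cx <- (W + 1) / 2 + shift[2]

  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse rotation into device coordinates
  U <- cos(a) * (rr - cy) + sin(a) * (cc - cx)
  V <- -sin(a) * (rr - cy) + cos(a) * (cc - cx)

  v0 <- -(n - 1) / 2 * spec$pitch # centre of channel 1
  j <- round((V - v0) / spec$pitch) + 1
  j[j < 1] <- 1L; j[j > n] <- n
  dv <- V - (v0 + (j - 1) * spec$pitch)

  interior <- abs(dv) <= w / 2 & U >= -L / 2 & U <= L / 2
  wall <- (abs(dv) <= w / 2 + ww & U >= -L / 2 - ww & U <= L / 2 + ww) &
    !interior

  img <- matrix(pal$bg, H, W)
  if (spec$illum_gradient > 0) {
    ramp <- pal$bg * spec$illum_gradient *
      (2 * (cc - 1) / (W - 1) - 1)
    img <- img + ramp
  }
  img[wall] <- pal$wall

  channel_labels <- matrix(0L, H, W)
  channel_labels[interior] <- j[interior]
  bacteria_labels <- matrix(0L, H, W)

  n_fluo <- spec$n_fluo
  fluo <- lapply(seq_len(n_fluo), function(i) matrix(spec$fluo_background, H, W))

  r_cell <- spec$cell_width / 2
  for (k in seq_len(n)) {
    ck <- cells[[k]]
    if (!nrow(ck)) next
    sel <- which(j == k & abs(dv) <= w / 2 + 2 &
                   U >= -L / 2 - 2 & U <= L / 2 + 2)
    uu <- U[sel]; vv <- dv[sel]
    for (p in seq_len(nrow(ck))) {
      u1 <- -L / 2 + ck$start[p] + r_cell
      u2 <- -L / 2 + ck$start[p] + ck$len[p] - r_cell
      du <- pmax(u1 - uu, 0, uu - u2)
      d2 <- du^2 + vv^2
      inside <- d2 <= r_cell^2
      img[sel[inside]] <- pal$cell
      if (!is.na(pal$halo)) {
        ring <- d2 > r_cell^2 & d2 <= (r_cell + 1.5)^2
        ring <- ring & channel_labels[sel] == k # halo stays in the channel
        img[sel[ring]] <- pal$halo
      }
      bacteria_labels[sel[inside]] <- ck$id[p]
      if (n_fluo > 0) {
        for (q in seq_len(n_fluo)) {
          fluo[[q]][sel[inside]] <- fluo[[q]][sel[inside]] + ck$fluo[p, q]
        }
      }
    }
  }

  contrast <- abs(pal$bg - pal$cell)
  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma * contrast),
                        H, W)
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  if (n_fluo > 0 && spec$fluo_noise_sd > 0) {
    fluo <- lapply(fluo, function(f)
      f + matrix(stats::rnorm(H * W, 0, spec$fluo_noise_sd), H, W))
  }

  # order channel labels left-to-right by centroid column
  cen <- label_centroids(channel_labels)
  ord <- order(cen[, 2])
  remap <- integer(n); remap[ord] <- seq_len(n)
  pos <- channel_labels > 0
  channel_labels[pos] <- remap[channel_labels[pos]]

  list(img = img, fluo = fluo, channel_labels = channel_labels,
       bacteria_labels = bacteria_labels)
}

#' @export
print.mm_fixture_series <- function(x, ...) {
  d <- dim(x$frames[[1]]$primary)
  cat(sprintf(
    "mm_fixture_series: %d frames of %dx%d px, %d channels, %s, %d cell tracks\n",
    length(x$frames), d[1], d[2], x$spec$n_channels, x$spec$modality,
    length(unique(x$truth$lineage$global_id))))
  invisible(x)
}
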