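# Independent oracles and shared fixture caching for the test suite.

# Exhaustive minimum-cross-entropy threshold search (Li & Lee criterion):
# evaluates the cross entropy at every candidate threshold between observed
# intensity values and returns the argmin. Intensities are canonicalised to
# the same positive baseline the fixed-point routine uses, so the two
# routes optimise the same objective by different means.
oracle_li_mask <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  y <- v - (rng[1] - 1e-8 * diff(rng))
  cand <- sort(unique(y))
  cand <- (cand[-1] + cand[-length(cand)]) / 2 # between consecutive values
  eta <- vapply(cand, function(t) {
    lo <- y[y <= t]; hi <- y[y > t]
    -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
  }, numeric(1))
  t_best <- cand[which.min(eta)]
  out <- y > t_best
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# Brute-force enumeration of tracking event strings: every assignment of
# {lysis, no-change, 1 division, 2 divisions} to each previous cell via
# expand.grid, plus new cells making up the count at the open end.
oracle_hypotheses <- function(n_prev, n_curr, division_cap = 2L) {
  children_opts <- 2^(0:division_cap)
  opts <- c(0L, children_opts) # children per cell; 0 = lysis
  if (n_prev == 0L) {
    return(list(list(counts = integer(0), divisions = integer(0),
                     n_new = n_curr)))
  }
  grid <- do.call(expand.grid, rep(list(opts), n_prev))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    counts <- as.integer(grid[i, ])
    used <- sum(counts)
    if (used > n_curr) next
    divs <- match(counts, children_opts, nomatch = 1L) - 1L
    divs[counts == 0L] <- 0L
    out[[length(out) + 1L]] <- list(counts = counts, divisions = divs,
                                    n_new = n_curr - used)
  }
  out
}

hypothesis_key <- function(h) {
  paste(paste(h$counts, collapse = ","), h$n_new, sep = "|")
}

# draw a rod (rectangle with semicircular caps) into a matrix; angle 0 runs
# along rows (a vertical, channel-confined cell), 90 along columns
draw_rod <- function(nr, nc, centre_r, centre_c, length, width,
                     angle = 0, value = 1, base = matrix(0, nr, nc)) {
  a <- angle * pi / 180
  u <- c(cos(a), sin(a))
  r <- width / 2
  half <- length / 2 - r
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  pr <- (rr - centre_r) * u[1] + (cc - centre_c) * u[2]
  po <- -(rr - centre_r) * u[2] + (cc - centre_c) * u[1]
  du <- pmax(abs(pr) - half, 0)
  base[du^2 + po^2 <= r^2] <- value
  base
}

# memoised default fixture series + analysis shared across test files
fixture_cache <- new.env(parent = emptyenv())

cached_series <- function() {
  if (is.null(fixture_cache$series)) {
    fixture_cache$series <- mm_generate_series(mm_fixture_spec(
      n_frames = 4, seed = 11, n_fluo = 1,
      division_schedule = data.frame(channel = 2, frame = 3, cell = 1),
      drift = c(1, -4)))
  }
  fixture_cache$series
}

cached_result <- function() {
  if (is.null(fixture_cache$result)) {
    fixture_cache$result <- suppressWarnings(mm_analyze(cached_series()))
  }
  fixture_cache$result
}
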