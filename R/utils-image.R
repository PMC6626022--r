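# Internal image helpers. Images are plain numeric matrices indexed
# (row, col), 1-based; label images are integer matrices with 0 = background.

#' @importFrom EBImage filter2 gblur makeBrush bwlabel fillHull dilate erode
#'   distmap propagate
NULL

mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = dim(x)[1])
}

# convolution with replicated borders
conv2 <- function(x, k) {
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  # pad by edge replication so the kernel never exceeds the image
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  pr <- max(0L, r - nrow(x) + 1L)
  pc <- max(0L, r - ncol(x) + 1L)
  if (pr > 0L || pc > 0L) {
    ri <- c(rep(1L, pr), seq_len(nrow(x)), rep(nrow(x), pr))
    ci <- c(rep(1L, pc), seq_len(ncol(x)), rep(ncol(x), pc))
    xp <- x[ri, ci, drop = FALSE]
    g <- as.matrix(EBImage::gblur(xp, sigma = sigma, boundary = "replicate"))
    g[pr + seq_len(nrow(x)), pc + seq_len(ncol(x)), drop = FALSE]
  } else {
    as.matrix(EBImage::gblur(x, sigma = sigma, boundary = "replicate"))
  }
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

label_components <- function(mask) {
  storage.mode(mask) <- "double"
  m <- as.matrix(EBImage::bwlabel(mask))
  storage.mode(m) <- "integer"
  m
}

fill_holes <- function(mask) {
  m <- as.matrix(EBImage::fillHull(mask * 1))
  m > 0
}

dilate_mask <- function(mask, radius) {
  as.matrix(EBImage::dilate(mask * 1, disc_brush(radius))) > 0
}

# grayscale morphological opening (erosion then dilation); the rolling-ball
# background estimate with a disc structuring element
gray_open <- function(x, radius) {
  b <- disc_brush(radius)
  as.matrix(EBImage::dilate(as.matrix(EBImage::erode(x, b)), b))
}

dist_transform <- function(mask) {
  as.matrix(EBImage::distmap(mask * 1))
}

# centroid (row, col) of each label 1..n; returns n x 2 matrix
label_centroids <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  cbind(
    tapply(rr, factor(lab, levels = seq_len(n)), mean),
    tapply(cc, factor(lab, levels = seq_len(n)), mean)
  )
}

label_areas <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

# (row, col) coordinates of the pixels of one label
label_pixels <- function(labels, id) {
  idx <- which(labels == id)
  cbind(((idx - 1L) %% nrow(labels)) + 1L,
        ((idx - 1L) %/% nrow(labels)) + 1L)
}

# boundary pixels of a binary mask (4-connectivity): mask pixels with at
# least one background 4-neighbour or on the image border
mask_boundary <- function(mask) {
  m <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] + pad[3:(nr + 2), 2:(nc + 1)] +
    pad[2:(nr + 1), 1:nc] + pad[2:(nr + 1), 3:(nc + 2)]
  core > 0 & nb < 4
}

# drop labels not in `keep`, renumber survivors 1..k preserving order
relabel_keep <- function(labels, keep) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
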