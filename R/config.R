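#' Pipeline configuration
#'
#' Builds the full set of tunable parameters for the analysis pipeline. All
#' length-dimensioned defaults are multiplied by `scale_factor` (areas by its
#' square) so that a single knob adapts the pipeline to a different
#' magnification.
#'
#' @param scale_factor Multiplier applied to every length-dimensioned default
#'   (vector length bounds, area bounds, structuring elements, filter scales).
#' @param n_fluo Number of fluorescence planes acquired per detection image.
#' @param modality One of `"auto"`, `"brightfield"`, `"phase"`; `"auto"`
#'   classifies each frame from its intensity-histogram skewness.
#' @param ... Named overrides for any of the defaults listed below.
#'
#' @return A list of class `mm_config` with components:
#' \describe{
#'   \item{channel_length_range}{Accepted channel axis-vector length, px
#'     (default 100--400).}
#'   \item{channel_width_range}{Accepted perpendicular channel width, px
#'     (default 5--40).}
#'   \item{channel_area_range}{Accepted channel-outline component area, px^2
#'     (default 500--50000).}
#'   \item{frangi_scales}{Gaussian scales for the ridge filter, px.}
#'   \item{dilation_radius}{Disc radius used to close outline gaps, px.}
#'   \item{min_channels}{Minimum detected channels for a frame to be accepted.}
#'   \item{rolling_ball_radius}{Radius of the rolling-ball background
#'     estimator, px.}
#'   \item{log_scales}{Laplacian-of-Gaussian scales for bacteria detection, px.}
#'   \item{marker_distance}{Distance-transform threshold generating watershed
#'     markers, px.}
#'   \item{bacteria_width_range, bacteria_area_range}{Size filters for
#'     candidate bacteria.}
#'   \item{split_k}{MAD multiplier for the skeleton-based splitting stage.}
#'   \item{p_no_change, p_division, p_lysis}{Event priors for the
#'     multiple-hypothesis tracker (sum to 1).}
#'   \item{area_sigma}{Scale of the Gaussian penalty on relative area change.}
#'   \item{centroid_sigma}{Scale of the centroid-displacement penalty, px;
#'     `NULL` means half the running median bacterium length.}
#'   \item{division_cap}{Maximum divisions per cell per frame interval.}
#'   \item{min_peak_correlation}{Normalised cross-correlation floor below
#'     which the frame shift falls back to (0, 0).}
#' }
#' @export
mm_config <- function(scale_factor = 1, n_fluo = 0, modality = "auto", ...) {
  stopifnot(scale_factor > 0, n_fluo >= 0)
  modality <- match.arg(modality, c("auto", "brightfield", "phase"))
  sf <- scale_factor
  cfg <- list(
    scale_factor = sf,
    n_fluo = as.integer(n_fluo),
    modality = modality,
    # channel detection
    channel_length_range = c(100, 400) * sf,
    channel_width_range  = c(5, 40) * sf,
    channel_area_range   = c(500, 50000) * sf^2,
    frangi_scales        = c(1, 1.5, 2, 2.5, 3) * sf,
    frangi_beta          = 0.5,
    dilation_radius      = max(1L, as.integer(round(2 * sf))),
    min_channels         = 3L,
    spacing_tol          = 0.3,
    # bacteria detection
    rolling_ball_radius  = max(2L, as.integer(round(10 * sf))),
    log_scales           = c(1.5, 2, 2.5, 3, 3.5) * sf,
    marker_distance      = 3 * sf,
    bacteria_width_range = c(2, 15) * sf,
    bacteria_area_range  = c(20, 2000) * sf^2,
    split_k              = 2,
    split_window         = 3L,
    # tracking
    p_no_change          = 0.9,
    p_division           = 0.07,
    p_lysis              = 0.03,
    area_sigma           = 0.2,
    centroid_sigma       = NULL,
    division_cap         = 2L,
    min_peak_correlation = 0.3,
    # geometry convention: end of the channel where new cells may appear
    open_end             = "high"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  pr <- cfg$p_no_change + cfg$p_division + cfg$p_lysis
  if (abs(pr - 1) > 1e-8) stop("event priors must sum to 1")
  class(cfg) <- "mm_config"
  cfg
}

#' @export
print.mm_config <- function(x, ...) {
  cat("mm_config (scale_factor =", x$scale_factor,
      ", n_fluo =", x$n_fluo, ", modality =", x$modality, ")\n")
  invisible(x)
}
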