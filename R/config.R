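#' Default analysis configuration
#'
#' Returns the full set of tunable parameters used by the measurement
#' pipeline, as a nested list.  Every stage of the pipeline takes a `config`
#' argument defaulting to this list, so a single modified copy (or a YAML
#' file read with [read_config()]) reproduces a whole run.
#'
#' Sections and defaults:
#' \describe{
#'   \item{canny}{`sigma` (Gaussian smoothing, px, default 2) and `low_frac`
#'     (low hysteresis threshold as a fraction of the Otsu-derived high
#'     threshold, default 0.55).}
#'   \item{hough}{`n_peaks` (number of accumulator peaks pooled into the
#'     median orientation, default 5), `theta_res_deg` (angular resolution,
#'     default 0.5), `min_sep_deg` / `min_sep_rho_px` (minimum peak
#'     separation, defaults 5 and 20), `min_votes` (minimum accumulator
#'     count for a usable peak, default 30).}
#'   \item{collimator}{`dilation_px`: radius of the disc used to dilate the
#'     border-connected zero region (default 5).}
#'   \item{width}{`first_line_offset_mm` (distance of the first width line
#'     below the lunate, default 5), `line_spacing_mm` (default 10),
#'     `smooth_window_rows` (running-median window for boundary smoothing,
#'     default 11), `max_missing_frac` (tolerated fraction of rows without a
#'     boundary pair, default 0.3).}
#'   \item{finger}{`roi_side_mm` (side of the square finger ROI, default 30),
#'     `peak_prominence_frac` (minimum peak prominence as a fraction of the
#'     profile dynamic range, default 0.05), `background_frac` (fraction of
#'     columns at each end of the profile used for the background level,
#'     default 0.1).}
#'   \item{lbp}{`roi_side_mm` (default 15), `offset_along_mm` (displacement
#'     from the styloid toward the lunate, default 10), `offset_proximal_mm`
#'     (displacement down the shaft, default 10).}
#'   \item{profile}{`edge_drop_frac` (termination when intensity falls below
#'     this fraction of the early-trace median, default 0.5),
#'     `short_segment_frac` (leading fraction of samples forming the short
#'     segment, default 0.5), `step_px` (sampling step, default 1).}
#' }
#'
#' @return Nested named list of parameters.
#' @seealso [read_config()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$hough$n_peaks
default_config <- function() {
  list(
    canny = list(sigma = 2, low_frac = 0.55),
    hough = list(n_peaks = 5L, theta_res_deg = 0.5, min_sep_deg = 5,
                 min_sep_rho_px = 20, min_votes = 30),
    collimator = list(dilation_px = 5L),
    width = list(first_line_offset_mm = 5, line_spacing_mm = 10,
                 smooth_window_rows = 11L, max_missing_frac = 0.3),
    finger = list(roi_side_mm = 30, peak_prominence_frac = 0.05,
                  background_frac = 0.1),
    lbp = list(roi_side_mm = 15, offset_along_mm = 10,
               offset_proximal_mm = 10),
    profile = list(edge_drop_frac = 0.5, short_segment_frac = 0.5,
                   step_px = 1)
  )
}

#' Read a configuration file
#'
#' Reads a YAML file containing any subset of the keys of
#' [default_config()] and merges it over the defaults; keys not present in
#' the file keep their default value.
#'
#' @param path Path to a YAML file.
#' @return Full configuration list (defaults overridden by the file).
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(default_config())
  modifyList(default_config(), user)
}
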