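#' Extract the central third of a radiograph
#'
#' Selects the central third of the image in both axes — the region where
#' the long bones of the forearm dominate — for orientation estimation.
#' The start index uses the floor and the length the ceiling of a third, so
#' the three thirds tile the image exactly.
#'
#' @param rad A [radiograph()].
#' @return List with `pixels` (the central sub-image) and `offset`
#'   `(row, col)`: `pixels[i, j]` equals the parent image at
#'   `(i + offset[1], j + offset[2])`.
#' @export
extract_central_region <- function(rad) {
  stopifnot(inherits(rad, "radiograph"))
  nr <- nrow(rad$pixels); nc <- ncol(rad$pixels)
  r0 <- floor(nr / 3); c0 <- floor(nc / 3)
  lr <- ceiling(nr / 3); lc <- ceiling(nc / 3)
  list(pixels = rad$pixels[(r0 + 1L):(r0 + lr), (c0 + 1L):(c0 + lc),
                           drop = FALSE],
       offset = c(r0, c0))
}

#' Estimate forearm orientation
#'
#' Computes Canny edges on the supplied sub-image, finds the strongest
#' Hough-transform line peaks (up to `config$hough$n_peaks`) and returns the
#' median of their angles measured from the vertical axis.  A positive angle
#' means the top of the forearm leans toward higher column indices.  If no
#' accumulator peak reaches `config$hough$min_votes`, the function warns and
#' returns 0 (identity rotation fallback).
#'
#' @param subimage Numeric matrix, typically from [extract_central_region()].
#' @param config Configuration list, see [default_config()].
#' @return Scalar angle in degrees in `(-90, 90]`, with the detected line
#'   table attached as attribute `"hough_lines"`.
#' @export
detect_orientation <- function(subimage, config = default_config()) {
  stopifnot(is.matrix(subimage))
  ed <- canny_edges(subimage, sigma = config$canny$sigma,
                    low_frac = config$canny$low_frac)
  hl <- hough_lines(ed, n_peaks = config$hough$n_peaks,
                    theta_res_deg = config$hough$theta_res_deg,
                    min_sep_deg = config$hough$min_sep_deg,
                    min_sep_rho_px = config$hough$min_sep_rho_px,
                    min_votes = config$hough$min_votes)
  if (nrow(hl) == 0L) {
    warning("no Hough line peaks found; assuming forearm already vertical")
    return(structure(0, hough_lines = hl))
  }
  # the forearm is near-vertical by acquisition protocol; orthogonal lines
  # (collimation edges, joint spaces) are discarded before taking the median
  near_vertical <- abs(hl$angle_deg) <= 45
  ang <- median(hl$angle_deg[if (any(near_vertical)) near_vertical
                             else rep(TRUE, nrow(hl))])
  if (ang <= -90) ang <- ang + 180
  structure(ang, hough_lines = hl)
}

#' Rotate a radiograph so the forearm becomes vertical
#'
#' Rotates the image by `-angle_deg` about its centre with bilinear
#' interpolation.  The output canvas is enlarged to contain the full rotated
#' frame; pixels outside the original frame are 0.  `angle_deg = 0` is an
#' exact identity fast path.
#'
#' @param rad A [radiograph()].
#' @param angle_deg Forearm angle from vertical in `(-90, 90]`, as returned
#'   by [detect_orientation()].
#' @return A [radiograph()] with the rotated pixels and unchanged
#'   `spacing_mm`; the forward point map (original `(row, col)` to rotated
#'   coordinates) is attached as attribute `"map"`.
#' @export
rotate_to_vertical <- function(rad, angle_deg) {
  stopifnot(inherits(rad, "radiograph"),
            angle_deg > -90, angle_deg <= 90)
  rot <- rotate_image(rad$pixels, -angle_deg)
  px <- rot$pixels
  px[px < 0] <- 0  # guard against interpolation undershoot
  out <- radiograph(px, rad$spacing_mm, rad$case_id, rad$meta)
  attr(out, "map") <- rot$map
  out
}

#' Detect the collimator border mask
#'
#' On digital radiographs the region outside the collimated field is stored
#' as exactly zero, while even the darkest exposed tissue stays above zero.
#' The mask is the union of connected components of exactly-zero pixels that
#' touch the image border, dilated by a disc to also swallow the bright
#' collimation edge lines.  Zero blobs in the interior are left alone.
#'
#' @param rad A [radiograph()].
#' @param dilation_px Disc radius for the morphological dilation.
#' @return Logical matrix, `TRUE` where pixels belong to the collimator
#'   region; all `FALSE` for strictly positive images.
#' @export
detect_collimator_mask <- function(rad, dilation_px = 5L) {
  stopifnot(inherits(rad, "radiograph"))
  px <- rad$pixels
  zero <- px == 0
  if (!any(zero)) return(matrix(FALSE, nrow(px), ncol(px)))
  lab <- EBImage::bwlabel(zero)
  border_labels <- unique(c(lab[1, ], lab[nrow(px), ], lab[, 1], lab[, ncol(px)]))
  border_labels <- border_labels[border_labels > 0]
  if (length(border_labels) == 0L)
    return(matrix(FALSE, nrow(px), ncol(px)))
  m0 <- matrix(as.numeric(lab %in% border_labels), nrow(px), ncol(px))
  if (dilation_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L, "disc")
    m0 <- EBImage::dilate(m0, brush)
  }
  m0 > 0
}

#' Preprocess a radiograph
#'
#' The automatic preprocessing stage: (1) detect and zero the collimator
#' border region, (2) estimate the forearm angle from the central third of
#' the image, (3) rotate the image so the forearm is vertical.  Landmarks
#' supplied on the original image are transformed by the same rotation.
#'
#' @param rad A [radiograph()].
#' @param landmarks Optional [landmark_set()] in original image coordinates.
#' @param config Configuration list, see [default_config()].
#' @return Object of class `wrist_preprocess`: a list with `image` (rotated,
#'   masked [radiograph()]), `rotation_deg` (applied forearm angle),
#'   `collimator_mask` (logical matrix in pre-rotation coordinates),
#'   `hough_lines` (line table used for orientation), `landmarks`
#'   (transformed, or `NULL`) and `map` (the point transform).
#' @export
preprocess_radiograph <- function(rad, landmarks = NULL,
                                  config = default_config()) {
  stopifnot(inherits(rad, "radiograph"))
  if (!is.null(landmarks)) {
    stopifnot(inherits(landmarks, "landmark_set"))
    check_landmarks_inside(landmarks, rad$pixels)
  }
  mask <- detect_collimator_mask(rad, config$collimator$dilation_px)
  px <- rad$pixels
  px[mask] <- 0
  rad2 <- radiograph(px, rad$spacing_mm, rad$case_id, rad$meta)
  ctr <- extract_central_region(rad2)
  ang <- detect_orientation(ctr$pixels, config)
  rotated <- rotate_to_vertical(rad2, as.numeric(ang))
  map <- attr(rotated, "map")
  attr(rotated, "map") <- NULL
  lm2 <- NULL
  if (!is.null(landmarks)) {
    lm2 <- landmark_set(
      lunate = as.numeric(map(landmarks$lunate)),
      styloid = as.numeric(map(landmarks$styloid)),
      finger = as.numeric(map(landmarks$finger)))
  }
  structure(
    list(image = rotated, rotation_deg = as.numeric(ang),
         collimator_mask = mask, hough_lines = attr(ang, "hough_lines"),
         landmarks = lm2, map = map),
    class = "wrist_preprocess")
}

#' @export
print.wrist_preprocess <- function(x, ...) {
  cat(sprintf("<wrist_preprocess> rotation %.2f deg, %d Hough line(s), %s collimator px\n",
              x$rotation_deg,
              if (is.null(x$hough_lines)) 0L else nrow(x$hough_lines),
              format(sum(x$collimator_mask))))
  invisible(x)
}
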