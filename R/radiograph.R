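#' Construct a radiograph object
#'
#' A radiograph is a 2-D grid of non-negative intensities together with the
#' physical pixel spacing.  All coordinates in this package are 1-based
#' `(row, col)` pairs with row 1 at the top of the image, matching R matrix
#' indexing.
#'
#' @param pixels Numeric matrix of intensities (rows x cols), all values
#'   `>= 0`, at least 64 rows and 64 columns.
#' @param spacing_mm Physical size of one pixel in millimetres (scalar;
#'   isotropic spacing is assumed).
#' @param case_id Opaque case identifier string.
#' @param meta Optional named list of acquisition metadata.
#' @return Object of class `radiograph` with fields `pixels`, `spacing_mm`,
#'   `case_id`, `meta`.
#' @export
#' @examples
#' r <- radiograph(matrix(1, 64, 64), spacing_mm = 0.2)
#' dim(r$pixels)
radiograph <- function(pixels, spacing_mm, case_id = "", meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    stop("radiograph must be at least 64 x 64 pixels")
  if (anyNA(pixels) || any(pixels < 0))
    stop("all intensities must be finite and >= 0")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("spacing_mm must be a positive scalar")
  structure(
    list(pixels = pixels, spacing_mm = as.numeric(spacing_mm),
         case_id = as.character(case_id), meta = meta),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %s: %d x %d px, %.4g mm/px, range [%.4g, %.4g]\n",
              if (nzchar(x$case_id)) x$case_id else "(unnamed)",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a landmark set
#'
#' The three manually placed landmarks anchoring all measurements: the base
#' of the lunate, the tip of the radial styloid and the centre of the
#' middle-finger metacarpal.  Points are `(row, col)` pairs; bounds against a
#' particular image are checked at pipeline stage, not here.
#'
#' @param lunate,styloid,finger Numeric length-2 vectors `(row, col)`.
#' @return Object of class `landmark_set`.
#' @export
#' @examples
#' lm <- landmark_set(c(390, 420), c(396, 486), c(225, 430))
landmark_set <- function(lunate, styloid, finger) {
  pts <- list(lunate = lunate, styloid = styloid, finger = finger)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || anyNA(p))
      stop(sprintf("landmark '%s' must be a numeric (row, col) pair", nm))
    pts[[nm]] <- as.numeric(p)
  }
  if (identical(pts$lunate, pts$styloid) || identical(pts$lunate, pts$finger) ||
      identical(pts$styloid, pts$finger))
    stop("the three landmarks must be pairwise distinct")
  structure(pts, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set> lunate (%.1f, %.1f), styloid (%.1f, %.1f), finger (%.1f, %.1f)\n",
    x$lunate[1], x$lunate[2], x$styloid[1], x$styloid[2],
    x$finger[1], x$finger[2]))
  invisible(x)
}

# check landmarks lie strictly inside an image; error names the offender
check_landmarks_inside <- function(landmarks, pixels) {
  for (nm in c("lunate", "styloid", "finger")) {
    p <- landmarks[[nm]]
    if (p[1] < 1 || p[1] > nrow(pixels) || p[2] < 1 || p[2] > ncol(pixels))
      stop(sprintf("landmark '%s' at (%.1f, %.1f) lies outside the image (%d x %d)",
                   nm, p[1], p[2], nrow(pixels), ncol(pixels)))
  }
  invisible(TRUE)
}

#' Study group labels
#'
#' The five group labels of the study design: healthy controls plus the four
#' fracture groups formed by crossing acquisition time (pre-/post-reduction)
#' with procedure outcome (successful/unsuccessful).
#'
#' @return Character vector of the five group labels.
#' @export
study_groups <- function() {
  c("control", "pre-successful", "pre-unsuccessful",
    "post-successful", "post-unsuccessful")
}

#' Measurement names and landmark families
#'
#' `measurement_names()` returns the 32 measurement names in canonical
#' order; `measurement_landmarks()` returns, for each measurement, the
#' landmark family it is anchored on (`Lunate`, `Finger`, `L+Rad Sty` or
#' `Radial Styloid`).
#'
#' @return Character vector of length 32 (named by measurement for
#'   `measurement_landmarks`).
#' @export
#' @examples
#' measurement_names()[1:3]
measurement_names <- function() {
  c("W1 / W4", "W2 / W4", "W3 / W4", "W5 / W4", "W6 / W4", "W7 / W4",
    "W8 / W4", "Min width / Max width", "W1+W8 / W4+W5", "W1+W2 / W7+W8",
    "Trabecular Area / Total Area", "Width Finger",
    paste("LBP", 1:10),
    "Slope profile 1 (full line)", "Slope profile 2 (full line)",
    "Slope profile 1 (short segment)", "Slope profile 2 (short segment)",
    "Std profile 1", "Std profile 2",
    "Std profile 1 adjusted", "Std profile 2 adjusted",
    "Distance profile 1", "Distance profile 2")
}

#' @rdname measurement_names
#' @export
measurement_landmarks <- function() {
  fam <- c(rep("Lunate", 10), rep("Finger", 2), rep("L+Rad Sty", 10),
           rep("Radial Styloid", 10))
  names(fam) <- measurement_names()
  fam
}
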