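# Radius texture via rotation-invariant uniform Local Binary Patterns over
# the 3x3 neighbourhood (8 neighbours).  With 8 sampling points the riu2
# mapping has exactly 10 pattern classes: 9 uniform classes indexed by the
# number of set bits (0..8) plus one catch-all class for non-uniform
# patterns, reported as "LBP 1" ... "LBP 10".

#' Locate the radius texture region of interest
#'
#' The ROI is placed automatically from the two wrist landmarks: starting at
#' the radial styloid, the centre is displaced `config$lbp$offset_along_mm`
#' along the unit vector toward the lunate and `config$lbp$offset_proximal_mm`
#' proximally (down the image, i.e. down the radius shaft), which lands it in
#' trabecular bone of the distal radius.  The ROI is a square of side
#' `config$lbp$roi_side_mm`.
#'
#' @param image A [radiograph()] (post-preprocess).
#' @param lunate,styloid Landmarks `(row, col)`.
#' @param config Configuration list.
#' @return Numeric matrix (the cropped ROI), with the integer centre
#'   attached as attribute `"centre"`.
#' @export
locate_texture_roi <- function(image, lunate, styloid,
                               config = default_config()) {
  stopifnot(inherits(image, "radiograph"))
  px <- image$pixels
  u <- c(lunate[1] - styloid[1], lunate[2] - styloid[2])
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("lunate and styloid landmarks coincide")
  u <- u / nu
  a <- config$lbp$offset_along_mm / image$spacing_mm
  b <- config$lbp$offset_proximal_mm / image$spacing_mm
  centre <- c(styloid[1] + a * u[1] + b, styloid[2] + a * u[2])
  side <- round(config$lbp$roi_side_mm / image$spacing_mm)
  half <- floor(side / 2)
  r <- round(centre[1]); c <- round(centre[2])
  if (r - half < 1 || r + half > nrow(px) || c - half < 1 ||
      c + half > ncol(px))
    stop(sprintf(
      "texture ROI (%d px square at (%d, %d)) exceeds image bounds; need %d px margins",
      2L * half + 1L, r, c, half))
  structure(px[(r - half):(r + half), (c - half):(c + half)],
            centre = c(r, c))
}

# riu2 lookup: for each 8-bit pattern, the 10-class index (1..10).
# Uniform patterns (<= 2 circular 0/1 transitions) map to 1 + popcount;
# all others to class 10.
lbp_riu2_table <- function() {
  codes <- 0:255
  bits <- t(vapply(codes, function(k) as.integer(intToBits(k))[1:8],
                   integer(8)))
  transitions <- rowSums(bits != bits[, c(2:8, 1)])
  popcount <- rowSums(bits)
  ifelse(transitions <= 2L, popcount + 1L, 10L)
}

#' Compute the 10-bin LBP texture histogram
#'
#' For every interior pixel of the ROI the 8 neighbours of its 3x3
#' neighbourhood are compared with the centre (neighbour `>=` centre counts
#' as 1; ties count as 1), in circular order starting at the east neighbour
#' and proceeding counterclockwise.  The resulting 8-bit pattern is mapped
#' to its rotation-invariant uniform (riu2) class — patterns with at most 2
#' circular 0/1 transitions map to their count of ones (classes 1..9 for
#' 0..8 ones), all remaining patterns to class 10 — and the class counts
#' are normalised to sum to 1.
#'
#' Because only order relations between neighbouring pixels enter, the
#' histogram is invariant to adding a constant to the ROI or multiplying it
#' by a positive constant.
#'
#' @param roi Numeric matrix, at least 16 x 16.
#' @return Named numeric vector of length 10 (`"LBP 1"` ... `"LBP 10"`),
#'   non-negative, summing to 1.
#' @export
#' @examples
#' compute_lbp_histogram(matrix(runif(1024), 32, 32))
compute_lbp_histogram <- function(roi) {
  if (!is.matrix(roi) || nrow(roi) < 16L || ncol(roi) < 16L)
    stop("LBP ROI must be a matrix of at least 16 x 16 pixels")
  nr <- nrow(roi); nc <- ncol(roi)
  ctr <- roi[2:(nr - 1L), 2:(nc - 1L)]
  # neighbour offsets (drow, dcol): E, NE, N, NW, W, SW, S, SE
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  code <- matrix(0L, nr - 2L, nc - 2L)
  for (k in seq_along(offs)) {
    d <- offs[[k]]
    nb <- roi[(2:(nr - 1L)) + d[1], (2:(nc - 1L)) + d[2]]
    code <- code + as.integer(nb >= ctr) * (2L^(k - 1L))
  }
  classes <- lbp_riu2_table()[code + 1L]
  h <- tabulate(classes, nbins = 10L)
  h <- h / sum(h)
  names(h) <- paste("LBP", 1:10)
  h
}
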