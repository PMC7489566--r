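# Middle-finger metacarpal measurements: a square ROI around the finger
# landmark is locally aligned so the bone is vertical, the intensities are
# projected onto the horizontal axis, and cortical/trabecular compartments
# are segmented on the projected profile.

#' Extract and vertically align the finger ROI
#'
#' Crops a square region of side `config$finger$roi_side_mm` centred on the
#' finger landmark, estimates the finger axis from the strongest Hough line
#' over Canny edges inside the ROI, and rotates the ROI so the axis is
#' vertical.  The global preprocessing aligns the forearm, not the fingers,
#' so a local correction is needed.  After rotation the largest inscribed
#' axis-aligned square is returned so that projection is not contaminated by
#' rotation fill.
#'
#' @param image A [radiograph()] (post-preprocess).
#' @param finger_landmark Finger landmark `(row, col)`.
#' @param config Configuration list.
#' @return List with `roi` (numeric matrix), `rotation_deg` (local finger
#'   angle from vertical that was corrected).
#' @export
extract_finger_roi <- function(image, finger_landmark,
                               config = default_config()) {
  stopifnot(inherits(image, "radiograph"))
  px <- image$pixels
  side <- round(config$finger$roi_side_mm / image$spacing_mm)
  half <- floor(side / 2)
  r <- round(finger_landmark[1]); c <- round(finger_landmark[2])
  if (r - half < 1 || r + half > nrow(px) || c - half < 1 ||
      c + half > ncol(px))
    stop(sprintf(
      "finger ROI (%d px square) exceeds image bounds around (%d, %d)",
      2L * half + 1L, r, c))
  roi <- px[(r - half):(r + half), (c - half):(c + half)]
  ed <- canny_edges(roi, sigma = config$canny$sigma,
                    low_frac = config$canny$low_frac)
  hl <- hough_lines(ed, n_peaks = 1L,
                    theta_res_deg = config$hough$theta_res_deg,
                    min_votes = config$hough$min_votes)
  if (nrow(hl) == 0L) {
    warning("no finger axis line found; using the ROI unrotated")
    return(list(roi = roi, rotation_deg = 0))
  }
  ang <- hl$angle_deg[1]
  if (ang != 0) {
    rot <- rotate_image(roi, -ang)
    roi <- crop_inscribed_square(rot$pixels, nrow(roi), ang)
  }
  list(roi = roi, rotation_deg = ang)
}

# central axis-aligned square of an image rotated by ang degrees that is
# guaranteed to contain only original content
crop_inscribed_square <- function(px, orig_side, ang) {
  a <- abs(ang) * pi / 180
  side_in <- floor(orig_side / (cos(a) + sin(a)))
  cy <- (nrow(px) + 1) / 2; cx <- (ncol(px) + 1) / 2
  half <- floor((side_in - 1) / 2)
  px[(round(cy) - half):(round(cy) + half),
     (round(cx) - half):(round(cx) + half)]
}

#' Project ROI intensities onto the horizontal axis
#'
#' Computes the mean intensity over rows for each column of a vertically
#' aligned finger ROI: a bright finger bone produces a characteristic
#' two-peak (cortical) profile with a dimmer trabecular plateau between.
#'
#' @param roi Numeric matrix (vertically aligned finger ROI).
#' @return Object of class `finger_profile`: list with `columns`
#'   (1-based positions) and `intensity` (mean per column).
#' @export
project_profile <- function(roi) {
  stopifnot(is.matrix(roi), ncol(roi) >= 3)
  structure(list(columns = seq_len(ncol(roi)),
                 intensity = as.numeric(colMeans(roi))),
            class = "finger_profile")
}

#' Segment cortical and trabecular bone on a projected profile
#'
#' Works entirely on the 1-D projected profile, mirroring the column-wise
#' shading of the finger figure: because cortical and trabecular regions
#' share the ROI height, their area ratio reduces to a ratio of interval
#' lengths on the profile.
#'
#' The segmentation rules are: background level = median of the outer
#' `config$finger$background_frac` of columns at each end; bone edges = the
#' outermost subpixel crossings of the level halfway between the background
#' and each side's cortical peak; cortical peaks = the two largest interior
#' local maxima with prominence at least
#' `config$finger$peak_prominence_frac` of the profile dynamic range;
#' trabecular region = the interval between the crossings of the level
#' halfway between each cortical peak and the central plateau minimum.
#'
#' @param profile A `finger_profile` from [project_profile()] (or a bare
#'   numeric vector of projected intensities).
#' @param config Configuration list.
#' @return List of class `finger_metrics` with `width_finger_px`,
#'   `trabecular_total_ratio`, and the annotated landmark positions
#'   `edges`, `cortical_peaks`, `trabecular_bounds`, `centre`.
#' @export
segment_cortical_trabecular <- function(profile, config = default_config()) {
  p <- if (inherits(profile, "finger_profile")) profile$intensity
       else as.numeric(profile)
  n <- length(p)
  if (n < 10L) stop("profile too short for segmentation")
  dyn <- diff(range(p))
  if (dyn == 0) stop("cortical peaks not found (flat profile)")
  nbg <- max(2L, ceiling(config$finger$background_frac * n))
  background <- median(c(p[seq_len(nbg)], p[(n - nbg + 1L):n]))

  pk <- local_maxima_prominence(p)
  pk <- pk[pk$prominence >= config$finger$peak_prominence_frac * dyn &
           pk$index > 1L & pk$index < n, , drop = FALSE]
  if (nrow(pk) < 2L) stop("cortical peaks not found")
  # the two cortical peaks: the highest pair of maxima separated by a real
  # valley (plateau-topped peaks register maxima at both plateau ends, so a
  # bare "two largest" rule could land on one band twice)
  pk <- pk[order(pk$index), , drop = FALSE]
  best <- NULL; best_score <- -Inf; best_sep <- -1
  for (i in seq_len(nrow(pk) - 1L)) {
    for (j in (i + 1L):nrow(pk)) {
      ii <- pk$index[i]; jj <- pk$index[j]
      score <- min(pk$value[i], pk$value[j])
      valley <- min(p[ii:jj])
      if (valley >= score - 0.1 * dyn) next
      sep <- jj - ii
      if (score > best_score + 1e-12 ||
          (abs(score - best_score) <= 1e-12 && sep > best_sep)) {
        best <- c(ii, jj); best_score <- score; best_sep <- sep
      }
    }
  }
  if (is.null(best)) stop("cortical peaks not found")
  il <- best[1]; ir <- best[2]

  # bone edges: outermost crossings of the half level on each side
  lev_l <- (background + p[il]) / 2
  lev_r <- (background + p[ir]) / 2
  edge_l <- cross_up_last(p, from = 1L, to = il, level = lev_l)
  edge_r <- cross_down_first_rev(p, from = ir, to = n, level = lev_r)
  if (is.na(edge_l) || is.na(edge_r)) stop("bone edges not found")

  # trabecular bounds: midpoint between each cortical peak and the central
  # minimum, crossed moving inward from each peak
  cmin <- min(p[il:ir])
  lev_tl <- (p[il] + cmin) / 2
  lev_tr <- (p[ir] + cmin) / 2
  t_l <- cross_down_first(p, from = il, to = ir, level = lev_tl)
  t_r <- cross_up_last2(p, from = il, to = ir, level = lev_tr)
  if (is.na(t_l) || is.na(t_r) || t_r <= t_l)
    stop("trabecular region not found")

  width <- edge_r - edge_l
  ratio <- (t_r - t_l) / width
  if (!(ratio > 0 && ratio < 1))
    stop("degenerate trabecular/total ratio")
  structure(list(width_finger_px = width,
                 trabecular_total_ratio = ratio,
                 edges = c(edge_l, edge_r),
                 cortical_peaks = c(il, ir),
                 trabecular_bounds = c(t_l, t_r),
                 centre = (il + ir) / 2,
                 background = background),
            class = "finger_metrics")
}

#' @export
print.finger_metrics <- function(x, ...) {
  cat(sprintf("<finger_metrics> width %.1f px, trabecular/total %.3f\n",
              x$width_finger_px, x$trabecular_total_ratio))
  invisible(x)
}

# local maxima with simple prominence (height above the higher of the two
# bracketing minima up to the nearest higher point on each side)
local_maxima_prominence <- function(p) {
  n <- length(p)
  idx <- which(diff(sign(diff(p))) < 0) + 1L
  if (length(idx) == 0L)
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    v <- p[i]
    lhs <- which(p[seq_len(i - 1L)] > v)
    lmin <- if (length(lhs)) min(p[(max(lhs) + 1L):(i - 1L)]) else min(p[1:i])
    rhs <- which(p[(i + 1L):n] > v)
    rmin <- if (length(rhs)) min(p[i:(i + min(rhs) - 1L)]) else min(p[i:n])
    v - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, value = p[idx], prominence = prom)
}

# subpixel crossing helpers (linear interpolation between samples)
cross_at <- function(p, i, level) {
  # crossing between samples i and i+1
  i + (level - p[i]) / (p[i + 1L] - p[i])
}
# outermost (leftmost) upward crossing of `level` in [from, to] (left edge)
cross_up_last <- function(p, from, to, level) {
  for (i in from:(to - 1L))
    if (p[i] < level && p[i + 1L] >= level) return(cross_at(p, i, level))
  NA_real_
}
# outermost (rightmost) downward crossing in [from, to] (right edge)
cross_down_first_rev <- function(p, from, to, level) {
  out <- NA_real_
  for (i in from:(to - 1L))
    if (p[i] >= level && p[i + 1L] < level) out <- cross_at(p, i, level)
  out
}
# first downward crossing after the left cortical peak (trabecular left bound)
cross_down_first <- function(p, from, to, level) {
  for (i in from:(to - 1L))
    if (p[i] >= level && p[i + 1L] < level) return(cross_at(p, i, level))
  NA_real_
}
# last upward crossing before the right cortical peak (trabecular right bound)
cross_up_last2 <- function(p, from, to, level) {
  out <- NA_real_
  for (i in from:(to - 1L))
    if (p[i] < level && p[i + 1L] >= level) out <- cross_at(p, i, level)
  out
}
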