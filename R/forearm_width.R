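# Forearm boundary tracing, the eight 1-cm-spaced width lines and the ten
# swelling ratios.  Assumes the forearm has been made vertical by
# preprocess_radiograph(), so "perpendicular to the forearm" is simply
# horizontal.

#' Trace the outer forearm boundaries below the lunate
#'
#' For every image row from the lunate row downward, finds the leftmost and
#' rightmost Canny edge columns — the outer soft-tissue (or cast) boundary
#' of the forearm — and smooths each boundary with a running median.  Rows
#' where no edge pair is found are linearly interpolated from neighbouring
#' rows; if more than `config$width$max_missing_frac` of the rows lack a
#' pair the forearm is considered undetectable.
#'
#' Edges falling in zero-valued regions (rotation fill or removed collimator
#' border) are ignored, so canvas borders do not masquerade as anatomy.
#'
#' @param image A vertically aligned [radiograph()] (post-preprocess).
#' @param lunate Lunate landmark `(row, col)` in the same coordinates.
#' @param config Configuration list, see [default_config()].
#' @return Data frame with columns `row`, `left`, `right` for rows from the
#'   lunate row to the bottom of the traceable region.
#' @export
trace_forearm_boundaries <- function(image, lunate,
                                     config = default_config()) {
  stopifnot(inherits(image, "radiograph"))
  px <- image$pixels
  if (lunate[1] < 1 || lunate[1] > nrow(px) || lunate[2] < 1 ||
      lunate[2] > ncol(px))
    stop("lunate landmark lies outside the image")
  ed <- canny_edges(px, sigma = config$canny$sigma,
                    low_frac = config$canny$low_frac)
  # only trust edges inside exposed (non-zero) content, eroded slightly so
  # the content/fill transition itself is excluded
  content <- matrix(as.numeric(px > 0), nrow(px), ncol(px))
  content <- EBImage::erode(content, EBImage::makeBrush(7L, "disc")) > 0
  ed <- ed & content
  r0 <- as.integer(round(lunate[1]))
  rows <- r0:nrow(px)
  left <- right <- rep(NA_real_, length(rows))
  for (i in seq_along(rows)) {
    cols <- which(ed[rows[i], ])
    if (length(cols) >= 2L) {
      left[i] <- cols[1]
      right[i] <- cols[length(cols)]
    }
  }
  # drop trailing rows with no boundary (image bottom / mask); keep interior
  last_ok <- max(which(!is.na(left)), 0L)
  if (last_ok < 5L) stop("forearm boundary not found")
  rows <- rows[seq_len(last_ok)]
  left <- left[seq_len(last_ok)]; right <- right[seq_len(last_ok)]
  frac_missing <- mean(is.na(left))
  if (frac_missing > config$width$max_missing_frac)
    stop(sprintf("forearm boundary not found (%.0f%% of rows have no edge pair)",
                 100 * frac_missing))
  left <- interp_na(left)
  right <- interp_na(right)
  w <- config$width$smooth_window_rows
  left <- stats::runmed(left, k = odd_window(w, length(left)))
  right <- stats::runmed(right, k = odd_window(w, length(right)))
  data.frame(row = rows, left = as.numeric(left), right = as.numeric(right))
}

# linear interpolation over NA runs (rule 2 extends end values)
interp_na <- function(v) {
  if (!anyNA(v)) return(v)
  idx <- seq_along(v)
  approx(idx[!is.na(v)], v[!is.na(v)], xout = idx, rule = 2)$y
}

odd_window <- function(w, n) {
  w <- min(as.integer(w), if (n %% 2L == 0L) n - 1L else n)
  if (w %% 2L == 0L) w <- w - 1L
  max(1L, w)
}

#' Measure the eight forearm width lines
#'
#' Places eight horizontal lines perpendicular to the (vertical) forearm:
#' line 1 sits `config$width$first_line_offset_mm` below the lunate row and
#' each subsequent line `config$width$line_spacing_mm` (1 cm by default)
#' further down.  W1 is the most distal line.  The width at a line is the
#' distance in pixels between the traced left and right boundaries at that
#' row.
#'
#' @param boundaries Data frame from [trace_forearm_boundaries()].
#' @param lunate Lunate landmark `(row, col)`.
#' @param spacing_mm Pixel spacing in millimetres.
#' @param config Configuration list.
#' @return Object of class `width_set`: list with `widths_px` (named
#'   `W1`...`W8`), `line_rows`, `spacing_mm`.
#' @export
measure_widths <- function(boundaries, lunate, spacing_mm,
                           config = default_config()) {
  stopifnot(is.data.frame(boundaries), spacing_mm > 0)
  gap <- round(config$width$line_spacing_mm / spacing_mm)
  first <- round(lunate[1]) + round(config$width$first_line_offset_mm / spacing_mm)
  line_rows <- first + (0:7) * gap
  if (max(line_rows) > max(boundaries$row))
    stop(sprintf("insufficient forearm extent: need rows to %d, boundary ends at %d",
                 max(line_rows), max(boundaries$row)))
  ix <- match(line_rows, boundaries$row)
  if (anyNA(ix)) stop("width line rows not covered by traced boundaries")
  widths <- boundaries$right[ix] - boundaries$left[ix]
  if (any(widths <= 0)) stop("non-positive forearm width measured")
  names(widths) <- paste0("W", 1:8)
  structure(list(widths_px = widths, line_rows = line_rows,
                 spacing_mm = spacing_mm),
            class = "width_set")
}

#' Compute the ten forearm width ratios
#'
#' The ten dimensionless swelling measurements derived from the eight width
#' lines: `Wi / W4` for i in 1, 2, 3, 5, 6, 7, 8; the ratio of the smallest
#' to the largest width; `(W1 + W8) / (W4 + W5)`; and
#' `(W1 + W2) / (W7 + W8)`.  Being ratios of pixel widths on the same
#' image, they are independent of pixel spacing.
#'
#' @param widthset A `width_set` from [measure_widths()], or a numeric
#'   vector of 8 positive widths.
#' @return Named numeric vector of the 10 ratios (names as in
#'   `measurement_names()[1:10]`).
#' @export
#' @examples
#' compute_ratios(c(12, 11, 10, 10, 10, 10, 11, 12))
compute_ratios <- function(widthset) {
  w <- if (inherits(widthset, "width_set")) widthset$widths_px else widthset
  if (length(w) != 8L) stop("exactly 8 widths are required")
  if (any(!is.finite(w)) || any(w <= 0)) stop("all widths must be positive")
  w <- as.numeric(w)
  out <- c(
    w[1] / w[4], w[2] / w[4], w[3] / w[4], w[5] / w[4], w[6] / w[4],
    w[7] / w[4], w[8] / w[4],
    min(w) / max(w),
    (w[1] + w[8]) / (w[4] + w[5]),
    (w[1] + w[2]) / (w[7] + w[8]))
  names(out) <- measurement_names()[1:10]
  out
}
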