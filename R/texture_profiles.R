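# Intensity-profile texture measurements: two lines traced from the radial
# styloid at 30 and 45 degrees from the lunate-styloid baseline, terminated
# where the intensity drops into the dark inter-bone gap at the edge of the
# radius, then summarised by slope, standard deviation (raw and detrended)
# and length.

#' Trace an intensity profile line from the radial styloid
#'
#' The baseline direction is the unit vector from the styloid to the lunate.
#' The profile direction is the baseline rotated by `offset_deg`; of the two
#' possible rotation senses the one whose first 10 samples are brighter is
#' kept, so the line enters the radius rather than leaving the bone.
#' Intensities are sampled with bilinear interpolation at
#' `config$profile$step_px` pixel steps until either the image border or the
#' radius edge: the trace terminates at the first sample (beyond the
#' reference window) whose intensity falls below
#' `config$profile$edge_drop_frac` times the median of the first quarter of
#' the full-length trace.
#'
#' @param image A [radiograph()] (post-preprocess).
#' @param lunate,styloid Landmarks `(row, col)`.
#' @param offset_deg Offset angle from the baseline: 30 or 45.
#' @param sense Either `"auto"` (brightness-resolved, default), `1` or `-1`
#'   to force a rotation sense.
#' @param config Configuration list.
#' @return Object of class `profile_trace`: list with `angle_offset_deg`,
#'   `positions_px` (0, 1, 2, ... arc length), `intensity`, `rows`, `cols`
#'   (sample coordinates), `terminated` (whether the edge-drop criterion
#'   fired before the border) and `direction` (unit `(drow, dcol)`).
#' @export
trace_profile <- function(image, lunate, styloid, offset_deg,
                          sense = "auto", config = default_config()) {
  stopifnot(inherits(image, "radiograph"), offset_deg %in% c(30, 45))
  px <- image$pixels
  base <- c(lunate[1] - styloid[1], lunate[2] - styloid[2])
  nb <- sqrt(sum(base^2))
  if (nb == 0) stop("lunate and styloid landmarks coincide")
  base <- base / nb
  rot_dir <- function(s) {
    a <- s * offset_deg * pi / 180
    # rotate (x = col, y = row) by a
    c(sin(a) * base[2] + cos(a) * base[1],
      cos(a) * base[2] - sin(a) * base[1])
  }
  step <- config$profile$step_px
  sample_dir <- function(d, nmax) {
    t <- seq_len(nmax) * step
    rows <- styloid[1] + t * d[1]
    cols <- styloid[2] + t * d[2]
    inside <- rows >= 1 & rows <= nrow(px) & cols >= 1 & cols <= ncol(px)
    k <- if (all(inside)) nmax else (which(!inside)[1] - 1L)
    if (k < 1L) return(NULL)
    list(rows = rows[seq_len(k)], cols = cols[seq_len(k)],
         intensity = bilinear_sample(px, rows[seq_len(k)], cols[seq_len(k)]))
  }
  if (identical(sense, "auto")) {
    s1 <- sample_dir(rot_dir(1), 10L)
    s2 <- sample_dir(rot_dir(-1), 10L)
    m1 <- if (is.null(s1)) -Inf else mean(s1$intensity)
    m2 <- if (is.null(s2)) -Inf else mean(s2$intensity)
    if (!is.finite(m1) && !is.finite(m2))
      stop("profile immediately terminated: styloid at the image border")
    sense <- if (m1 >= m2) 1 else -1
  }
  d <- rot_dir(sense)
  nmax <- ceiling(sqrt(nrow(px)^2 + ncol(px)^2) / step)
  full <- sample_dir(d, nmax)
  if (is.null(full) || length(full$intensity) < 5L)
    stop("profile immediately terminated: fewer than 5 samples")
  v <- full$intensity
  nref <- max(5L, floor(length(v) / 4))
  ref <- median(v[seq_len(min(nref, length(v)))])
  # the line must start on bone: its early intensity has to stand out
  # against the overall exposed-field level
  bg <- median(px[px > 0])
  if (ref <= 1.2 * bg)
    stop("profile immediately terminated: styloid region is not brighter than background")
  thr <- config$profile$edge_drop_frac * ref
  below <- which(v < thr)
  below <- below[below > 1L]
  terminated <- length(below) > 0L
  k <- if (terminated) below[1] - 1L else length(v)
  if (k < 5L) stop("profile immediately terminated: fewer than 5 samples")
  structure(list(angle_offset_deg = offset_deg,
                 positions_px = (seq_len(k) - 1L) * step,
                 intensity = v[seq_len(k)],
                 rows = full$rows[seq_len(k)], cols = full$cols[seq_len(k)],
                 terminated = terminated,
                 direction = d, sense = sense),
            class = "profile_trace")
}

#' Remove the linear trend from a profile
#'
#' Subtracts the least-squares straight line (intensity versus position)
#' from the trace so that slope-driven brightening does not inflate the
#' dispersion statistics.  The result has zero mean and zero least-squares
#' slope.
#'
#' @param trace A `profile_trace` from [trace_profile()], or a numeric
#'   vector of intensities (positions then default to 0, 1, 2, ...).
#' @return Numeric vector of detrended intensities.
#' @export
#' @examples
#' detrend_profile(2 * (0:20))  # a pure ramp detrends to zero
detrend_profile <- function(trace) {
  if (inherits(trace, "profile_trace")) {
    y <- trace$intensity; x <- trace$positions_px
  } else {
    y <- as.numeric(trace); x <- seq_along(y) - 1
  }
  stopifnot(length(y) >= 2L)
  fit <- stats::lm.fit(cbind(1, x), y)
  as.numeric(fit$residuals)
}

#' Summary statistics of a profile trace
#'
#' Computes the five per-line statistics: least-squares slope over the whole
#' trace (`slope_full`), slope over the leading short segment
#' (`slope_short`, the first `config$profile$short_segment_frac` of the
#' samples from the styloid end), sample standard deviation of the raw
#' intensities (`std_raw`), standard deviation after detrending
#' (`std_adjusted`) and the trace length in samples (`distance`, in pixels
#' at unit step).
#'
#' @param trace A `profile_trace` from [trace_profile()].
#' @param config Configuration list.
#' @return Named list of class `profile_stats` with `slope_full`,
#'   `slope_short`, `std_raw`, `std_adjusted`, `distance`.
#' @export
profile_statistics <- function(trace, config = default_config()) {
  stopifnot(inherits(trace, "profile_trace"))
  y <- trace$intensity; x <- trace$positions_px
  ls_slope <- function(xx, yy) {
    if (length(yy) < 2L) return(NA_real_)
    as.numeric(stats::cov(xx, yy) / stats::var(xx))
  }
  nshort <- max(2L, ceiling(config$profile$short_segment_frac * length(y)))
  structure(list(
    slope_full = ls_slope(x, y),
    slope_short = ls_slope(x[seq_len(nshort)], y[seq_len(nshort)]),
    std_raw = sd(y),
    std_adjusted = sd(detrend_profile(trace)),
    distance = length(y)), class = "profile_stats")
}

#' @export
print.profile_stats <- function(x, ...) {
  cat(sprintf(
    "<profile_stats> slope %.4g (short %.4g), sd %.4g (adjusted %.4g), %d px\n",
    x$slope_full, x$slope_short, x$std_raw, x$std_adjusted, x$distance))
  invisible(x)
}
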