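# Orchestration: preprocess a radiograph, run the four measurement
# families, assemble the 32-entry measurement vector, and run whole studies.

#' Measure one case
#'
#' Applies [preprocess_radiograph()] (transforming the landmarks by the
#' fitted rotation) and then the four measurement families: forearm width
#' ratios, finger metrics, LBP texture coefficients and intensity-profile
#' statistics.  A family that fails (e.g. a ROI that does not fit) yields
#' `NA` for its measurements with a diagnostic message; preprocessing
#' failures are fatal for the case.
#'
#' @param rad A [radiograph()].
#' @param landmarks A [landmark_set()] in original image coordinates (set
#'   `landmarks_prealigned = TRUE` if they were picked on an already
#'   preprocessed image).
#' @param config Configuration list, see [default_config()].
#' @param landmarks_prealigned If `TRUE`, landmarks are taken to be in the
#'   coordinates of the rotated image and are not transformed.
#' @return Named numeric vector of length 32 (names
#'   [measurement_names()]), with the landmark family of each entry as
#'   attribute `"landmark"` and the preprocessing result as attribute
#'   `"preprocess"`.
#' @export
run_case <- function(rad, landmarks, config = default_config(),
                     landmarks_prealigned = FALSE) {
  stopifnot(inherits(rad, "radiograph"), inherits(landmarks, "landmark_set"))
  check_landmarks_inside(landmarks, rad$pixels)
  pre <- tryCatch(
    preprocess_radiograph(rad,
                          landmarks = if (landmarks_prealigned) NULL else landmarks,
                          config = config),
    error = function(e) stop(sprintf("preprocess failed for case '%s': %s",
                                     rad$case_id, conditionMessage(e))))
  img <- pre$image
  lm <- if (landmarks_prealigned) landmarks else pre$landmarks
  vec <- rep(NA_real_, 32L)
  names(vec) <- measurement_names()

  run_family <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      message(sprintf("case '%s': %s measurements unavailable: %s",
                      rad$case_id, label, conditionMessage(e)))
      NULL
    })
  }

  widths <- run_family("forearm width", {
    b <- trace_forearm_boundaries(img, lm$lunate, config)
    ws <- measure_widths(b, lm$lunate, img$spacing_mm, config)
    compute_ratios(ws)
  })
  if (!is.null(widths)) vec[names(widths)] <- widths

  finger <- run_family("finger", {
    roi <- extract_finger_roi(img, lm$finger, config)
    fm <- segment_cortical_trabecular(project_profile(roi$roi), config)
    c("Trabecular Area / Total Area" = fm$trabecular_total_ratio,
      "Width Finger" = fm$width_finger_px)
  })
  if (!is.null(finger)) vec[names(finger)] <- finger

  lbp <- run_family("LBP texture", {
    roi <- locate_texture_roi(img, lm$lunate, lm$styloid, config)
    compute_lbp_histogram(roi)
  })
  if (!is.null(lbp)) vec[names(lbp)] <- lbp

  profiles <- run_family("intensity profile", {
    s1 <- profile_statistics(
      trace_profile(img, lm$lunate, lm$styloid, 30, config = config), config)
    s2 <- profile_statistics(
      trace_profile(img, lm$lunate, lm$styloid, 45, config = config), config)
    c("Slope profile 1 (full line)" = s1$slope_full,
      "Slope profile 2 (full line)" = s2$slope_full,
      "Slope profile 1 (short segment)" = s1$slope_short,
      "Slope profile 2 (short segment)" = s2$slope_short,
      "Std profile 1" = s1$std_raw,
      "Std profile 2" = s2$std_raw,
      "Std profile 1 adjusted" = s1$std_adjusted,
      "Std profile 2 adjusted" = s2$std_adjusted,
      "Distance profile 1" = s1$distance,
      "Distance profile 2" = s2$distance)
  })
  if (!is.null(profiles)) vec[names(profiles)] <- profiles

  attr(vec, "landmark") <- measurement_landmarks()
  attr(vec, "preprocess") <- pre
  vec
}

#' Run a whole study
#'
#' Measures every case of a case table and computes the seven group
#' contrasts.  Individual case failures are recorded (the case keeps `NA`
#' measurements) and are fatal only if every case fails.
#'
#' @param case_table Data frame with columns `case_id`, `group` (one of
#'   [study_groups()]) and `image` (path readable by [read_radiograph()]),
#'   or a list of ready-made [radiograph()] objects in an `image` column.
#' @param landmarks Named list mapping `case_id` to [landmark_set()]
#'   objects, e.g. from [read_landmarks()].
#' @param config Configuration list.
#' @param out_dir Optional directory; when given, `measurements.csv` and
#'   `comparisons.csv` are written there.
#' @param spacing_override Passed to [read_radiograph()] for PNG/TIFF input.
#' @return List with `study_table` (data frame: `case_id`, `group`, 32
#'   measurement columns) and `comparison` (a `comparison_table` from
#'   [compare_groups()], or `NULL` if fewer than two groups have two
#'   analysable cases).
#' @export
run_study <- function(case_table, landmarks, config = default_config(),
                      out_dir = NULL, spacing_override = NULL) {
  stopifnot(is.data.frame(case_table))
  if (nrow(case_table) == 0L) stop("empty case table")
  need <- c("case_id", "group", "image")
  missing <- setdiff(need, names(case_table))
  if (length(missing) > 0)
    stop(sprintf("case table is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  bad <- setdiff(unique(case_table$group), study_groups())
  if (length(bad) > 0)
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))

  rows <- vector("list", nrow(case_table))
  n_ok <- 0L
  for (i in seq_len(nrow(case_table))) {
    id <- as.character(case_table$case_id[i])
    vec <- rep(NA_real_, 32L)
    names(vec) <- measurement_names()
    res <- tryCatch({
      im <- case_table$image[[i]]
      rad <- if (inherits(im, "radiograph")) im
             else read_radiograph(im, spacing_override = spacing_override)
      lm <- landmarks[[id]]
      if (is.null(lm)) stop(sprintf("no landmarks for case '%s'", id))
      run_case(rad, lm, config)
    }, error = function(e) {
      message(sprintf("case '%s' failed: %s", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      vec[] <- as.numeric(res)
      n_ok <- n_ok + 1L
    }
    rows[[i]] <- data.frame(case_id = id,
                            group = as.character(case_table$group[i]),
                            t(vec), check.names = FALSE)
  }
  if (n_ok == 0L) stop("all cases failed")
  study_table <- do.call(rbind, rows)

  comparison <- NULL
  counts <- table(study_table$group[rowSums(is.finite(
    as.matrix(study_table[, measurement_names()]))) > 0])
  if (sum(counts >= 2L) >= 2L)
    comparison <- compare_groups(study_table)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_measurements(study_table, file.path(out_dir, "measurements.csv"))
    if (!is.null(comparison))
      write_comparison(comparison, file.path(out_dir, "comparisons.csv"))
  }
  list(study_table = study_table, comparison = comparison)
}
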