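# Synthetic wrist-radiograph phantoms with known ground truth.  The phantom
# emulates the features the measurement pipeline depends on: a rotated
# forearm containing two near-parallel bone bands (ulna and radius) with
# bright cortical margins and textured trabecular interiors, a hand region
# with a finger metacarpal showing cortical/trabecular banding, a dark
# inter-bone gap bounding the radius, an exactly-zero collimator frame, and
# landmarks placed on the rendered anatomy.  Anatomy is rendered upright and
# then rotated with the same bilinear operator used by the preprocessing
# stage, so recovery errors in tests isolate detection, not rendering.

#' Phantom generation parameters
#'
#' @param shape Image size `(rows, cols)` before rotation.
#' @param spacing_mm Pixel spacing in millimetres.
#' @param rotation_deg True forearm rotation applied to the rendered
#'   anatomy (angle from vertical, positive when the top leans toward
#'   higher columns).
#' @param widths_px True forearm width: a scalar (constant width) or a
#'   vector of 8 widths, one per nominal width-line position (W1 most
#'   distal); intermediate rows interpolate linearly.
#' @param cortical_px,trabecular_px Finger cortical band width and
#'   trabecular core width, in pixels.
#' @param background_intensity,soft_intensity,trabecular_intensity,cortical_intensity,lunate_intensity,gap_intensity
#'   Intensity levels of the rendered compartments.
#' @param noise_sd Standard deviation of the global white noise.
#' @param texture_sd,texture_scale Amplitude and correlation length (px) of
#'   the Gaussian-smoothed noise field added to trabecular interiors.
#' @param collimator_border_px Width of the exactly-zero collimator frame
#'   applied to the final canvas (0 disables it).
#' @param finger_angle_deg Local tilt of the finger metacarpal from
#'   vertical.
#' @param seed Integer seed; fixes the generated image exactly.
#' @return List of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(900L, 700L), spacing_mm = 0.2,
                           rotation_deg = 0, widths_px = 300,
                           cortical_px = 8L, trabecular_px = 24L,
                           background_intensity = 30, soft_intensity = 90,
                           trabecular_intensity = 150,
                           cortical_intensity = 220, lunate_intensity = 200,
                           gap_intensity = 40, noise_sd = 2,
                           texture_sd = 15, texture_scale = 3,
                           collimator_border_px = 40L,
                           finger_angle_deg = 0, seed = 1L) {
  if (length(widths_px) == 1L) widths_px <- rep(widths_px, 8L)
  stopifnot(length(shape) == 2L, all(shape >= 256), spacing_mm > 0,
            rotation_deg > -90, rotation_deg <= 90,
            length(widths_px) == 8L, all(widths_px > 0),
            cortical_px >= 2, trabecular_px >= 4,
            cortical_intensity > background_intensity,
            trabecular_intensity > background_intensity,
            noise_sd >= 0, texture_sd >= 0, texture_scale > 0,
            collimator_border_px >= 0)
  structure(as.list(environment()), class = "phantom_params")
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_phantom_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic wrist radiograph with known ground truth
#'
#' @param params A [phantom_params()] list.
#' @return List with `radiograph` (a [radiograph()]), `landmarks` (a
#'   [landmark_set()] in the coordinates of the generated image, i.e. after
#'   rotation) and `truth`, a list holding the generating quantities:
#'   `rotation_deg`, `widths_px` (true width at each of the 8 lines),
#'   `line_rows` (their pre-rotation rows), `finger_ratio` (true
#'   trabecular/total ratio), `radius_mask` and `forearm_mask` (logical,
#'   post-rotation), `collimator_mask` (logical, the applied zero frame),
#'   `gap_distance_px` (named, distance from the styloid to the radius edge
#'   along the 30- and 45-degree profile directions).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params(rotation_deg = 10, seed = 7))
#' ph$truth$rotation_deg
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  R <- as.integer(p$shape[1]); C <- as.integer(p$shape[2])
  sp <- p$spacing_mm
  r_w <- round(0.44 * R)              # wrist row (top of the radius)
  c0 <- round(C / 2)                  # forearm axis column
  r_bot <- R - 80L                    # proximal end of rendered forearm
  lunate_lm <- c(r_w - 6, c0 + max(p$widths_px) / 2 - 80)
  gap_rows <- round(10 / sp)
  first_row <- round(lunate_lm[1]) + round(5 / sp)
  line_rows <- first_row + (0:7) * gap_rows
  if (max(line_rows) + 20 > r_bot)
    stop("anatomy does not fit the frame: width lines extend past the forearm")

  half <- p$widths_px / 2
  h_fun <- function(r) {
    approx(line_rows, half, xout = r, rule = 2)$y
  }
  h_w <- h_fun(r_w)
  h_min <- min(half)
  ul1 <- round(c0 - h_min + 10); ul2 <- round(c0 - h_min + 80)
  ra1 <- round(c0 + h_min - 120); ra2 <- round(c0 + h_min - 10)
  if (ul2 + 10 >= ra1)
    stop("anatomy does not fit the frame: forearm too narrow for two bone bands")
  styloid_lm <- c(r_w, ra2 - 4)
  finger_c <- c0 + 80
  finger_r <- round(0.25 * R)
  f_half <- p$cortical_px + p$trabecular_px / 2

  with_phantom_seed(p$seed, {
    img <- matrix(p$background_intensity, R, C)
    radius_mask <- matrix(FALSE, R, C)
    forearm_mask <- matrix(FALSE, R, C)
    trab_mask <- matrix(FALSE, R, C)

    # hand soft tissue
    hand_cols <- max(1L, round(c0 - h_w)):min(C, round(c0 + h_w))
    img[50:(r_w - 1L), hand_cols] <- p$soft_intensity
    # forearm soft-tissue band with the prescribed width profile
    for (r in r_w:r_bot) {
      h <- h_fun(r)
      cc <- max(1L, round(c0 - h)):min(C, round(c0 + h))
      img[r, cc] <- p$soft_intensity
      forearm_mask[r, cc] <- TRUE
    }
    # dark radio-carpal space above the radius (terminates the wrong-sense
    # profile candidates) and inter-bone gap between ulna and radius
    img[(r_w - 15L):(r_w - 1L), (ra2 - 50L):(ra2 + 5L)] <- p$gap_intensity
    img[r_w:min(r_bot, r_w + 160L), (ul2 + 5L):(ra1 - 1L)] <- p$gap_intensity

    draw_bone <- function(img, rows, c1, c2) {
      img[rows, c1:c2] <- p$trabecular_intensity
      cw <- 6L
      img[rows, c1:(c1 + cw - 1L)] <- p$cortical_intensity
      img[rows, (c2 - cw + 1L):c2] <- p$cortical_intensity
      trab_mask[rows, (c1 + cw):(c2 - cw)] <<- TRUE
      img
    }
    img <- draw_bone(img, (r_w + 15L):r_bot, ul1, ul2)   # ulna
    img <- draw_bone(img, r_w:r_bot, ra1, ra2)           # radius
    radius_mask[r_w:r_bot, ra1:ra2] <- TRUE

    # lunate: bright ellipse just distal to the radius
    lc_r <- r_w - 10; lc_c <- lunate_lm[2]
    rr <- matrix(seq_len(R), R, C); cc <- matrix(rep(seq_len(C), each = R), R, C)
    lun <- ((rr - lc_r) / 9)^2 + ((cc - lc_c) / 11)^2 <= 1
    img[lun] <- p$lunate_intensity

    # finger metacarpal: cortical bands around a trabecular core, tilted by
    # finger_angle_deg from vertical
    tanf <- tan(p$finger_angle_deg * pi / 180)
    for (r in 60:(r_w - 20L)) {
      ctr <- finger_c + tanf * (finger_r - r)
      c1 <- round(ctr - f_half); c2 <- round(ctr + f_half)
      img[r, c1:c2] <- p$trabecular_intensity
      img[r, c1:(c1 + p$cortical_px - 1L)] <- p$cortical_intensity
      img[r, (c2 - p$cortical_px + 1L):c2] <- p$cortical_intensity
      trab_mask[r, (c1 + p$cortical_px):(c2 - p$cortical_px)] <- TRUE
    }
    finger_lm <- c(finger_r, finger_c)

    # trabecular texture: smoothed white noise
    if (p$texture_sd > 0) {
      noise <- gauss_blur(matrix(rnorm(R * C), R, C), p$texture_scale)
      noise <- noise / sd(noise) * p$texture_sd
      img[trab_mask] <- img[trab_mask] + noise[trab_mask]
    }
    if (p$noise_sd > 0)
      img <- img + matrix(rnorm(R * C, sd = p$noise_sd), R, C)
    img <- pmax(img, 0.5)  # exposed field is strictly positive

    # ground-truth profile gap distances, computed on the upright geometry
    base <- (lunate_lm - styloid_lm) / sqrt(sum((lunate_lm - styloid_lm)^2))
    gap_distance <- vapply(c(30, 45), function(off) {
      for (s in c(1, -1)) {
        a <- s * off * pi / 180
        d <- c(sin(a) * base[2] + cos(a) * base[1],
               cos(a) * base[2] - sin(a) * base[1])
        probe <- round(styloid_lm + 5 * d)
        if (radius_mask[probe[1], probe[2]]) {
          for (t in seq_len(2L * (ra2 - ra1))) {
            q <- round(styloid_lm + t * d)
            if (q[1] < 1 || q[1] > R || q[2] < 1 || q[2] > C ||
                !radius_mask[q[1], q[2]])
              return(t - 1)
          }
        }
      }
      NA_real_
    }, numeric(1))
    names(gap_distance) <- c("30", "45")

    # rotate anatomy and transform landmarks and masks alike
    if (p$rotation_deg != 0) {
      rot <- rotate_image(img, p$rotation_deg)
      img <- pmax(rot$pixels, 0)
      rot_mask <- function(m)
        rotate_image(matrix(as.numeric(m), R, C), p$rotation_deg)$pixels >= 0.5
      radius_mask <- rot_mask(radius_mask)
      forearm_mask <- rot_mask(forearm_mask)
      lunate_lm <- as.numeric(rot$map(lunate_lm))
      styloid_lm <- as.numeric(rot$map(styloid_lm))
      finger_lm <- as.numeric(rot$map(finger_lm))
    }

    # exactly-zero collimator frame on the final canvas
    b <- as.integer(p$collimator_border_px)
    collimator_mask <- matrix(FALSE, nrow(img), ncol(img))
    if (b > 0) {
      collimator_mask[c(seq_len(b), (nrow(img) - b + 1L):nrow(img)), ] <- TRUE
      collimator_mask[, c(seq_len(b), (ncol(img) - b + 1L):ncol(img))] <- TRUE
      img[collimator_mask] <- 0
      if (any(forearm_mask & collimator_mask))
        stop("anatomy does not fit the frame: forearm reaches the collimator border")
    }

    rad <- radiograph(img, sp, case_id = sprintf("phantom-%d", p$seed))
    list(
      radiograph = rad,
      landmarks = landmark_set(lunate = lunate_lm, styloid = styloid_lm,
                               finger = finger_lm),
      truth = list(
        rotation_deg = p$rotation_deg,
        widths_px = p$widths_px,
        line_rows = line_rows,
        finger_ratio = p$trabecular_px / (p$trabecular_px + 2 * p$cortical_px),
        radius_mask = radius_mask,
        forearm_mask = forearm_mask,
        collimator_mask = collimator_mask,
        gap_distance_px = gap_distance,
        params = p))
  })
}

#' Generate a synthetic measurement cohort
#'
#' Draws per-case measurement vectors directly from per-measurement normal
#' distributions (no image rendering), with optional group-level mean
#' shifts, for fast testing of the statistical stage.  Baseline means and
#' standard deviations are fixed per measurement family (ratios near 1,
#' LBP coefficients near 0.1, profile statistics on their natural scales).
#'
#' @param n_per_group Number of cases per study group (>= 2).
#' @param effect_spec Optional named list: names are measurement names, each
#'   element a named numeric vector of mean shifts in standard-deviation
#'   units keyed by group label, e.g.
#'   `list("LBP 4" = c("post-successful" = 3, "post-unsuccessful" = 3))`.
#' @param seed Integer seed.
#' @return Data frame with columns `case_id`, `group` and the 32
#'   measurements; `5 * n_per_group` rows.
#' @export
generate_cohort <- function(n_per_group, effect_spec = NULL, seed = 1L) {
  stopifnot(n_per_group >= 2)
  meas <- measurement_names()
  base_mean <- c(rep(1, 7), 0.9, 1, 1,      # width ratios
                 0.6, 40,                    # finger
                 rep(0.1, 10),               # LBP
                 0.3, 0.3, 0.3, 0.3,         # slopes
                 10, 10, 8, 8,               # stds
                 120, 120)                   # distances
  base_sd <- c(rep(0.05, 7), 0.03, 0.05, 0.05,
               0.05, 3,
               rep(0.02, 10),
               rep(0.1, 4),
               rep(2, 4),
               rep(15, 2))
  names(base_mean) <- names(base_sd) <- meas
  if (!is.null(effect_spec)) {
    bad <- setdiff(names(effect_spec), meas)
    if (length(bad) > 0)
      stop(sprintf("unknown measurement(s) in effect_spec: %s",
                   paste(bad, collapse = ", ")))
  }
  groups <- rep(study_groups(), each = n_per_group)
  n <- length(groups)
  with_phantom_seed(seed, {
    out <- data.frame(case_id = sprintf("case-%03d", seq_len(n)),
                      group = groups, stringsAsFactors = FALSE)
    for (m in meas) {
      mu <- rep(base_mean[m], n)
      if (!is.null(effect_spec[[m]])) {
        sh <- effect_spec[[m]]
        bad <- setdiff(names(sh), study_groups())
        if (length(bad) > 0)
          stop(sprintf("unknown group label(s) in effect_spec: %s",
                       paste(bad, collapse = ", ")))
        for (g in names(sh)) mu[groups == g] <- mu[groups == g] + sh[g] * base_sd[m]
      }
      out[[m]] <- rnorm(n, mean = mu, sd = base_sd[m])
    }
    out
  })
}
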