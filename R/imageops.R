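# Low-level raster operations shared by the preprocessing and measurement
# stages.  Images are plain numeric matrices (rows x cols, row 1 at top);
# line/rotation geometry uses x = col, y = row.

# replicate-pad a matrix by r pixels on every side
pad_replicate <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  img[c(rep(1L, r), seq_len(nr), rep(nr, r)),
      c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
}

# separable Gaussian blur, replicate boundary
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  p <- pad_replicate(img, r)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (i in 0:(2L * r))
    tmp <- tmp + k[i + 1L] * p[(1L + i):(nr + i), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in 0:(2L * r))
    out <- out + k[i + 1L] * tmp[, (1L + i):(nc + i), drop = FALSE]
  out
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sb2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sb2)]
}

# shift matrix content by (dr, dc), zero fill
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantised gradient direction and hysteresis thresholding.  The high
#' hysteresis threshold is derived automatically from the gradient-magnitude
#' distribution (Otsu's criterion); the low threshold is `low_frac` times
#' the high one.
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param low_frac Low threshold as a fraction of the high threshold.
#' @return Logical matrix of edge pixels, same shape as `img`.
#' @export
canny_edges <- function(img, sigma = 2, low_frac = 0.55) {
  stopifnot(is.matrix(img), low_frac > 0, low_frac <= 1)
  sm <- gauss_blur(img, sigma)
  p <- pad_replicate(sm, 1L)
  nr <- nrow(img); nc <- ncol(img)
  ix <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  # Sobel; gx along columns (x), gy along rows (y, downward)
  gx <- (ix(-1, 1) + 2 * ix(0, 1) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(0, -1) + ix(1, -1))
  gy <- (ix(1, -1) + 2 * ix(1, 0) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(-1, 0) + ix(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nr, nc))
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180  # orientation only
  sector <- (floor((ang + 22.5) / 45) %% 4)  # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  n1 <- matrix(0, nr, nc); n2 <- matrix(0, nr, nc)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    d <- offs[[as.character(s)]]
    a <- shift_mat(mag, -d[1], -d[2])  # neighbour at +d
    b <- shift_mat(mag, d[1], d[2])    # neighbour at -d
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  nms <- mag
  nms[mag < n1 | mag < n2] <- 0
  high <- otsu_threshold(mag[mag > 0])
  low <- low_frac * high
  weak <- nms >= low
  strong <- nms >= high
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nr, nc)
}

#' Hough transform line detection
#'
#' Standard line Hough transform over a binary edge map using the normal
#' parameterisation `x*cos(theta) + y*sin(theta) = rho` with `x = col`,
#' `y = row`.  For a line, `theta` equals the angle between the line and the
#' vertical image axis, so near-vertical structures yield `theta` near 0.
#' Peaks are extracted greedily by accumulator votes with a minimum
#' separation window; ties between equal-vote peaks go to the smaller
#' absolute angle.
#'
#' @param edges Logical matrix (e.g. from [canny_edges()]).
#' @param n_peaks Maximum number of peaks to return.
#' @param theta_res_deg Angular resolution in degrees.
#' @param min_sep_deg,min_sep_rho_px Minimum separation between peaks.
#' @param min_votes Minimum accumulator votes for a usable peak.
#' @return Data frame with columns `angle_deg` (angle from vertical, in
#'   `(-90, 90]`), `rho_px`, `votes`, and clipped segment endpoints
#'   `row1, col1, row2, col2`; zero rows if no peak reaches `min_votes`.
#' @export
hough_lines <- function(edges, n_peaks = 5L, theta_res_deg = 0.5,
                        min_sep_deg = 5, min_sep_rho_px = 20,
                        min_votes = 30) {
  stopifnot(is.matrix(edges))
  empty <- data.frame(angle_deg = numeric(0), rho_px = numeric(0),
                      votes = numeric(0), row1 = numeric(0), col1 = numeric(0),
                      row2 = numeric(0), col2 = numeric(0))
  idx <- which(edges != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  y <- idx[, 1]; x <- idx[, 2]
  thetas <- seq(-90, 90 - theta_res_deg, by = theta_res_deg)
  th <- thetas * pi / 180
  rho_max <- ceiling(sqrt(nrow(edges)^2 + ncol(edges)^2))
  nrho <- 2L * rho_max + 1L
  acc <- matrix(0L, length(thetas), nrho)
  for (j in seq_along(th)) {
    rho <- round(x * cos(th[j]) + y * sin(th[j])) + rho_max + 1L
    acc[j, ] <- tabulate(rho, nbins = nrho)
  }
  sep_t <- max(1L, as.integer(round(min_sep_deg / theta_res_deg)))
  sep_r <- max(1L, as.integer(round(min_sep_rho_px)))
  out <- empty
  for (k in seq_len(n_peaks)) {
    best <- max(acc)
    if (best < min_votes) break
    cand <- which(acc == best, arr.ind = TRUE)
    # ties: smallest |angle from vertical|
    a_cand <- abs(thetas[cand[, 1]])
    m <- cand[which.min(a_cand), , drop = TRUE]
    theta <- thetas[m[1]]
    rho <- m[2] - rho_max - 1L
    seg <- clip_line_to_image(theta, rho, nrow(edges), ncol(edges))
    out <- rbind(out, data.frame(angle_deg = theta, rho_px = rho,
                                 votes = best, row1 = seg[1], col1 = seg[2],
                                 row2 = seg[3], col2 = seg[4]))
    tr <- max(1L, m[1] - sep_t):min(length(thetas), m[1] + sep_t)
    rr <- max(1L, m[2] - sep_r):min(nrho, m[2] + sep_r)
    acc[tr, rr] <- 0L
  }
  out
}

# clip the line x cos(t) + y sin(t) = rho to the image rectangle;
# returns c(row1, col1, row2, col2) (NA if the line misses the rectangle)
clip_line_to_image <- function(theta_deg, rho, nr, nc) {
  t <- theta_deg * pi / 180
  ct <- cos(t); st <- sin(t)
  pts <- list()
  if (abs(st) > 1e-12) {
    for (x in c(1, nc)) {
      yy <- (rho - x * ct) / st
      if (yy >= 1 - 1e-9 && yy <= nr + 1e-9) pts[[length(pts) + 1L]] <- c(yy, x)
    }
  }
  if (abs(ct) > 1e-12) {
    for (y in c(1, nr)) {
      xx <- (rho - y * st) / ct
      if (xx >= 1 - 1e-9 && xx <= nc + 1e-9) pts[[length(pts) + 1L]] <- c(y, xx)
    }
  }
  if (length(pts) < 2L) return(rep(NA_real_, 4L))
  pm <- do.call(rbind, pts)
  d <- as.matrix(stats::dist(pm))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  c(pm[ij[1], ], pm[ij[2], ])
}

# bilinear sampling at fractional (row, col); 0 outside the image
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- numeric(length(rows))
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  val <- get(r0, c0) * (1 - fr) * (1 - fc) +
         get(r0 + 1, c0) * fr * (1 - fc) +
         get(r0, c0 + 1) * (1 - fr) * fc +
         get(r0 + 1, c0 + 1) * fr * fc
  val
}

# Rotate image content by angle_deg about its centre onto an enlarged canvas
# (fill 0), bilinear interpolation.  The forward point map sends (row, col)
# in the input to its location in the output; in (x = col, y = row)
# coordinates the content rotation matrix is [[cos, -sin], [sin, cos]].
# Returns list(pixels, map(points_matrix) -> points_matrix, inverse map).
rotate_image <- function(img, angle_deg) {
  nr <- nrow(img); nc <- ncol(img)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  if (angle_deg == 0) {
    idmap <- function(p) p
    return(list(pixels = img, map = idmap, inv_map = idmap))
  }
  nr2 <- as.integer(ceiling(abs(nr * ca) + abs(nc * sa)))
  nc2 <- as.integer(ceiling(abs(nc * ca) + abs(nr * sa)))
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  cy2 <- (nr2 + 1) / 2; cx2 <- (nc2 + 1) / 2
  # output grid -> input coords (inverse rotation)
  rr <- matrix(seq_len(nr2), nr2, nc2) - cy2
  cc <- matrix(rep(seq_len(nc2), each = nr2), nr2, nc2) - cx2
  src_x <- ca * cc + sa * rr + cx
  src_y <- -sa * cc + ca * rr + cy
  px <- matrix(bilinear_sample(img, as.vector(src_y), as.vector(src_x)),
               nr2, nc2)
  map <- function(p) {
    p <- matrix(p, ncol = 2)
    x <- p[, 2] - cx; y <- p[, 1] - cy
    cbind(sa * x + ca * y + cy2, ca * x - sa * y + cx2)
  }
  inv_map <- function(p) {
    p <- matrix(p, ncol = 2)
    x <- p[, 2] - cx2; y <- p[, 1] - cy2
    cbind(-sa * x + ca * y + cy, ca * x + sa * y + cx)
  }
  list(pixels = px, map = map, inv_map = inv_map)
}
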