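# Size/shape descriptors of the segmented brightfield object: 17 scalar
# measures plus 30 Zernike moment magnitudes (degree <= 9).

mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  data.frame(r = w[, 1], c = w[, 2])
}

# Crofton-style perimeter: pi/4 times the count of fg/bg transitions along
# rows and columns. Exact in expectation for smooth convex outlines.
mask_perimeter <- function(mask) {
  m <- mask * 1L
  h <- sum(abs(m[, -1] - m[, -ncol(m)])) + sum(m[, 1]) + sum(m[, ncol(m)])
  v <- sum(abs(m[-1, ] - m[-nrow(m), ])) + sum(m[1, ]) + sum(m[nrow(m), ])
  # half-pixel end correction per direction: a digitized extent of k pixels
  # corresponds to a continuous extent of about k - 1
  (pi / 4) * (max(h - 2, 2) + max(v - 2, 2))
}

# Euler number (components minus holes) via connected-component labelling;
# holes are background components not touching the padded border.
mask_euler <- function(mask) {
  n_comp <- max(EBImage::bwlabel(mask * 1))
  inv <- matrix(1, nrow(mask) + 2L, ncol(mask) + 2L)
  inv[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- 1 - mask
  lab <- EBImage::imageData(EBImage::bwlabel(inv))
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  n_holes <- length(setdiff(unique(lab[lab > 0]), border_labs))
  as.integer(n_comp - n_holes)
}

convex_hull_area <- function(coords) {
  if (nrow(coords) < 3) return(nrow(coords))
  h <- grDevices::chull(coords$c, coords$r)
  x <- coords$c[h]; y <- coords$r[h]
  n <- length(h)
  a <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  # Pick-style correction: hull vertices are pixel centres, pixels have extent
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  a + per / 2 + 1
}

feret_diameters <- function(coords) {
  h <- if (nrow(coords) >= 3) grDevices::chull(coords$c, coords$r)
       else seq_len(nrow(coords))
  x <- coords$c[h]; y <- coords$r[h]
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  max_f <- sqrt(max(d2)) + 1
  angles <- seq(0, pi, length.out = 90L)[-90L]
  widths <- vapply(angles, function(a) {
    p <- x * cos(a) + y * sin(a)
    diff(range(p)) + 1
  }, numeric(1))
  c(min_feret = min(widths), max_feret = max_f)
}

#' Shape features of a binary object mask
#'
#' Seventeen scalar descriptors (area, Crofton perimeter, form factor
#' 4*pi*A/P^2, moment-ellipse eccentricity/orientation/axes, solidity,
#' extent, Euler number, compactness, equivalent diameter, distance-map
#' radii, Feret diameters) followed by the magnitudes of all Zernike
#' moments with degree n <= 9 (30 values), computed on the mask mapped to
#' the unit disk around its centroid.
#'
#' @param mask logical/0-1 matrix containing a single object.
#' @return named numeric vector of length 47.
#' @export
shape_features <- function(mask) {
  mask <- mask > 0
  area <- sum(mask)
  if (area == 0) stop("empty mask")
  co <- mask_coords(mask)
  cen <- c(r = mean(co$r), c = mean(co$c))
  dr <- co$r - cen["r"]; dc <- co$c - cen["c"]
  # second central moments with 1/12 pixel-extent correction
  mrr <- mean(dr^2) + 1 / 12; mcc <- mean(dc^2) + 1 / 12; mrc <- mean(dr * dc)
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2; l2 <- (mrr + mcc - common) / 2
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- sqrt(max(0, 1 - l2 / max(l1, .Machine$double.eps)))
  orient <- 0.5 * atan2(2 * mrc, mcc - mrr)
  per <- mask_perimeter(mask)
  dmap <- EBImage::imageData(EBImage::distmap(mask * 1))
  radii <- dmap[mask]
  d2 <- dr^2 + dc^2
  fer <- feret_diameters(co)
  scalars <- c(
    area = area,
    perimeter = per,
    form_factor = 4 * pi * area / per^2,
    eccentricity = ecc,
    solidity = area / convex_hull_area(co),
    extent = area / (diff(range(co$r)) + 1) / (diff(range(co$c)) + 1),
    euler_number = mask_euler(mask),
    orientation = orient,
    major_axis_length = major,
    minor_axis_length = minor,
    compactness = 2 * pi * mean(d2) / area,
    equivalent_diameter = sqrt(4 * area / pi),
    max_radius = max(radii),
    mean_radius = mean(radii),
    median_radius = median(radii),
    min_feret = unname(fer["min_feret"]),
    max_feret = unname(fer["max_feret"])
  )
  c(scalars, zernike_magnitudes(mask, degree = 9L))
}

# (n, m) index pairs for Zernike moments with n <= degree, m >= 0, m == n mod 2.
zernike_index <- function(degree = 9L) {
  idx <- do.call(rbind, lapply(0:degree, function(n) {
    m <- seq(n %% 2, n, by = 2)
    cbind(n = n, m = m)
  }))
  as.data.frame(idx)
}

# Radial polynomial R_nm(rho), vectorised over rho.
zernike_radial <- function(n, m, rho) {
  s_max <- (n - m) / 2
  out <- numeric(length(rho))
  for (s in 0:s_max) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

#' Zernike moment magnitudes of a mask on the unit disk
#'
#' The mask is centred on its centroid and scaled so its most distant pixel
#' lies on the unit circle; moments are `(n+1)/pi * sum(f * conj(V_nm))`
#' with `f` the pixel indicator normalised to unit mass, which makes the
#' magnitudes scale-invariant.
#'
#' @param mask logical/0-1 matrix.
#' @param degree maximum Zernike degree (default 9, giving 30 moments).
#' @return named numeric vector `zernike_<n>_<m>`.
#' @export
zernike_magnitudes <- function(mask, degree = 9L) {
  mask <- mask > 0
  co <- mask_coords(mask)
  dr <- co$r - mean(co$r); dc <- co$c - mean(co$c)
  rad <- sqrt(max(dr^2 + dc^2))
  if (rad == 0) rad <- 1
  rho <- sqrt(dr^2 + dc^2) / rad
  theta <- atan2(dr, dc)
  keep <- rho <= 1
  rho <- rho[keep]; theta <- theta[keep]
  f <- rep(1 / length(rho), length(rho))
  idx <- zernike_index(degree)
  vals <- vapply(seq_len(nrow(idx)), function(k) {
    n <- idx$n[k]; m <- idx$m[k]
    R <- zernike_radial(n, m, rho)
    z <- sum(f * R * exp(-1i * m * theta)) * (n + 1) / pi
    Mod(z)
  }, numeric(1))
  names(vals) <- sprintf("zernike_%d_%d", idx$n, idx$m)
  vals
}
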