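# Intensity and radial-distribution descriptors. Both operate either on a
# masked object (brightfield) or on the full frame (darkfield, which is
# deliberately never segmented).

# 1-px inner boundary of a mask (fg pixels 4-adjacent to bg); for a full
# frame, the outermost border row/columns.
edge_region <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !core
}

#' Intensity features over a region
#'
#' Sixteen values: integrated, mean, s.d., MAD (raw median absolute
#' deviation), min, max, median, lower/upper quartile, range; integrated,
#' mean, s.d., min and max over the region's 1-px inner boundary (the
#' border frame for full-frame regions); and the mass displacement, i.e.
#' the distance between the intensity-weighted and unweighted centroids.
#'
#' @param image 2-D numeric matrix.
#' @param mask optional logical mask; `NULL` means the full frame.
#' @param prefix name prefix for the returned vector.
#' @return named numeric vector of length 16.
#' @export
intensity_features <- function(image, mask = NULL, prefix = "int") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- mask > 0
  if (!any(mask)) stop("empty region")
  x <- image[mask]
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
  edge <- edge_region(mask)
  e <- image[edge]
  co <- which(mask, arr.ind = TRUE)
  w <- x - min(x)
  cen_u <- colMeans(co)
  cen_w <- if (sum(w) > 0) colSums(co * w) / sum(w) else cen_u
  vals <- c(
    integrated = sum(x),
    mean = mean(x),
    sd = if (length(x) > 1) sd(x) else 0,
    mad = median(abs(x - q[2])),
    min = min(x),
    max = max(x),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    range = max(x) - min(x),
    edge_integrated = sum(e),
    edge_mean = mean(e),
    edge_sd = if (length(e) > 1) sd(e) else 0,
    edge_min = min(e),
    edge_max = max(e),
    mass_displacement = sqrt(sum((cen_w - cen_u)^2))
  )
  names(vals) <- paste(prefix, names(vals), sep = "_")
  vals
}

#' Radial intensity distribution over concentric rings
#'
#' The region (mask or full frame) is divided into `n_rings` equal-width
#' annuli from the centre (mask centroid, or the frame centre for
#' full-frame regions) out to the most distant region pixel. Per ring:
#' `frac_at_d` (fraction of total regional intensity), `mean_frac`
#' (`frac_at_d` normalised by the ring's share of region area) and
#' `radial_cv` (coefficient of variation of mean intensity over
#' `n_wedges` equal angular sectors within the ring).
#'
#' @param image 2-D numeric matrix.
#' @param mask optional logical mask; `NULL` means full frame.
#' @param center optional `(row, col)` centre override.
#' @param n_rings number of annuli (default 4).
#' @param n_wedges number of angular sectors for `radial_cv` (default 8).
#' @param prefix name prefix.
#' @return named numeric vector of length `3 * n_rings`.
#' @export
radial_distribution <- function(image, mask = NULL, center = NULL,
                                n_rings = 4L, n_wedges = 8L,
                                prefix = "rad") {
  full_frame <- is.null(mask)
  if (full_frame) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- mask > 0
  if (!any(mask)) stop("empty region")
  co <- which(mask, arr.ind = TRUE)
  if (is.null(center))
    center <- if (full_frame) (c(nrow(image), ncol(image)) + 1) / 2
              else colMeans(co)
  dr <- co[, 1] - center[1]; dc <- co[, 2] - center[2]
  d <- sqrt(dr^2 + dc^2)
  R <- max(d)
  ring <- pmin(floor(d / (R / n_rings)), n_rings - 1L) + 1L
  wedge <- (floor((atan2(dr, dc) + pi) / (2 * pi / n_wedges)) %% n_wedges) + 1L
  x <- image[mask]
  total <- sum(x)
  out <- numeric(0)
  if (total <= 0) {
    out <- rep(0, 3L * n_rings)
    names(out) <- as.vector(vapply(seq_len(n_rings), function(i)
      paste0(prefix, "_", c("frac_at_d", "mean_frac", "radial_cv"), "_", i),
      character(3)))
    attr(out, "qc_zero_intensity") <- TRUE
    return(out)
  }
  area_tot <- length(x)
  for (i in seq_len(n_rings)) {
    in_ring <- ring == i
    frac <- sum(x[in_ring]) / total
    afrac <- sum(in_ring) / area_tot
    mean_frac <- if (afrac > 0) frac / afrac else 0
    wmeans <- tapply(x[in_ring], wedge[in_ring], mean)
    rcv <- if (length(wmeans) > 1 && mean(wmeans) != 0)
      sd(wmeans) / abs(mean(wmeans)) else 0
    v <- c(frac, mean_frac, rcv)
    names(v) <- paste0(prefix, "_", c("frac_at_d", "mean_frac", "radial_cv"),
                       "_", i)
    out <- c(out, v)
  }
  out
}
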