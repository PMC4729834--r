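#' Default segmentation parameters
#'
#' @param min_area smallest object area (px^2) accepted as a cell; smaller
#'   components are treated as debris.
#' @param closing_size diameter of the disc brush used for morphological
#'   closing of the thresholded edge map.
#' @param border_heavy_frac fraction of object pixels on the outermost
#'   image row/column above which the `touches_border_heavily` flag is set.
#' @return named list of parameters.
#' @export
segmentation_params <- function(min_area = 50L, closing_size = 5L,
                                border_heavy_frac = 0.05) {
  list(min_area = as.integer(min_area), closing_size = as.integer(closing_size),
       border_heavy_frac = border_heavy_frac)
}

# 3x3 Sobel gradient magnitude; removes any constant (DC) intensity offset.
sobel_gradient <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(img, kx, boundary = "replicate")
  gy <- EBImage::filter2(img, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, n_breaks = 256L) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_breaks + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_breaks)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / w1
  m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
  between <- w1 * w2 * (m1 - m2)^2
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Label-free segmentation of a brightfield tile
#'
#' Pipeline: Sobel gradient-magnitude edge enhancement, global Otsu
#' threshold on the enhanced image (floored at the background mean plus two
#' background standard deviations of the enhanced image's border frame),
#' morphological closing, hole filling, connected-component labelling, and
#' retention of the largest component. The darkfield channel is never read:
#' side scatter does not depict the cell's physical outline and is used
#' whole-frame downstream.
#'
#' @param tile 2-D numeric brightfield matrix (standard reshaped size).
#' @param params a [segmentation_params()] list.
#' @return An object of class `segmentation_result` with fields `mask`
#'   (binary matrix), `object_found`, `area`, and `qc_flags` (subset of
#'   `no_object`, `too_small`, `multiple_objects`,
#'   `touches_border_heavily`, `missing_values`).
#' @export
segment_brightfield <- function(tile, params = segmentation_params()) {
  stopifnot(is.matrix(tile))
  qc <- character(0)
  mask <- matrix(FALSE, nrow(tile), ncol(tile))
  if (any(!is.finite(tile))) {
    qc <- c(qc, "missing_values")
    finite_vals <- tile[is.finite(tile)]
    tile[!is.finite(tile)] <- if (length(finite_vals)) median(finite_vals) else 0
  }
  grad <- sobel_gradient(tile)
  if (max(grad) < 1e-8) {            # flat tile (up to FFT round-off)
    return(structure(list(mask = mask, object_found = FALSE, area = 0L,
                          qc_flags = union(qc, "no_object")),
                     class = "segmentation_result"))
  }
  bg <- estimate_background(grad)
  bvals <- bg(4000L)
  floor_thr <- mean(bvals) + 2 * stats::sd(bvals)
  thr <- max(otsu_threshold(as.numeric(grad)), floor_thr)
  bw <- grad > thr
  if (!any(bw)) {
    return(structure(list(mask = mask, object_found = FALSE, area = 0L,
                          qc_flags = union(qc, "no_object")),
                     class = "segmentation_result"))
  }
  bw <- EBImage::closing(EBImage::Image(bw * 1),
                         EBImage::makeBrush(params$closing_size, "disc"))
  bw <- EBImage::fillHull(bw)
  # the gradient magnitude straddles the true boundary by about one pixel;
  # a single 4-neighbourhood erosion recentres the mask on the outline
  bw <- EBImage::erode(bw, matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3))
  lab <- EBImage::bwlabel(bw)
  labm <- EBImage::imageData(lab)
  n_obj <- max(labm)
  if (n_obj == 0) {
    return(structure(list(mask = mask, object_found = FALSE, area = 0L,
                          qc_flags = union(qc, "no_object")),
                     class = "segmentation_result"))
  }
  areas <- tabulate(labm[labm > 0], n_obj)
  if (sum(areas >= params$min_area) > 1L) qc <- c(qc, "multiple_objects")
  best <- which.max(areas)
  mask <- labm == best
  area <- areas[best]
  if (area < params$min_area) {
    return(structure(list(mask = matrix(FALSE, nrow(tile), ncol(tile)),
                          object_found = FALSE, area = as.integer(area),
                          qc_flags = union(qc, "too_small")),
                     class = "segmentation_result"))
  }
  border_px <- sum(mask[1, ]) + sum(mask[nrow(mask), ]) +
    sum(mask[, 1]) + sum(mask[, ncol(mask)])
  if (border_px > params$border_heavy_frac * area)
    qc <- c(qc, "touches_border_heavily")
  structure(list(mask = mask, object_found = TRUE, area = as.integer(area),
                 qc_flags = qc),
            class = "segmentation_result")
}

#' Quality-control partition of segmentation results
#'
#' The default policy discards cells with no object, too-small objects, or
#' missing pixel values. Cells flagged `multiple_objects` are kept by
#' default: telophase cells legitimately present as doublets, and dropping
#' them would bias the mitotic classes. The policy is configurable and the
#' decision is recorded per cell.
#'
#' @param results list of `segmentation_result`.
#' @param discard_flags QC flags that cause a cell to be discarded.
#' @return data.frame with columns `index`, `kept`, `reasons`.
#' @export
qc_filter <- function(results,
                      discard_flags = c("no_object", "too_small",
                                        "missing_values")) {
  kept <- vapply(results, function(r)
    !length(intersect(r$qc_flags, discard_flags)), logical(1))
  reasons <- vapply(results, function(r) {
    bad <- intersect(r$qc_flags, discard_flags)
    if (length(bad)) paste(bad, collapse = ";") else ""
  }, character(1))
  data.frame(index = seq_along(results), kept = kept, reasons = reasons,
             stringsAsFactors = FALSE)
}
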