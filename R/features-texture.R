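# Gray-level co-occurrence (Haralick) texture and the morphological
# granularity spectrum.

# Quantize region pixels to integer levels 0..levels-1 by linear min-max
# binning; values exactly on a bin edge fall in the lower bin. Constant
# regions map to level 0 everywhere.
quantize_region <- function(image, mask, levels = 8L) {
  x <- image
  rng <- range(x[mask])
  q <- matrix(NA_integer_, nrow(x), ncol(x))
  if (diff(rng) < .Machine$double.eps) {
    q[mask] <- 0L
    return(q)
  }
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  iv <- findInterval(x[mask], edges, left.open = TRUE, rightmost.closed = TRUE)
  q[mask] <- pmin(pmax(iv, 1L), levels) - 1L
  q
}

glcm_offsets <- function(scale)
  list(c(0L, scale), c(scale, 0L), c(scale, scale), c(scale, -scale))

# Symmetric, normalised co-occurrence matrix for one offset over the
# region (both pixels of a pair must lie in the region).
glcm_one <- function(q, offset, levels = 8L) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, levels, levels))
  ia <- a[ok]; ib <- b[ok]
  counts <- matrix(0, levels, levels)
  tab <- tabulate(ia * levels + ib + 1L, levels * levels)
  counts <- matrix(tab, levels, levels, byrow = TRUE)
  counts <- counts + t(counts)
  counts / sum(counts)
}

# The 13 Haralick statistics of a normalised GLCM (log base 2; degenerate
# cases take the documented conventions: correlation 0 when a marginal has
# zero variance, information measures 0 when undefined).
haralick_stats <- function(p) {
  levels <- nrow(p)
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(seq_len(levels) * px); my <- sum(seq_len(levels) * py)
  sx <- sqrt(sum((seq_len(levels) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(levels) - my)^2 * py))
  lg <- function(v) ifelse(v > 0, log2(v), 0)
  mu <- sum(i * p)
  # p_{x+y} on k = 2..2L, p_{x-y} on k = 0..L-1
  pxy_sum <- vapply(2:(2 * levels), function(k) sum(p[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(levels - 1), function(k) sum(p[abs(i - j) == k]),
                    numeric(1))
  f6 <- sum((2:(2 * levels)) * pxy_sum)
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  hxy <- -sum(p * lg(p))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * lg(pxpy))
  hxy2 <- -sum(pxpy * lg(pxpy))
  dif_mean <- sum((0:(levels - 1)) * pxy_dif)
  c(
    asm = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = if (sx > 0 && sy > 0)
      (sum(i * j * p) - mx * my) / (sx * sy) else 0,
    variance = sum((i - mu)^2 * p),
    idm = sum(p / (1 + (i - j)^2)),
    sum_average = f6,
    sum_variance = sum(((2:(2 * levels)) - f6)^2 * pxy_sum),
    sum_entropy = -sum(pxy_sum * lg(pxy_sum)),
    entropy = hxy,
    difference_variance = sum(((0:(levels - 1)) - dif_mean)^2 * pxy_dif),
    difference_entropy = -sum(pxy_dif * lg(pxy_dif)),
    info_correlation_1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    info_correlation_2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  )
}

#' Haralick texture features at multiple offset scales
#'
#' Region pixels are quantized to `levels` gray levels by min-max binning
#' (making the features invariant to affine intensity rescaling); for each
#' offset scale a symmetric co-occurrence matrix is accumulated over the
#' four principal directions (averaged unless `directions` restricts them),
#' and the 13 Haralick statistics are computed on the averaged matrix.
#'
#' @param image 2-D numeric matrix.
#' @param mask optional logical mask; `NULL` means full frame.
#' @param scales integer pixel offsets (default `c(1, 2, 4)`).
#' @param levels gray levels (default 8).
#' @param directions subset of 1:4 selecting offsets
#'   (right, down, down-right, down-left); default all four.
#' @param prefix name prefix.
#' @return named numeric vector of length `13 * length(scales)`.
#' @export
haralick_texture <- function(image, mask = NULL, scales = c(1L, 2L, 4L),
                             levels = 8L, directions = 1:4,
                             prefix = "tex") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- mask > 0
  if (sum(mask) < 2) stop("region must contain at least 2 pixels")
  q <- quantize_region(image, mask, levels)
  out <- numeric(0)
  for (s in scales) {
    offs <- glcm_offsets(as.integer(s))[directions]
    mats <- lapply(offs, function(o) glcm_one(q, o, levels))
    keep <- vapply(mats, function(m) sum(m) > 0, logical(1))
    p <- if (any(keep)) Reduce(`+`, mats[keep]) / sum(keep)
         else matrix(0, levels, levels)
    st <- if (sum(p) == 0) {
      v <- haralick_stats(diag(c(1, rep(0, levels - 1))))   # degenerate
      v
    } else haralick_stats(p)
    names(st) <- paste0(prefix, "_", names(st), "_s", s)
    out <- c(out, st)
  }
  out
}

#' Morphological granularity spectrum
#'
#' Background-subtracted regional image volume removed by grayscale
#' openings with disc structuring elements of increasing radius
#' `1..length`: element `i` is the percentage of the initial volume removed
#' between opening `i-1` and opening `i`. Elements are non-negative and sum
#' to at most 100.
#'
#' @param image 2-D numeric matrix.
#' @param mask optional logical mask; `NULL` means full frame.
#' @param length spectrum length (default 16).
#' @param prefix name prefix.
#' @return named numeric vector of length `length`.
#' @export
granularity_spectrum <- function(image, mask = NULL, length = 16L,
                                 prefix = "gran") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- mask > 0
  if (!any(mask)) stop("empty region")
  base <- min(image[mask])
  v <- image - base
  v[!mask] <- 0
  vol0 <- sum(v[mask])
  out <- numeric(length)
  names(out) <- sprintf("%s_%02d", prefix, seq_len(length))
  if (vol0 <= .Machine$double.eps) return(out)
  prev <- v
  prev_vol <- vol0
  for (i in seq_len(length)) {
    op <- EBImage::imageData(EBImage::opening(
      v, EBImage::makeBrush(2L * i + 1L, "disc")))
    op <- pmin(op, prev)              # enforce anti-extensivity across radii
    vol <- sum(op[mask])
    out[i] <- 100 * (prev_vol - vol) / vol0
    prev <- op
    prev_vol <- vol
  }
  out
}
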