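#' Empirical background sampler from an image's border frame
#'
#' Imaging-flow-cytometry tiles have no reference empty field, so the
#' outermost 2-pixel border frame is taken as the label-free proxy for
#' background. The returned closure draws i.i.d. samples from the empirical
#' distribution of those border pixels.
#'
#' @param image 2-D numeric matrix.
#' @param frame_width border frame width in pixels (default 2).
#' @return `function(n)` returning `n` sampled background values.
#' @export
estimate_background <- function(image, frame_width = 2L) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  nr <- nrow(image); nc <- ncol(image)
  w <- min(frame_width, ceiling(nr / 2), ceiling(nc / 2))
  in_frame <- outer(seq_len(nr), seq_len(nc), function(r, c)
    r <= w | r > nr - w | c <= w | c > nc - w)
  vals <- image[in_frame]
  function(n) vals[sample.int(length(vals), n, replace = TRUE)]
}

#' Reshape a single-cell image to a fixed square side
#'
#' Smaller images are centred and padded with values sampled from their own
#' background border frame; larger images are centre-cropped by discarding
#' edge pixels. Content pixels are never rescaled or interpolated. For odd
#' gaps the extra padded/cropped row/column goes to the bottom/right.
#'
#' If cropping discards pixels that look like object (above the background
#' mean + 3 background s.d.) beyond `crop_tol` (fraction of the discarded
#' pixels), a warning is raised and the result carries attribute
#' `qc_cropped_object = TRUE`.
#'
#' @param image 2-D numeric matrix.
#' @param target output side in pixels (default 55).
#' @param seed optional RNG seed for padding reproducibility.
#' @param crop_tol tolerated fraction of object-like pixels among discarded
#'   edge pixels.
#' @return `target` x `target` matrix.
#' @export
reshape_image <- function(image, target = 55L, seed = NULL, crop_tol = 0.02) {
  stopifnot(is.matrix(image), target >= 8L)
  target <- as.integer(target)
  nr <- nrow(image); nc <- ncol(image)
  if (nr == target && nc == target) return(image)
  if (!is.null(seed)) set.seed(seed)
  bg <- estimate_background(image)

  crop_axis <- function(n) {        # start index for centre crop of length target
    drop <- n - target
    1L + drop %/% 2L                 # extra discarded pixel at the far end
  }
  pad_axis <- function(n) {          # start offset for centre placement
    gap <- target - n
    gap %/% 2L                       # extra padded row/col at the far end
  }

  out <- image
  cropped <- c()
  if (nr > target) {
    s <- crop_axis(nr)
    cropped <- c(cropped, out[-(s:(s + target - 1L)), , drop = TRUE])
    out <- out[s:(s + target - 1L), , drop = FALSE]
  }
  if (nc > target) {
    s <- crop_axis(nc)
    cropped <- c(cropped, out[, -(s:(s + target - 1L)), drop = TRUE])
    out <- out[, s:(s + target - 1L), drop = FALSE]
  }
  qc <- FALSE
  if (length(cropped)) {
    bvals <- bg(2000L)
    cut <- mean(bvals) + 3 * stats::sd(bvals)
    frac <- mean(cropped > cut)
    if (is.finite(frac) && frac > crop_tol) {
      warning(sprintf("cropping discarded %.1f%% object-like pixels", 100 * frac))
      qc <- TRUE
    }
  }
  if (nrow(out) < target || ncol(out) < target) {
    canvas <- matrix(bg(target * target), target, target)
    r0 <- pad_axis(nrow(out)); c0 <- pad_axis(ncol(out))
    canvas[r0 + seq_len(nrow(out)), c0 + seq_len(ncol(out))] <- out
    out <- canvas
  }
  if (qc) attr(out, "qc_cropped_object") <- TRUE
  out
}

new_montage <- function(image, grid, tile, index_map, channel) {
  if (length(index_map) > grid^2) stop("index_map longer than grid^2")
  if (anyDuplicated(index_map)) stop("index_map has duplicate cell ids")
  structure(list(image = image, grid = as.integer(grid),
                 tile = as.integer(tile), index_map = index_map,
                 channel = channel),
            class = "montage")
}

reshape_seed <- function(seed, i) cell_seed(seed %||% 0L, i)

#' Reshape every record's channels to the standard tile side
#'
#' Padding RNG is seeded from `(seed, cell index)` so the operation is
#' reproducible cell-by-cell under subsetting.
#'
#' @param records list of `cell_record`.
#' @param target tile side (default 55).
#' @param seed base seed for padding.
#' @param channels channels to reshape.
#' @return list of records with reshaped channels.
#' @export
reshape_records <- function(records, target = 55L, seed = 0L,
                            channels = c("brightfield", "darkfield", "stain")) {
  lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    for (ch in channels) {
      if (!is.null(rec[[ch]]))
        # the crop-QC guard protects the segmented object; darkfield and
        # stain are unsegmented whole-frame channels
        rec[[ch]] <- reshape_image(rec[[ch]], target,
                                   seed = reshape_seed(seed, i),
                                   crop_tol = if (ch == "brightfield") 0.02
                                              else Inf)
    }
    rec
  })
}

#' Tile single-cell images into square montages
#'
#' Cells are reshaped to `tile` pixels per side and placed row-major in
#' input order; each montage holds up to `grid^2` cells (15 x 15 = 225 by
#' default). Unfilled slots are filled with the per-montage median
#' background value. Brightfield and darkfield montages share identical
#' index maps by construction.
#'
#' @param records list of `cell_record` (all must carry every requested
#'   channel).
#' @param grid tiles per montage side (default 15).
#' @param tile pixels per tile side (default 55).
#' @param channels channels to tile.
#' @param seed base seed for reshape padding.
#' @return named list (per channel) of lists of `montage` objects.
#' @export
build_montages <- function(records, grid = 15L, tile = 55L,
                           channels = c("brightfield", "darkfield"),
                           seed = 0L) {
  if (!length(records)) stop("empty record list")
  for (ch in channels)
    if (any(vapply(records, function(r) is.null(r[[ch]]), logical(1))))
      stop("some records lack channel ", ch)
  reshaped <- reshape_records(records, tile, seed, channels)
  ids <- vapply(records, function(r) r$cell_id, character(1))
  n <- length(records)
  n_montages <- ceiling(n / grid^2)
  out <- lapply(channels, function(ch) {
    lapply(seq_len(n_montages), function(m) {
      sel <- ((m - 1L) * grid^2 + 1L):min(m * grid^2, n)
      tiles <- lapply(reshaped[sel], function(r) r[[ch]])
      # per-montage median background from the tiles' border frames
      borders <- unlist(lapply(tiles, function(tl)
        c(tl[c(1:2, tile - 1L, tile), ], tl[, c(1:2, tile - 1L, tile)])))
      img <- matrix(median(borders), grid * tile, grid * tile)
      for (k in seq_along(sel)) {
        row <- (k - 1L) %/% grid; col <- (k - 1L) %% grid
        img[row * tile + seq_len(tile), col * tile + seq_len(tile)] <- tiles[[k]]
      }
      new_montage(img, grid, tile, ids[sel], ch)
    })
  })
  names(out) <- channels
  out
}

#' Split a montage back into per-cell tiles
#'
#' @param montage a `montage` object.
#' @return named list of `tile x tile` matrices, one per `index_map` entry,
#'   in index order.
#' @export
split_montage <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  grid <- montage$grid; tile <- montage$tile
  if (length(montage$index_map) > grid^2) stop("index_map longer than grid^2")
  if (anyDuplicated(montage$index_map)) stop("index_map has duplicate cell ids")
  if (nrow(montage$image) != grid * tile || ncol(montage$image) != grid * tile)
    stop("montage image side must equal grid * tile")
  out <- lapply(seq_along(montage$index_map), function(k) {
    row <- (k - 1L) %/% grid; col <- (k - 1L) %% grid
    montage$image[row * tile + seq_len(tile), col * tile + seq_len(tile)]
  })
  names(out) <- montage$index_map
  out
}

#' Write a montage as TIFF plus a JSON index-map sidecar
#'
#' @param montage a `montage`.
#' @param path output TIFF path; the sidecar is `<path>.idx.json`.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  tiff::writeTIFF(t(pmin(pmax(montage$image, 0), 1)), path,
                  bits.per.sample = 16L)
  jsonlite::write_json(
    list(grid = montage$grid, tile = montage$tile,
         channel = montage$channel, index_map = montage$index_map),
    paste0(path, ".idx.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a montage written by [write_montage()]
#'
#' @param path TIFF path with `<path>.idx.json` sidecar.
#' @return a `montage` object.
#' @export
read_montage <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".idx.json"), simplifyVector = TRUE)
  img <- t(tiff::readTIFF(path))
  new_montage(img, meta$grid, meta$tile, meta$index_map, meta$channel)
}
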