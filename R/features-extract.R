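# The canonical, versioned 213-feature profile: 130 brightfield features
# computed on the segmented object and 83 darkfield features computed on
# the full frame (side scatter is never segmented).

shape_scalar_names <- c(
  "area", "perimeter", "form_factor", "eccentricity", "solidity", "extent",
  "euler_number", "orientation", "major_axis_length", "minor_axis_length",
  "compactness", "equivalent_diameter", "max_radius", "mean_radius",
  "median_radius", "min_feret", "max_feret")

intensity_names <- c(
  "integrated", "mean", "sd", "mad", "min", "max", "median", "q1", "q3",
  "range", "edge_integrated", "edge_mean", "edge_sd", "edge_min", "edge_max",
  "mass_displacement")

haralick_names <- c(
  "asm", "contrast", "correlation", "variance", "idm", "sum_average",
  "sum_variance", "sum_entropy", "entropy", "difference_variance",
  "difference_entropy", "info_correlation_1", "info_correlation_2")

#' The canonical v1 feature manifest
#'
#' Ordered list of the 213 features extracted per cell, with channel
#' (brightfield features from the segmented object, darkfield features from
#' the full frame), category (the five classes: size and shape,
#' granularity, intensity, radial distribution, texture) and parameter tag.
#' Brightfield contributes 130 features (17 shape scalars + 30 Zernike
#' magnitudes of degree <= 9 + 16 intensity + 12 radial + 39 texture +
#' 16 granularity) and darkfield 83 (16 intensity + 12 radial + 39 texture
#' + 16 granularity). The layout is versioned; any change to identities or
#' order bumps the version tag.
#'
#' @return data.frame with columns `name`, `channel`, `category`, `params`
#'   and attribute `version`.
#' @export
feature_manifest <- function() {
  zi <- zernike_index(9L)
  bf <- rbind(
    data.frame(name = paste0("bf_shape_", shape_scalar_names),
               channel = "brightfield", category = "size_shape",
               params = "mask"),
    data.frame(name = sprintf("bf_zernike_%d_%d", zi$n, zi$m),
               channel = "brightfield", category = "size_shape",
               params = sprintf("n=%d,m=%d", zi$n, zi$m)),
    data.frame(name = paste0("bf_int_", intensity_names),
               channel = "brightfield", category = "intensity",
               params = "mask"),
    data.frame(name = as.vector(t(outer(
                 paste0("bf_rad_", c("frac_at_d", "mean_frac", "radial_cv")),
                 1:4, paste, sep = "_"))),
               channel = "brightfield", category = "radial_distribution",
               params = "rings=4,wedges=8"),
    data.frame(name = as.vector(vapply(c(1, 2, 4), function(s)
                 paste0("bf_tex_", haralick_names, "_s", s), character(13))),
               channel = "brightfield", category = "texture",
               params = "levels=8"),
    data.frame(name = sprintf("bf_gran_%02d", 1:16),
               channel = "brightfield", category = "granularity",
               params = sprintf("radius=%d", 1:16))
  )
  df <- rbind(
    data.frame(name = paste0("df_int_", intensity_names),
               channel = "darkfield", category = "intensity",
               params = "full_frame"),
    data.frame(name = as.vector(t(outer(
                 paste0("df_rad_", c("frac_at_d", "mean_frac", "radial_cv")),
                 1:4, paste, sep = "_"))),
               channel = "darkfield", category = "radial_distribution",
               params = "rings=4,wedges=8,center=frame"),
    data.frame(name = as.vector(vapply(c(1, 2, 4), function(s)
                 paste0("df_tex_", haralick_names, "_s", s), character(13))),
               channel = "darkfield", category = "texture",
               params = "levels=8"),
    data.frame(name = sprintf("df_gran_%02d", 1:16),
               channel = "darkfield", category = "granularity",
               params = sprintf("radius=%d", 1:16))
  )
  out <- rbind(bf, df)
  rownames(out) <- NULL
  attr(out, "version") <- "v1"
  out
}

fix_radial_names <- function(v, prefix) {
  # radial_distribution emits frac/mean/cv grouped per ring; manifest order
  # is stat-major (all frac_at_d, then mean_frac, then radial_cv). Reorder.
  stats_order <- c("frac_at_d", "mean_frac", "radial_cv")
  nm <- as.vector(t(outer(paste0(prefix, "_", stats_order), 1:4,
                          paste, sep = "_")))
  v[nm]
}

#' Extract the 213-feature profile for one cell
#'
#' Concatenates, in manifest order, the brightfield-object blocks (shape +
#' Zernike, intensity, radial distribution, Haralick texture, granularity)
#' and the darkfield full-frame blocks (intensity, radial distribution
#' centred on the frame centre, texture, granularity).
#'
#' @param record a `cell_record` with brightfield and darkfield channels.
#' @param seg a `segmentation_result` with `object_found = TRUE`.
#' @param manifest the [feature_manifest()] (checked for version v1).
#' @return named numeric vector of length 213. Non-finite entries trigger
#'   attribute `qc_missing_values = TRUE` (such cells are discarded
#'   downstream).
#' @export
extract_features <- function(record, seg, manifest = feature_manifest()) {
  if (is.null(record$brightfield) || is.null(record$darkfield))
    stop("record must carry brightfield and darkfield channels")
  if (!isTRUE(seg$object_found)) stop("segmentation found no object")
  if (!identical(attr(manifest, "version"), "v1"))
    stop("unsupported manifest version")
  bf <- record$brightfield; df <- record$darkfield
  mask <- seg$mask
  sh <- shape_features(mask)
  names(sh) <- c(paste0("bf_shape_", shape_scalar_names),
                 paste0("bf_", names(sh)[-(1:17)]))
  v <- c(
    sh,
    intensity_features(bf, mask, prefix = "bf_int"),
    fix_radial_names(radial_distribution(bf, mask, prefix = "bf_rad"),
                     "bf_rad"),
    haralick_texture(bf, mask, prefix = "bf_tex"),
    granularity_spectrum(bf, mask, prefix = "bf_gran"),
    intensity_features(df, prefix = "df_int"),
    fix_radial_names(radial_distribution(df, prefix = "df_rad"), "df_rad"),
    haralick_texture(df, prefix = "df_tex"),
    granularity_spectrum(df, prefix = "df_gran")
  )
  v <- v[manifest$name]
  if (anyNA(v) || any(!is.finite(v))) attr(v, "qc_missing_values") <- TRUE
  v
}

#' Ground-truth integrated stain intensity of a cell
#'
#' Sum of background-subtracted stain pixels within the segmentation mask
#' dilated by 2 px (to capture the whole nucleus); background is the median
#' of the stain image's 2-px border frame.
#'
#' @param record a `cell_record` with a stain channel.
#' @param seg a `segmentation_result`.
#' @return scalar intensity in the stain's arbitrary units.
#' @export
integrated_stain_intensity <- function(record, seg) {
  if (is.null(record$stain)) stop("record has no stain channel")
  stain <- record$stain
  mask <- EBImage::imageData(EBImage::dilate(
    seg$mask * 1, EBImage::makeBrush(5L, "disc"))) > 0
  bg_sampler <- estimate_background(stain)
  bg <- median(bg_sampler(2000L))
  sum(pmax(stain[mask] - bg, 0))
}

#' Build the per-population feature table
#'
#' Segments every record, applies the QC policy, and extracts the
#' 213-feature profile for kept cells; cells whose profile contains
#' non-finite values are discarded (missing values). When stain channels
#' are present the integrated stain intensity is added as the ground-truth
#' column `stain_integrated`.
#'
#' @param population a `cell_population` (or plain list of records).
#' @param tile standard tile side for reshaping (default 55).
#' @param seg_params [segmentation_params()].
#' @param manifest the [feature_manifest()].
#' @param reshape reshape records to `tile` first? (default TRUE)
#' @param seed base seed for reshape padding.
#' @return list with `features` (data.frame: `cell_id`, `phase` and
#'   `dna_content` when known, `stain_integrated` when measurable, then the
#'   213 manifest columns), `qc` (per-cell keep/discard table) and
#'   `manifest_version`.
#' @export
feature_table <- function(population, tile = 55L,
                          seg_params = segmentation_params(),
                          manifest = feature_manifest(),
                          reshape = TRUE, seed = 0L) {
  records <- if (inherits(population, "cell_population"))
    population$records else population
  truth <- if (inherits(population, "cell_population"))
    population$truth else NULL
  if (reshape) records <- reshape_records(records, tile, seed)
  segs <- lapply(records, function(r) segment_brightfield(r$brightfield,
                                                          seg_params))
  qc <- qc_filter(segs)
  rows <- vector("list", length(records))
  stain_vals <- rep(NA_real_, length(records))
  for (i in seq_along(records)) {
    if (!qc$kept[i]) next
    v <- extract_features(records[[i]], segs[[i]], manifest)
    if (isTRUE(attr(v, "qc_missing_values"))) {
      qc$kept[i] <- FALSE
      qc$reasons[i] <- "missing_values"
      next
    }
    rows[[i]] <- v
    if (!is.null(records[[i]]$stain))
      stain_vals[i] <- integrated_stain_intensity(records[[i]], segs[[i]])
  }
  keep <- which(qc$kept)
  feat <- do.call(rbind, rows[keep])
  out <- data.frame(cell_id = vapply(records[keep], function(r) r$cell_id,
                                     character(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    m <- match(out$cell_id, truth$cell_id)
    out$phase <- truth$phase[m]
    out$dna_content <- truth$dna_content[m]
  }
  if (any(!is.na(stain_vals[keep]))) out$stain_integrated <- stain_vals[keep]
  out <- cbind(out, as.data.frame(feat))
  rownames(out) <- NULL
  qc$cell_id <- vapply(records, function(r) r$cell_id, character(1))
  list(features = out, qc = qc, manifest_version = attr(manifest, "version"))
}

#' Write / read a feature table as CSV (header = manifest names)
#'
#' @param tab the `features` data.frame from [feature_table()].
#' @param path CSV path.
#' @return `path` / the data.frame.
#' @export
write_feature_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Split a feature table into the numeric matrix + metadata
#'
#' @param tab `features` data.frame from [feature_table()].
#' @param manifest the manifest defining feature columns.
#' @return list with `X` (numeric matrix, cells x 213) and `meta`
#'   (the non-feature columns).
#' @export
feature_matrix <- function(tab, manifest = feature_manifest()) {
  missing_cols <- setdiff(manifest$name, colnames(tab))
  if (length(missing_cols))
    stop("feature table lacks manifest columns: ",
         paste(head(missing_cols, 3), collapse = ", "))
  X <- as.matrix(tab[, manifest$name])
  meta <- tab[, setdiff(colnames(tab), manifest$name), drop = FALSE]
  list(X = X, meta = meta)
}
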