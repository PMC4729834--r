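disk_mask <- function(r, side = 2 * r + 11) {
  ctr <- (side + 1) / 2
  d <- sqrt(outer((1:side - ctr)^2, (1:side - ctr)^2, "+"))
  d <= r
}

test_that("the v1 manifest is exactly the canonical 213-feature layout", {
  m <- feature_manifest()
  expect_equal(nrow(m), 213)
  expect_false(anyDuplicated(m$name) > 0)
  expect_identical(attr(m, "version"), "v1")
  expect_equal(sum(m$channel == "brightfield"), 130)
  expect_equal(sum(m$channel == "darkfield"), 83)
  expect_setequal(unique(m$category),
                  c("size_shape", "granularity", "intensity",
                    "radial_distribution", "texture"))
  counts <- table(m$channel, m$category)
  expect_equal(unname(counts["brightfield", "size_shape"]), 47)
  expect_equal(unname(counts["brightfield", "texture"]), 39)
  expect_equal(unname(counts["darkfield", "granularity"]), 16)
  # stable across calls
  expect_identical(m, feature_manifest())
})

test_that("shape scalars match analytic values on reference masks", {
  dm <- disk_mask(15)
  sf <- shape_features(dm)
  expect_length(sf, 47)
  expect_lt(sf["eccentricity"], 0.05)
  expect_gt(sf["solidity"], 0.95)
  expect_equal(unname(sf["form_factor"]), 1, tolerance = 0.05)
  expect_equal(unname(sf["euler_number"]), 1)
  # scaling law: doubling the radius quadruples the area
  sf2 <- shape_features(disk_mask(30))
  expect_equal(unname(sf2["area"] / sf["area"]), 4, tolerance = 0.02)
  # 2:1 ellipse eccentricity: sqrt(1 - 1/4)
  side <- 61; ctr <- 31
  ell <- outer((1:side - ctr)^2 / 400, (1:side - ctr)^2 / 100, "+") <= 1
  expect_equal(unname(shape_features(ell)["eccentricity"]), sqrt(3) / 2,
               tolerance = 0.02)
  expect_error(shape_features(matrix(FALSE, 5, 5)), "empty")
})

test_that("Zernike magnitudes vanish for asymmetric orders on a disk", {
  z <- zernike_magnitudes(disk_mask(15))
  expect_length(z, 30)
  m_pos <- !grepl("_0$", names(z))
  expect_lt(max(z[m_pos]), 0.05)
  expect_gt(z["zernike_0_0"], 0)
})

test_that("intensity features handle constant and point images", {
  const <- intensity_features(matrix(0.4, 12, 12))
  expect_length(const, 16)
  expect_equal(unname(const[c("int_sd", "int_mad", "int_mass_displacement")]),
               c(0, 0, 0))
  point <- matrix(0, 11, 11); point[6, 6] <- 1
  expect_equal(unname(intensity_features(point)["int_integrated"]), 1)
})

test_that("radial distribution is symmetric-aware and normalised", {
  side <- 41; ctr <- 21
  d <- sqrt(outer((1:side - ctr)^2, (1:side - ctr)^2, "+"))
  r <- radial_distribution(exp(-d / 8))
  expect_length(r, 12)
  expect_lt(max(r[grep("radial_cv", names(r))]), 0.05)
  expect_equal(sum(r[grep("frac_at_d", names(r))]), 1, tolerance = 1e-6)
  # uniform disk: every ring holds its area share
  dm <- disk_mask(16)
  ru <- radial_distribution((dm * 1), mask = dm)
  expect_equal(unname(ru[grep("mean_frac", names(ru))]), rep(1, 4),
               tolerance = 0.1)
})

test_that("Haralick statistics match the hand-computed stripe matrix", {
  img <- matrix(0, 8, 8); img[, seq(1, 8, 2)] <- 1
  # horizontal offset across 1-px vertical stripes: all pairs are (0,7)
  h <- haralick_texture(img, scales = 1, directions = 1)
  expect_equal(unname(h["tex_contrast_s1"]), 49)
  expect_equal(unname(h["tex_asm_s1"]), 0.5)      # two symmetric cells
  expect_equal(unname(h["tex_entropy_s1"]), 1)    # log2: two equal cells
  # along the stripes: identical neighbours only
  v <- haralick_texture(img, scales = 1, directions = 2)
  expect_equal(unname(v["tex_contrast_s1"]), 0)
  # constant region conventions
  hc <- haralick_texture(matrix(0.3, 8, 8), scales = c(1, 2, 4))
  expect_length(hc, 39)
  expect_equal(unname(hc["tex_asm_s1"]), 1)
  expect_equal(unname(hc["tex_contrast_s2"]), 0)
  expect_equal(unname(hc["tex_entropy_s4"]), 0)
  expect_equal(unname(hc["tex_correlation_s1"]), 0)
})

test_that("Haralick features are invariant to affine intensity rescaling", {
  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  h1 <- haralick_texture(img)
  h2 <- haralick_texture(3.7 * img + 0.4)
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("granularity spectrum telescopes and tracks grain size", {
  g0 <- granularity_spectrum(matrix(0.8, 40, 40))
  expect_length(g0, 16)
  expect_true(all(g0 == 0))
  set.seed(4)
  plant <- function(rad, k) {
    im <- matrix(0, 60, 60)
    for (i in seq_len(k)) {
      cx <- sample((rad + 2):(58 - rad), 1); cy <- sample((rad + 2):(58 - rad), 1)
      dd <- sqrt(outer((1:60 - cx)^2, (1:60 - cy)^2, "+"))
      im[dd <= rad] <- 1
    }
    im
  }
  g_small <- granularity_spectrum(plant(2, 25))
  g_large <- granularity_spectrum(plant(6, 6))
  expect_true(all(g_small >= 0) && all(g_large >= 0))
  expect_lte(sum(g_small), 100 + 1e-9)
  expect_lte(which.max(g_small), 3)
  expect_gt(which.max(g_large), which.max(g_small))
})

test_that("feature vectors have manifest order, length and determinism", {
  pop <- small_population()
  rec <- reshape_records(pop$records, 55, seed = 101)[[2]]
  seg <- segment_brightfield(rec$brightfield)
  v1 <- extract_features(rec, seg)
  v2 <- extract_features(rec, seg)
  expect_length(v1, 213)
  expect_identical(names(v1), feature_manifest()$name)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
})

test_that("brightfield and darkfield feature blocks are independent", {
  pop <- small_population()
  rec <- reshape_records(pop$records, 55, seed = 101)[[3]]
  seg <- segment_brightfield(rec$brightfield)
  v <- extract_features(rec, seg)
  rec2 <- rec
  rec2$darkfield <- matrix(0.25, 55, 55)
  v2 <- extract_features(rec2, seg)
  bf_cols <- startsWith(names(v), "bf_")
  expect_identical(v[bf_cols], v2[bf_cols])
  # constant darkfield hits the convention values
  expect_equal(unname(v2["df_tex_asm_s1"]), 1)
  expect_true(all(v2[startsWith(names(v2), "df_gran")] == 0))
  rec3 <- rec
  rec3$brightfield <- rec$brightfield * 0.9 + 0.03
  v3 <- extract_features(rec3, seg)
  expect_identical(v[!bf_cols], v3[!bf_cols])
})

test_that("missing channels raise errors; stain intensity is linear", {
  pop <- small_population()
  rec <- reshape_records(pop$records, 55, seed = 101)[[4]]
  seg <- segment_brightfield(rec$brightfield)
  norec <- rec; norec$darkfield <- NULL
  expect_error(extract_features(norec, seg), "darkfield")
  nostain <- rec; nostain$stain <- NULL
  expect_error(integrated_stain_intensity(nostain, seg), "stain")
  s1 <- integrated_stain_intensity(rec, seg)
  rec2 <- rec; rec2$stain <- rec$stain * 2
  expect_equal(integrated_stain_intensity(rec2, seg), 2 * s1,
               tolerance = 1e-9)
  zero <- rec; zero$stain <- matrix(0, 55, 55)
  expect_equal(integrated_stain_intensity(zero, seg), 0)
})

test_that("the ground-truth stain recovers the stoichiometric value", {
  cfg <- population_config(n_cells = 1, stain_cv = 1e-12)
  st <- structure(list(phase = "G1", t = 0, dna_content = 2,
                       nominal_radius = 9), class = "cell_state")
  set.seed(2)
  rec <- render_cell(st, cfg)
  rec <- reshape_records(list(rec), 55, seed = 2)[[1]]
  seg <- segment_brightfield(rec$brightfield)
  expect_equal(integrated_stain_intensity(rec, seg), 2 * cfg$dna_g1,
               tolerance = 0.01)
})

test_that("feature tables drop QC failures and keep provenance", {
  ft <- small_features()
  expect_equal(ncol(ft$features), 213 + 4)   # id, phase, content, stain
  expect_equal(nrow(ft$features) + sum(!ft$qc$kept), 60)
  expect_identical(ft$manifest_version, "v1")
  fm <- feature_matrix(ft$features)
  expect_equal(ncol(fm$X), 213)
  expect_true(all(is.finite(fm$X)))
  # round trip through CSV
  path <- file.path(withr::local_tempdir(), "feat.csv")
  write_feature_table(ft$features, path)
  back <- read_feature_table(path)
  expect_equal(dim(back), dim(ft$features))
  expect_equal(feature_matrix(back)$X, fm$X, tolerance = 1e-12)
})
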