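test_that("population configs validate their invariants", {
  expect_error(population_config(phase_priors = c(G1 = 0.5, S = 0.5)),
               "named over")
  bad <- c(G1 = 0.5, S = 0.2, G2 = 0.2, prophase = 0.05, metaphase = 0.02,
           anaphase = 0.02, telophase = 0.02)
  expect_error(population_config(phase_priors = bad), "sum to 1")
  expect_error(population_config(stain_cv = 0.7), "stain_cv")
  expect_error(population_config(image_side_range = c(10, 60)),
               "image_side_range")
  expect_error(population_config(image_side_range = c(60, 30)),
               "image_side_range")
  expect_silent(population_config())
})

test_that("degenerate priors give a pure-G1 population with content 2", {
  pri <- c(G1 = 1, S = 0, G2 = 0, prophase = 0, metaphase = 0,
           anaphase = 0, telophase = 0)
  cfg <- population_config(n_cells = 25, phase_priors = pri, seed = 4)
  pop <- generate_population(cfg)
  expect_true(all(pop$truth$phase == "G1"))
  expect_true(all(pop$truth$dna_content == 2))
})

test_that("cell states follow the DNA-content rules and radius coupling", {
  cfg <- population_config(seed = 8)
  set.seed(8)
  states <- replicate(400, sample_cell_state(cfg), simplify = FALSE)
  for (st in states) {
    expected <- switch(st$phase, G1 = 2, S = 2 + 2 * st$t, 4)
    expect_equal(st$dna_content, expected)
    expect_gt(st$nominal_radius, 0)
  }
  c_vals <- vapply(states, `[[`, numeric(1), "dna_content")
  s_cells <- c_vals > 2 & c_vals < 4
  if (any(s_cells)) expect_true(all(c_vals[s_cells] < 4 & c_vals[s_cells] > 2))
})

test_that("empirical phase frequencies match the priors within 3 s.e.", {
  cfg <- population_config(n_cells = 10000, seed = 12)
  set.seed(12)
  phases <- replicate(cfg$n_cells, sample_cell_state(cfg)$phase)
  p <- cfg$phase_priors
  freq <- table(factor(phases, names(p))) / cfg$n_cells
  se <- sqrt(p * (1 - p) / cfg$n_cells)
  expect_true(all(abs(freq - p) <= 3 * se + 1e-12))
})

test_that("a mitotic block moves the stated mass into the 4N pool", {
  cfg <- population_config(block_shift = 0.15)
  p <- blocked_priors(cfg)
  expect_equal(sum(p), 1)
  base <- cfg$phase_priors
  sinks <- c("G2", "prophase", "metaphase", "anaphase", "telophase")
  expect_equal(sum(p[sinks]), sum(base[sinks]) + 0.15)
  # empirical 4N fraction = baseline + shift within binomial error
  cfgb <- population_config(n_cells = 4000, seed = 9, block_shift = 0.15)
  popb <- generate_population(cfgb, with_stain = FALSE)
  f4 <- mean(popb$truth$dna_content == 4)
  target <- sum(base[sinks]) + 0.15
  expect_lt(abs(f4 - target), 3 * sqrt(target * (1 - target) / 4000))
})

test_that("identical (config, seed) populations are bit-identical", {
  cfg <- population_config(n_cells = 40, seed = 77)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$records, p2$records)
  # per-cell reproducibility under subsetting: regenerating gives the
  # same cells independent of their neighbours
  expect_identical(p1$records[[17]]$brightfield, p2$records[[17]]$brightfield)
})

test_that("image sides stay inside the configured range", {
  pop <- small_population()
  sides <- vapply(pop$records, function(r) nrow(r$brightfield), numeric(1))
  expect_true(all(sides >= 30 & sides <= 60))
  expect_true(all(vapply(pop$records, function(r)
    identical(dim(r$brightfield), dim(r$darkfield)), logical(1))))
})

test_that("stain is stoichiometric in DNA content", {
  # regression slope of integrated stain on content at low noise
  cfg <- population_config(n_cells = 5000, seed = 5, stain_cv = 0.05)
  pop <- generate_population(cfg)
  sl <- coef(lm(stain_integrated ~ 0 + dna_content, pop$truth))[[1]]
  expect_lt(abs(sl - cfg$dna_g1) / cfg$dna_g1, 0.02)
  # near-zero stain noise: G2 integrates to exactly twice G1
  g1 <- render_fixture("G1", radius = 9, seed = 3)
  g2 <- render_fixture("G2", radius = 9 * sqrt(2), seed = 3)
  expect_equal(sum(g2$stain) / sum(g1$stain), 2, tolerance = 0.2)
  cfg0 <- population_config(n_cells = 1, stain_cv = 1e-12)
  s1 <- structure(list(phase = "G1", t = 0, dna_content = 2,
                       nominal_radius = 9), class = "cell_state")
  s2 <- structure(list(phase = "G2", t = 0, dna_content = 4,
                       nominal_radius = 9), class = "cell_state")
  set.seed(1); r1 <- render_cell(s1, cfg0)
  set.seed(2); r2 <- render_cell(s2, cfg0)
  expect_equal(sum(r2$stain) / sum(r1$stain), 2, tolerance = 1e-6)
  # high-precision stain tracks content almost perfectly
  cfg2 <- population_config(n_cells = 2000, seed = 6, stain_cv = 0.01)
  pop2 <- generate_population(cfg2)
  expect_gte(cor(pop2$truth$stain_integrated, pop2$truth$dna_content), 0.99)
})

test_that("mean object area increases with DNA content when coupled", {
  pop <- cached("area_pop", generate_population(
    population_config(n_cells = 500, seed = 15)))
  interphase <- pop$truth$phase %in% c("G1", "G2")
  areas <- vapply(which(interphase), function(i) {
    rec <- pop$records[[i]]
    seg <- segment_brightfield(reshape_image(rec$brightfield, 55, seed = i))
    as.numeric(seg$area)
  }, numeric(1))
  cc <- pop$truth$dna_content[interphase]
  expect_gt(mean(areas[cc == 4]), mean(areas[cc == 2]))
})

test_that("telophase renders as two disjoint lobes", {
  rec <- render_fixture("telophase", radius = 10, seed = 2)
  bw <- rec$brightfield < 0.45   # rim band is far below background
  lab <- EBImage::bwlabel(bw * 1)
  # two rims -> at least two components among sizeable ones
  sizes <- table(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  expect_equal(sum(sizes > 10), 2)
})

test_that("an oversized cell is rejected by the renderer", {
  cfg <- population_config(n_cells = 1, image_side_range = c(30, 40))
  st <- structure(list(phase = "G1", t = 0, dna_content = 2,
                       nominal_radius = 30), class = "cell_state")
  expect_error(render_cell(st, cfg), "does not fit")
})

test_that("populations round-trip through TIFF + CSV on disk", {
  pop <- small_population()
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  back <- read_population(dir)
  expect_equal(back$truth$phase, pop$truth$phase)
  expect_equal(back$truth$stain_integrated, pop$truth$stain_integrated)
  # 16-bit quantisation: pixel values round-trip to ~1/65535
  expect_equal(back$records[[3]]$brightfield, pop$records[[3]]$brightfield,
               tolerance = 1e-4)
})
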