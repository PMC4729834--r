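#' Phase labels used throughout the package
#'
#' Interphase classes (G1, S, G2) followed by the four mitotic phases.
#' The order is canonical: tie-breaks and class lists follow it.
#'
#' @export
PHASES <- c("G1", "S", "G2", "prophase", "metaphase", "anaphase", "telophase")

MITOTIC_PHASES <- c("prophase", "metaphase", "anaphase", "telophase")

#' Configuration for a synthetic cell population
#'
#' Defines the statistical structure of a simulated imaging-flow-cytometry
#' experiment: how many cells, the phase composition, how integrated stain
#' intensity reports DNA content (stoichiometry with multiplicative noise),
#' how cell size couples to DNA content, and an optional mitotic block that
#' moves probability mass from G1/S into the G2 + mitotic pool (emulating a
#' Nocodazole-type treatment).
#'
#' @param n_cells number of cells to simulate.
#' @param phase_priors named probability vector over
#'   `c("G1","S","G2","prophase","metaphase","anaphase","telophase")`,
#'   summing to 1. The default mimics an asynchronously cycling population
#'   with rare mitotic figures (about 5% combined).
#' @param dna_g1 stain units per unit of DNA content (arbitrary scale).
#'   DNA content `c` runs 2 (G1) to 4 (G2/M) and integrated stain is
#'   `c * dna_g1` up to multiplicative noise, so a G1 cell integrates to
#'   `2 * dna_g1`.
#' @param stain_cv coefficient of variation of the multiplicative stain
#'   noise; must lie in (0, 0.5). Use values near 0 for stoichiometry tests.
#' @param size_coupling exponent linking projected cell radius to DNA
#'   content: nominal radius is proportional to `(c/2)^size_coupling`.
#' @param noise_sd additive Gaussian pixel noise (gray levels, images are
#'   rendered in \[0,1\]).
#' @param image_side_range integer pair `(min, max)`; each cell's frame side
#'   is drawn uniformly from this range (instrument tiles vary in size).
#' @param block_shift probability mass moved from G1/S into the G2+mitotic
#'   classes; 0 is the untreated condition.
#' @param base_radius nominal G1 cell radius in pixels.
#' @param radius_jitter lognormal sdlog of per-cell radius jitter.
#' @param seed RNG seed for the population stream.
#'
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_cells = 1000,
                              phase_priors = c(G1 = 0.55, S = 0.20, G2 = 0.20,
                                               prophase = 0.02, metaphase = 0.01,
                                               anaphase = 0.01, telophase = 0.01),
                              dna_g1 = 100,
                              stain_cv = 0.05,
                              size_coupling = 0.5,
                              noise_sd = 0.02,
                              image_side_range = c(30L, 60L),
                              block_shift = 0,
                              base_radius = 8,
                              radius_jitter = 0.08,
                              seed = 1L) {
  stopifnot(length(n_cells) == 1L, n_cells >= 1)
  if (!all(PHASES %in% names(phase_priors)))
    stop("phase_priors must be named over: ", paste(PHASES, collapse = ", "))
  phase_priors <- phase_priors[PHASES]
  if (abs(sum(phase_priors) - 1) > 1e-9)
    stop("phase_priors must sum to 1 (got ", sum(phase_priors), ")")
  if (any(phase_priors < 0)) stop("phase_priors must be non-negative")
  if (!(stain_cv > 0 && stain_cv < 0.5))
    stop("stain_cv must lie in (0, 0.5)")
  image_side_range <- as.integer(round(image_side_range))
  if (length(image_side_range) != 2L ||
      image_side_range[1] > image_side_range[2] ||
      image_side_range[1] < 20L || image_side_range[2] > 128L)
    stop("image_side_range must be (min, max) within [20, 128]")
  if (block_shift < 0 || block_shift > sum(phase_priors[c("G1", "S")]))
    stop("block_shift must be in [0, prior mass of G1+S]")
  structure(list(
    n_cells = as.integer(n_cells), phase_priors = phase_priors,
    dna_g1 = dna_g1, stain_cv = stain_cv, size_coupling = size_coupling,
    noise_sd = noise_sd, image_side_range = image_side_range,
    block_shift = block_shift, base_radius = base_radius,
    radius_jitter = radius_jitter, seed = as.integer(seed)
  ), class = "population_config")
}

#' Phase priors after applying a mitotic block
#'
#' Moves `block_shift` probability mass out of G1 and S (proportionally to
#' their prior mass) into G2 and the mitotic classes (proportionally to
#' theirs), emulating a microtubule-poison block that inflates the 4N pool.
#'
#' @param config a [population_config()].
#' @return named probability vector over the seven phases.
#' @export
blocked_priors <- function(config) {
  p <- config$phase_priors
  s <- config$block_shift
  if (s == 0) return(p)
  donors <- c("G1", "S")
  sinks <- c("G2", MITOTIC_PHASES)
  p[donors] <- p[donors] * (1 - s / sum(p[donors]))
  p[sinks] <- p[sinks] + s * p[sinks] / sum(p[sinks])
  p
}

# Deterministic per-cell seed: depends only on (population seed, cell index)
# so any subset of cells reproduces bit-identically.
cell_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483647)
}

#' Draw one cell's latent cycle state
#'
#' Phase is drawn from the (block-adjusted) priors; interphase position `t`
#' is uniform on \[0,1); DNA content is 2 in G1, linear 2 to 4 through S, and
#' 4 in G2 and every mitotic phase; nominal radius scales as
#' `(c/2)^size_coupling` with lognormal jitter.
#'
#' @param config a [population_config()].
#' @return An object of class `cell_state` with fields `phase`, `t`,
#'   `dna_content`, `nominal_radius`.
#' @export
sample_cell_state <- function(config) {
  p <- blocked_priors(config)
  phase <- sample(PHASES, 1L, prob = p)
  t <- runif(1)
  c_val <- switch(phase, G1 = 2, S = 2 + 2 * t, 4)
  radius <- config$base_radius * (c_val / 2)^config$size_coupling *
    rlnorm(1, 0, config$radius_jitter)
  structure(list(phase = phase, t = t, dna_content = c_val,
                 nominal_radius = radius),
            class = "cell_state")
}

# Ellipse/lobe layout per phase. Returns list of lobes (cx, cy offsets from
# frame centre in px, a/b semi-axes, angle) and overall max extent.
phase_geometry <- function(state) {
  r <- state$nominal_radius
  ph <- state$phase
  ang <- runif(1, 0, pi)
  if (ph %in% c("G1", "S", "G2", "prophase")) {
    # prophase cells are 4N and round like G2; only their condensed-
    # chromatin texture (variable strength) betrays them
    # natural ellipticity of cells deformed in flow; its upper tail
    # overlaps the metaphase range, so shape alone is not a clean split
    q <- min(1.9, 1 + abs(rnorm(1, 0, 0.25)))
    a <- r * sqrt(q); b <- r / sqrt(q)
    lobes <- list(list(cx = 0, cy = 0, a = a, b = b, angle = ang))
  } else if (ph == "metaphase") {
    q <- max(1.6, rnorm(1, 1.7, 0.12))          # elongated metaphase plate
    a <- r * sqrt(q); b <- r / sqrt(q)
    lobes <- list(list(cx = 0, cy = 0, a = a, b = b, angle = ang))
  } else {                                       # anaphase / telophase
    rl <- r / sqrt(2)                            # area-conserving lobes
    d <- if (ph == "anaphase") 1.2 * rl else runif(1, 2.4, 3.2) * rl
    dx <- cos(ang) * d / 2; dy <- sin(ang) * d / 2
    lobes <- list(list(cx = -dx, cy = -dy, a = rl, b = rl, angle = 0),
                  list(cx = dx, cy = dy, a = rl, b = rl, angle = 0))
  }
  ext <- max(vapply(lobes, function(l)
    sqrt(l$cx^2 + l$cy^2) + max(l$a, l$b), numeric(1)))
  list(lobes = lobes, extent = ext)
}

# Normalised elliptical radius field: u <= 1 inside the union of lobes.
# Low-order angular harmonics roughen every outline a little — real cell
# boundaries are never perfect conics.
lobe_field <- function(side, lobes, roughness = 0.03) {
  ctr <- (side + 1) / 2
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  u <- rep(Inf, side * side)
  for (l in lobes) {
    dx <- xy$x - (ctr + l$cx); dy <- xy$y - (ctr + l$cy)
    xr <- dx * cos(l$angle) + dy * sin(l$angle)
    yr <- -dx * sin(l$angle) + dy * cos(l$angle)
    ul <- sqrt((xr / l$a)^2 + (yr / l$b)^2)
    if (roughness > 0) {
      th <- atan2(yr, xr)
      sc <- 1
      for (k in 2:4) sc <- sc + rnorm(1, 0, roughness) * sin(k * th +
                                                              runif(1, 0, 2 * pi))
      ul <- ul / pmax(sc, 0.7)
    }
    u <- pmin(u, ul)
  }
  matrix(u, side, side)
}

#' Render one synthetic cell record
#'
#' Produces the paired brightfield/darkfield (and stain) images for a latent
#' state. Brightfield: mid-gray background (0.5), brighter interior, darker
#' rim band inside the cell boundary; phase-specific geometry (metaphase
#' elongation, anaphase overlapping lobes, telophase disjoint lobes,
#' prophase interior granular texture). Darkfield: speckle under a Gaussian
#' envelope whose centre is deliberately offset from the brightfield cell
#' (the two channels are not registered) and whose integrated intensity
#' scales with DNA content. Stain: uniform nuclear disk(s) whose integrated
#' intensity equals `dna_content/2 * dna_g1 * (1 + eps)`,
#' `eps ~ N(0, stain_cv)` — exactly stoichiometric at `stain_cv -> 0`.
#'
#' @param state a [sample_cell_state()] result.
#' @param config the [population_config()].
#' @param cell_id identifier stored in the record.
#' @param with_stain include the stain channel?
#' @return An object of class `cell_record` with fields `cell_id`,
#'   `brightfield`, `darkfield`, `stain` (or NULL), `truth`.
#' @export
render_cell <- function(state, config, cell_id = "cell", with_stain = TRUE) {
  geom <- phase_geometry(state)
  needed <- as.integer(2 * ceiling(geom$extent) + 5)
  lo <- max(config$image_side_range[1], needed)
  hi <- config$image_side_range[2]
  if (needed > hi)
    stop("cell extent ", round(geom$extent, 1),
         " px does not fit the maximum image side ", hi)
  side <- if (lo >= hi) hi else sample(lo:hi, 1L)

  u <- lobe_field(side, geom$lobes)
  bf <- matrix(0.5, side, side)
  bf[u <= 1] <- 0.35                 # dark rim band
  bf[u <= 0.8] <- 0.62               # bright interior
  if (state$phase == "prophase") {   # condensed-chromatin granular texture,
    inner <- u <= 0.8                # of variable strength: weakly textured
    amp <- runif(1, 0, 0.10)         # prophases shade into round G2 cells
    tex <- matrix(rnorm(side * side, 0, amp), side, side)
    bf[inner] <- bf[inner] + tex[inner]
  }
  bf <- bf + matrix(rnorm(side * side, 0, config$noise_sd), side, side)
  bf <- pmin(pmax(bf, 0), 1)

  # Darkfield: speckle, mis-registered centre, integrated intensity ~ c
  ctr <- (side + 1) / 2
  off <- rnorm(2, 0, 2)
  xs <- matrix(seq_len(side), side, side)
  ys <- matrix(seq_len(side), side, side, byrow = TRUE)
  sig <- 0.6 * state$nominal_radius
  env <- exp(-(((xs - ctr - off[1])^2 + (ys - ctr - off[2])^2) / (2 * sig^2)))
  speckle <- matrix(runif(side * side, 0.2, 1), side, side)
  raw <- env * speckle
  df_gain <- 15
  df <- raw * (state$dna_content * df_gain / sum(raw))
  df <- df + matrix(abs(rnorm(side * side, 0, config$noise_sd / 2)), side, side)
  df <- pmin(df, 1)

  stain <- NULL
  if (with_stain) {
    eps <- rnorm(1, 0, config$stain_cv)
    total <- state$dna_content * config$dna_g1 * (1 + eps)
    nuc <- u <= 0.55                 # nucleus occupies the cell interior
    if (!any(nuc)) nuc <- u <= 1
    stain <- matrix(0, side, side)
    stain[nuc] <- total / sum(nuc)
  }

  structure(list(cell_id = cell_id, brightfield = bf, darkfield = df,
                 stain = stain, truth = state),
            class = "cell_record")
}

#' Generate a seeded synthetic cell population
#'
#' Draws `n_cells` latent states and renders their image records. One RNG
#' stream per population, split per cell by a counter-derived seed, so equal
#' `(config, seed)` give bit-identical populations and any subset of cells
#' is individually reproducible.
#'
#' @param config a [population_config()].
#' @param with_stain include the stoichiometric stain channel?
#' @return An object of class `cell_population`: a list with `records`
#'   (list of `cell_record`) and `truth` (data.frame with columns
#'   `cell_id`, `phase`, `dna_content`, `stain_integrated`).
#' @export
generate_population <- function(config, with_stain = TRUE) {
  stopifnot(inherits(config, "population_config"))
  records <- vector("list", config$n_cells)
  truth <- data.frame(cell_id = character(config$n_cells),
                      phase = character(config$n_cells),
                      dna_content = numeric(config$n_cells),
                      stain_integrated = numeric(config$n_cells),
                      stringsAsFactors = FALSE)
  for (i in seq_len(config$n_cells)) {
    set.seed(cell_seed(config$seed, i))
    id <- sprintf("cell%05d", i)
    state <- sample_cell_state(config)
    rec <- render_cell(state, config, cell_id = id, with_stain = with_stain)
    records[[i]] <- rec
    truth$cell_id[i] <- id
    truth$phase[i] <- state$phase
    truth$dna_content[i] <- state$dna_content
    truth$stain_integrated[i] <-
      if (with_stain) sum(rec$stain) else NA_real_
  }
  structure(list(records = records, truth = truth, config = config),
            class = "cell_population")
}

#' Write a population to disk as per-cell TIFFs plus a ground-truth CSV
#'
#' Images are written 16-bit as `<dir>/<cell_id>_<channel>.tif` with
#' channels `bf`, `df` and (when present) `stain`; the truth table goes to
#' `<dir>/truth.csv`. Stain images are scaled by the population maximum to
#' fit the 16-bit range; the scale factor is recorded in
#' `<dir>/stain_scale.json`.
#'
#' @param population a [generate_population()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "cell_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  has_stain <- !is.null(population$records[[1]]$stain)
  scale <- 1
  if (has_stain)
    scale <- max(vapply(population$records,
                        function(r) max(r$stain), numeric(1)), 1e-12)
  for (rec in population$records) {
    base <- file.path(dir, rec$cell_id)
    tiff::writeTIFF(t(rec$brightfield), paste0(base, "_bf.tif"),
                    bits.per.sample = 16L)
    tiff::writeTIFF(t(rec$darkfield), paste0(base, "_df.tif"),
                    bits.per.sample = 16L)
    if (has_stain)
      tiff::writeTIFF(t(rec$stain) / scale, paste0(base, "_stain.tif"),
                      bits.per.sample = 16L)
  }
  write.csv(population$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (has_stain)
    jsonlite::write_json(list(stain_scale = scale),
                         file.path(dir, "stain_scale.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a population written by [write_population()]
#'
#' @param dir directory holding `<cell_id>_<channel>.tif` files and
#'   `truth.csv`.
#' @return A `cell_population` (without latent `truth` states on records).
#' @export
read_population <- function(dir) {
  truth <- read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  scale_file <- file.path(dir, "stain_scale.json")
  scale <- if (file.exists(scale_file))
    jsonlite::read_json(scale_file)$stain_scale else 1
  records <- lapply(truth$cell_id, function(id) {
    base <- file.path(dir, id)
    bf <- t(tiff::readTIFF(paste0(base, "_bf.tif")))
    df <- t(tiff::readTIFF(paste0(base, "_df.tif")))
    sf <- paste0(base, "_stain.tif")
    stain <- if (file.exists(sf)) t(tiff::readTIFF(sf)) * scale else NULL
    structure(list(cell_id = id, brightfield = bf, darkfield = df,
                   stain = stain, truth = NULL),
              class = "cell_record")
  })
  structure(list(records = records, truth = truth, config = NULL),
            class = "cell_population")
}
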