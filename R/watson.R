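# Watson pragmatic deconvolution of DNA-content histograms. Gaussians are
# fitted to the outer halves of the G1 and G2 peaks (which are
# uncontaminated by S phase); the counts between the peaks left unexplained
# by the two Gaussians are assigned to S. G2 and M share DNA content (4N)
# and are reported as one fraction.

#' Build a DNA-content histogram
#'
#' Equal-width bins over `[0, 1.02 * max]`; non-positive or non-finite
#' values are dropped (with the count recorded). At least 100 usable values
#' are required for a stable curve fit.
#'
#' @param intensities per-cell DNA-content values (measured integrated
#'   stain or model predictions).
#' @param n_bins number of bins (default 256).
#' @param source tag: `"measured"` or `"predicted"`.
#' @return object of class `dna_histogram`: `breaks`, `mids`, `counts`,
#'   `n_cells`, `n_dropped`, `source`.
#' @export
build_histogram <- function(intensities, n_bins = 256L,
                            source = c("measured", "predicted")) {
  source <- match.arg(source)
  x <- intensities[is.finite(intensities) & intensities > 0]
  n_dropped <- length(intensities) - length(x)
  if (length(x) < 100) stop("need at least 100 usable values for a fit")
  breaks <- seq(0, 1.02 * max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), n_bins)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                 counts = counts, n_cells = length(x), n_dropped = n_dropped,
                 source = source),
            class = "dna_histogram")
}

moving_average <- function(x, w = 3L) {
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Sub-bin peak refinement: parabola through the smoothed counts at the
# mode and its two neighbours.
refine_peak <- function(mids, sm, i) {
  if (i <= 1 || i >= length(mids)) return(mids[i])
  y1 <- sm[i - 1]; y2 <- sm[i]; y3 <- sm[i + 1]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(mids[i])
  mids[i] + 0.5 * (y1 - y3) / den * (mids[2] - mids[1])
}

# Half-peak Gaussian fit by Poisson deviance minimisation on raw counts.
# The window runs to `extend` bins past the peak anchor (side = +1 fits
# the G1 peak on its left half, side = -1 the G2 peak on its right half):
# the outer halves are uncontaminated by S phase, and the few bins past
# the top anchor the amplitude and mean. The S plateau of level `L`
# (counts per bin) spills under the peak as a noise-smeared step
# L * Phi(side * (x - mu) / s), which the model accounts for explicitly.
# All coordinates enter relative to mu0, so the fit is equivariant under
# intensity rescaling.
fit_half_gaussian <- function(mids, counts, mu0, binw, L = 0, side = 1,
                              extend = 6L) {
  use <- if (side > 0) mids <= mu0 + extend * binw
         else mids >= mu0 - extend * binw
  xs <- mids[use]; cc <- counts[use]
  if (sum(cc) <= 0) return(list(a = 0, mu = mu0, s = 0.05 * mu0, value = 0))
  dev <- function(par) {
    m <- par[1]; sg <- par[2]; a <- exp(par[3])
    lam <- a * exp(-(xs - m)^2 / (2 * sg^2)) +
      L * stats::pnorm(side * (xs - m) / sg) + 1e-9
    v <- 2 * sum(lam - cc - cc * log(lam / pmax(cc, 1e-12)) * (cc > 0))
    if (!is.finite(v)) 1e18 else v
  }
  a0 <- max(max(cc) - L / 2, 1)
  o <- optim(c(mu0, 0.05 * mu0, log(a0)), dev, method = "L-BFGS-B",
             lower = c(mu0 - extend * binw, 0.005 * mu0, log(a0) - 5),
             upper = c(mu0 + extend * binw, 0.5 * mu0, log(a0) + 5),
             control = list(factr = 1e3, maxit = 500))
  list(a = exp(o$par[3]), mu = o$par[1], s = o$par[2], value = o$value)
}

#' Fit the Watson pragmatic model to a DNA histogram
#'
#' Procedure: (1) the G1 peak is the global mode after 3-bin moving-average
#' smoothing; (2) the G2 peak is the highest local mode within
#' `g2_window * muG1` (default `[1.7, 2.3]`), falling back to a fixed
#' `muG2 = 2 * muG1` when no mode is found there (or always, with
#' `fix_g2_ratio = TRUE`); (3) the G1 Gaussian is least-squares fitted
#' using only bins at or below `muG1`, the G2 Gaussian using only bins at
#' or above `muG2` — the outer half-peaks are uncontaminated by S phase;
#' (4) per-bin S counts between the peaks are the observed counts minus
#' both fitted Gaussians, clipped at zero; (5) fractions are component
#' sums over their total, hence always summing to 1.
#'
#' @param hist a [build_histogram()] result.
#' @param g2_window search window for the G2 peak, as multiples of `muG1`.
#' @param fix_g2_ratio force `muG2 = 2 * muG1` instead of locating the G2
#'   mode freely.
#' @param smooth_window smoothing window (bins) for peak finding.
#' @return object of class `watson_fit`: Gaussian parameters (`muG1`,
#'   `sigmaG1`, `aG1`, `muG2`, `sigmaG2`, `aG2`), per-bin S counts,
#'   `fractions` (named `G1`, `S`, `G2M`), and diagnostics (`residual_norm`,
#'   `cv_g1`, `warnings`).
#' @export
fit_watson <- function(hist, g2_window = c(1.7, 2.3), fix_g2_ratio = FALSE,
                       smooth_window = 3L) {
  stopifnot(inherits(hist, "dna_histogram"))
  mids <- hist$mids; counts <- hist$counts
  sm <- moving_average(counts, smooth_window)
  if (max(sm) <= 0 || sum(counts > 0) < 3)
    stop("no detectable G1 peak in the histogram")
  i_g1 <- which.max(sm)
  muG1 <- refine_peak(mids, sm, i_g1)
  # a genuine G1 peak towers over the bulk of the histogram
  if (max(sm) < 2 * median(sm[sm > 0]))
    stop("histogram is flat: no detectable G1 peak")
  # G2 peak: highest local mode within the search window
  win <- which(mids >= g2_window[1] * muG1 & mids <= g2_window[2] * muG1)
  muG2 <- 2 * muG1
  if (!fix_g2_ratio && length(win) > 2) {
    interior <- win[win > 1 & win < length(mids)]
    is_mode <- sm[interior] >= sm[interior - 1] & sm[interior] >= sm[interior + 1]
    cand <- interior[is_mode & sm[interior] > 0]
    if (length(cand)) {
      i_g2 <- cand[which.max(sm[cand])]
      muG2 <- refine_peak(mids, sm, i_g2)
    }
  }
  bin_w <- diff(hist$breaks[1:2])
  gauss_curve <- function(g) g$a * exp(-(mids - g$mu)^2 / (2 * g$s^2))
  # pass 1: plain half fits to locate the peaks precisely
  g1 <- fit_half_gaussian(mids, counts, muG1, bin_w)
  g2 <- fit_half_gaussian(mids, counts, muG2, bin_w, side = -1)
  # S plateau level (counts per bin) from the middle third between peaks
  mid3 <- mids > g1$mu + (g2$mu - g1$mu) / 3 &
          mids < g2$mu - (g2$mu - g1$mu) / 3
  plateau <- median(counts[mid3] - gauss_curve(g1)[mid3] -
                      gauss_curve(g2)[mid3], na.rm = TRUE)
  if (!is.finite(plateau) || plateau < 0) plateau <- 0
  # pass 2: refit with the S spillover accounted for under each half-peak
  g1 <- fit_half_gaussian(mids, counts, g1$mu, bin_w, plateau, side = 1)
  g2 <- fit_half_gaussian(mids, counts, g2$mu, bin_w, plateau, side = -1)
  g1_curve <- gauss_curve(g1)
  g2_curve <- gauss_curve(g2)
  s_counts <- numeric(length(mids))
  between <- mids > g1$mu & mids < g2$mu
  s_counts[between] <- pmax(0, counts[between] - g1_curve[between] -
                              g2_curve[between])
  g1_total <- g1$a * g1$s * sqrt(2 * pi) / bin_w
  g2_total <- g2$a * g2$s * sqrt(2 * pi) / bin_w
  # S spillover mass smeared beyond the two peaks
  s_total <- sum(s_counts) + plateau * (g1$s + g2$s) / sqrt(2 * pi) / bin_w
  total <- g1_total + g2_total + s_total
  fractions <- c(G1 = g1_total, S = s_total, G2M = g2_total) / total
  model <- g1_curve + g2_curve + s_counts
  warnings <- character(0)
  cv_g1 <- g1$s / g1$mu
  if (cv_g1 < 0.005 || cv_g1 > 0.4)
    warnings <- c(warnings, sprintf("G1 CV %.3f outside (0.005, 0.4)", cv_g1))
  cv_g2 <- g2$s / g2$mu
  if (cv_g2 < 0.005 || cv_g2 > 0.4)
    warnings <- c(warnings, sprintf("G2 CV %.3f outside (0.005, 0.4)", cv_g2))
  if (g2$mu <= g1$mu)
    warnings <- c(warnings, "muG2 <= muG1: degenerate peak layout")
  structure(list(muG1 = g1$mu, sigmaG1 = g1$s, aG1 = g1$a,
                 muG2 = g2$mu, sigmaG2 = g2$s, aG2 = g2$a,
                 s_counts = s_counts, fractions = fractions,
                 residual_norm = sqrt(sum((counts - model)^2)),
                 cv_g1 = cv_g1, warnings = warnings,
                 hist = hist),
            class = "watson_fit")
}

#' @export
print.watson_fit <- function(x, ...) {
  cat(sprintf("Watson pragmatic fit (n = %d cells, %s intensities)\n",
              x$hist$n_cells, x$hist$source))
  cat(sprintf("  G1: mu = %.3g, cv = %.3f | G2: mu = %.3g (ratio %.2f)\n",
              x$muG1, x$cv_g1, x$muG2, x$muG2 / x$muG1))
  f <- x$fractions
  cat(sprintf("  fractions: G1 %.1f%%, S %.1f%%, G2/M %.1f%%\n",
              100 * f["G1"], 100 * f["S"], 100 * f["G2M"]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

watson_fractions <- function(intensities, n_bins = 256L, source = "measured",
                             ...) {
  fit_watson(build_histogram(intensities, n_bins, source), ...)$fractions
}

#' Compare cell-cycle fractions between two populations
#'
#' Differences `treated - control` in the G1, S and G2/M fractions. When
#' raw per-cell intensities are supplied, bootstrap confidence intervals
#' (resampling cells, B draws) are attached.
#'
#' @param control,treated either `watson_fit` objects or raw per-cell
#'   intensity vectors.
#' @param B bootstrap draws (only used with raw intensities; default 200).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param ... passed to [fit_watson()].
#' @return list with `delta` (named `G1`, `S`, `G2M`), the two fraction
#'   vectors, and (with raw input) `ci`, a 2 x 3 matrix of bootstrap
#'   percentile intervals for the deltas.
#' @export
compare_populations <- function(control, treated, B = 200L, seed = 1L,
                                conf = 0.95, ...) {
  raw <- is.numeric(control) && is.numeric(treated)
  if (raw) {
    fc <- watson_fractions(control, ...)
    ft <- watson_fractions(treated, ...)
  } else {
    stopifnot(inherits(control, "watson_fit"), inherits(treated, "watson_fit"))
    fc <- control$fractions; ft <- treated$fractions
  }
  out <- list(control = fc, treated = ft, delta = ft - fc)
  if (raw) {
    set.seed(seed)
    boots <- vapply(seq_len(B), function(b) {
      bc <- sample(control, replace = TRUE)
      bt <- sample(treated, replace = TRUE)
      tryCatch(watson_fractions(bt, ...) - watson_fractions(bc, ...),
               error = function(e) c(G1 = NA_real_, S = NA_real_,
                                     G2M = NA_real_))
    }, numeric(3))
    a <- (1 - conf) / 2
    out$ci <- apply(boots, 1, quantile, probs = c(a, 1 - a), na.rm = TRUE)
    out$B <- B
  }
  out
}
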