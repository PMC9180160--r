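#' Configuration of the synthetic tea-spectra generator
#'
#' Describes a family of tea-like NIR absorbance spectra: a gentle baseline,
#' a saturation shoulder (near-total absorbance, hence transmittance close
#' to zero, below `saturation_region` cm^-1), a handful of Gaussian
#' absorption bands in the informative high-wavenumber region whose depths
#' grow with the quality level, and per-sample variability (a global
#' band-strength factor, per-band depth jitter, and additive white noise).
#'
#' Class structure is graded: the depth of band `b` for level `l` is
#' `band_depths[b] * class_effect[l, b]`, and the default `class_effect`
#' rises smoothly with `l`, so adjacent levels differ least and
#' adjacent-level confusion is the typical classification error.
#'
#' @param n_classes Number of quality levels (default 6).
#' @param samples_per_class Samples per level (default 20).
#' @param n_points Grid points (default 1557).
#' @param wn_range Wavenumber range in cm^-1, given high-to-low (default
#'   `c(10000, 4000)`, stored descending).
#' @param band_centers,band_widths,band_depths Gaussian absorption band
#'   parameters (centers/widths in cm^-1, depths in absorbance units).
#' @param class_effect `n_classes x n_bands` matrix of multiplicative
#'   band-depth factors; default `1 + slope_b * (l - 1)` with per-band
#'   slopes `class_slopes`.
#' @param class_slopes Per-band depth increment per quality level used to
#'   build the default `class_effect`.
#' @param baseline Baseline absorbance at 10,000 cm^-1 (default 0.05).
#' @param baseline_tilt Extra baseline absorbance accumulated towards
#'   4,000 cm^-1 (default 0.02).
#' @param saturation_region Wavenumber threshold below which absorbance is
#'   driven high (default 7500 cm^-1).
#' @param saturation_absorbance Plateau absorbance of the saturated region
#'   (default 2.5, i.e. transmittance ~ 0.003).
#' @param strength_sd Log-scale s.d. of the per-sample global band-strength
#'   factor (default 0.01).
#' @param band_jitter_sd Log-scale s.d. of independent per-sample, per-band
#'   depth jitter (default 0.02).
#' @param noise_sd Additive white measurement noise, absorbance units
#'   (default 0.004).
#' @param seed Optional integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 6L, samples_per_class = 20L,
                         n_points = 1557L, wn_range = c(10000, 4000),
                         band_centers = c(8250, 8800, 9500),
                         band_widths = c(150, 250, 350),
                         band_depths = c(0.30, 0.45, 0.25),
                         class_effect = NULL,
                         class_slopes = c(0.12, 0.08, 0.05),
                         baseline = 0.05, baseline_tilt = 0.02,
                         saturation_region = 7500,
                         saturation_absorbance = 2.5,
                         strength_sd = 0.01, band_jitter_sd = 0.02,
                         noise_sd = 0.004, seed = NULL) {
  n_classes <- as.integer(n_classes)
  samples_per_class <- as.integer(samples_per_class)
  n_points <- as.integer(n_points)
  if (n_classes < 1L || samples_per_class < 1L || n_points < 2L)
    stop("all counts must be >= 1 (and n_points >= 2)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  nb <- length(band_centers)
  if (length(band_widths) != nb || length(band_depths) != nb)
    stop("band_centers, band_widths, band_depths must share one length",
         call. = FALSE)
  if (is.null(class_effect)) {
    class_slopes <- rep_len(class_slopes, nb)
    class_effect <- 1 + outer(seq_len(n_classes) - 1L, class_slopes)
  }
  class_effect <- as.matrix(class_effect)
  if (nrow(class_effect) != n_classes || ncol(class_effect) != nb)
    stop("class_effect must be n_classes x n_bands", call. = FALSE)
  structure(list(n_classes = n_classes, samples_per_class = samples_per_class,
                 n_points = n_points, wn_range = as.numeric(wn_range),
                 band_centers = band_centers, band_widths = band_widths,
                 band_depths = band_depths, class_effect = class_effect,
                 baseline = baseline, baseline_tilt = baseline_tilt,
                 saturation_region = saturation_region,
                 saturation_absorbance = saturation_absorbance,
                 strength_sd = strength_sd, band_jitter_sd = band_jitter_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_classes, " classes x ", x$samples_per_class,
      " samples, ", x$n_points, " points (",
      format(x$wn_range[1]), " -> ", format(x$wn_range[2]), " cm^-1)\n", sep = "")
  cat("  ", length(x$band_centers), " absorption bands; noise_sd = ",
      format(x$noise_sd), "\n", sep = "")
  invisible(x)
}

#' Generate a labelled set of synthetic tea-like NIR absorbance spectra
#'
#' Deterministic under `cfg$seed`; labels are balanced (`samples_per_class`
#' of each level, grouped by level). Spectra are generated in absorbance
#' mode; convert with [absorbance_to_transmittance()] to obtain the
#' transmittance spectra the classification pipeline consumes.
#'
#' @param cfg A [synth_config()].
#' @return A `spectra_set` in absorbance mode with labels `1..n_classes`.
#' @examples
#' set <- generate_tea_spectra(synth_config(seed = 1))
#' set
#' @export
generate_tea_spectra <- function(cfg = synth_config()) {
  if (!inherits(cfg, "synth_config")) stop("expected a 'synth_config'", call. = FALSE)
  with_seed(cfg$seed, {
    wn <- seq(cfg$wn_range[1], cfg$wn_range[2], length.out = cfg$n_points)
    nb <- length(cfg$band_centers)
    # n_points x n_bands matrix of unit Gaussian band shapes
    shapes <- vapply(seq_len(nb), function(b)
      exp(-(wn - cfg$band_centers[b])^2 / (2 * cfg$band_widths[b]^2)),
      numeric(cfg$n_points))
    base <- cfg$baseline +
      cfg$baseline_tilt * (cfg$wn_range[1] - wn) /
        abs(cfg$wn_range[1] - cfg$wn_range[2]) +
      cfg$saturation_absorbance /
        (1 + exp((wn - cfg$saturation_region) / 60))
    n <- cfg$n_classes * cfg$samples_per_class
    vals <- matrix(0, n, cfg$n_points)
    labs <- rep(seq_len(cfg$n_classes), each = cfg$samples_per_class)
    for (i in seq_len(n)) {
      l <- labs[i]
      strength <- exp(stats::rnorm(1L, 0, cfg$strength_sd))
      jit <- exp(stats::rnorm(nb, 0, cfg$band_jitter_sd))
      depths <- cfg$band_depths * cfg$class_effect[l, ] * strength * jit
      a <- base + as.numeric(shapes %*% depths) +
        stats::rnorm(cfg$n_points, 0, cfg$noise_sd)
      vals[i, ] <- pmax(a, 0)
    }
    spectra_set(vals, wn, "absorbance",
                sample_id = sprintf("L%d_%02d", labs,
                                    sequence(rep(cfg$samples_per_class,
                                                 cfg$n_classes))),
                label = labs)
  })
}

#' Generate separable Gaussian feature blobs for classifier tests
#'
#' Draws `n_classes` class centers and unit-spread Gaussian samples around
#' them, rescaling the centers so the *minimum* inter-center distance equals
#' `separation`. `separation = 0` collapses all classes onto one
#' distribution (chance-level problem).
#'
#' @param n_classes Number of classes.
#' @param per_class Samples per class.
#' @param dim Feature dimension.
#' @param separation Minimum inter-center Euclidean distance, `>= 0`.
#' @param seed Optional integer seed.
#' @return A list with `x` (feature matrix, `n_classes * per_class` rows),
#'   `labels` (integer `1..n_classes`), and `centers`.
#' @export
generate_separable_features <- function(n_classes, per_class, dim,
                                        separation, seed = NULL) {
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  n_classes <- as.integer(n_classes)
  per_class <- as.integer(per_class)
  dim <- as.integer(dim)
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_classes * dim), n_classes, dim)
    if (separation == 0 || n_classes == 1L) {
      centers[] <- 0
    } else {
      dmin <- min(stats::dist(centers))
      while (dmin < .Machine$double.eps) {   # essentially never
        centers <- matrix(stats::rnorm(n_classes * dim), n_classes, dim)
        dmin <- min(stats::dist(centers))
      }
      centers <- centers * (separation / dmin)
    }
    labels <- rep(seq_len(n_classes), each = per_class)
    x <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(length(labels) * dim), ncol = dim)
    list(x = x, labels = labels, centers = centers)
  })
}

#' Write a synthetic-spectra configuration as JSON
#'
#' @param cfg A [synth_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
synth_config_write_json <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a synthetic-spectra configuration written by
#' [synth_config_write_json()]
#'
#' @param path JSON path.
#' @return A [synth_config()].
#' @export
synth_config_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$class_effect <- as.matrix(obj$class_effect)
  do.call(synth_config, obj)
}
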