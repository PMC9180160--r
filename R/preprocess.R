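#' Savitzky-Golay smoothing of a spectra set
#'
#' Smooths each spectrum with a moving least-squares polynomial filter.
#' The filter is parameterized by an odd window (`frame_length`, in grid
#' points) and a polynomial order; within each window the signal is replaced
#' by the value of the best-fitting polynomial at the window centre. A
#' degree-`p` filter reproduces any polynomial of degree `<= p` exactly in
#' the interior of the signal.
#'
#' @param x A `spectra_set`.
#' @param frame_length Odd window length in points, `>= 3` (default 21, the
#'   usual choice for FT-NIR grids of a few thousand points).
#' @param poly_order Polynomial order, `0 <= poly_order < frame_length`
#'   (default 2).
#' @param edge Edge handling: `"polynomial"` (default) fits the boundary
#'   windows' polynomials and evaluates them at the edge points, so the
#'   output keeps the input length; `"interior"` trims `(frame_length-1)/2`
#'   points from each end (grid trimmed accordingly).
#' @return A smoothed `spectra_set`.
#' @examples
#' s <- spectra_set(matrix(sin(seq(0, 6, length.out = 200)) + 0.5, 1),
#'                  seq(10000, 4000, length.out = 200), "absorbance")
#' sm <- sg_smooth(s, frame_length = 21, poly_order = 2)
#' @export
sg_smooth <- function(x, frame_length = 21L, poly_order = 2L,
                      edge = c("polynomial", "interior")) {
  stop_if_not_spectra(x)
  edge <- match.arg(edge)
  frame_length <- as.integer(frame_length)
  poly_order <- as.integer(poly_order)
  if (frame_length < 3L || frame_length %% 2L == 0L)
    stop("frame_length must be an odd integer >= 3", call. = FALSE)
  if (poly_order < 0L || poly_order >= frame_length)
    stop("poly_order must satisfy 0 <= poly_order < frame_length", call. = FALSE)
  p <- ncol(x$values)
  if (p < frame_length)
    stop("spectrum length (", p, ") is shorter than frame_length (",
         frame_length, ")", call. = FALSE)
  sm <- t(apply(x$values, 1L, signal::sgolayfilt, p = poly_order, n = frame_length))
  grid <- x$wavenumbers
  if (edge == "interior") {
    h <- (frame_length - 1L) %/% 2L
    keep <- (h + 1L):(p - h)
    sm <- sm[, keep, drop = FALSE]
    grid <- grid[keep]
  }
  # smoothing can nudge transmittance slightly outside [0,1]; clip
  if (x$mode == "transmittance") {
    sm[sm < 0] <- 0
    sm[sm > 1] <- 1
  } else {
    sm[sm < 0] <- 0
  }
  spectra_set(sm, grid, x$mode, sample_id = x$sample_id, label = x$label)
}

#' Fit a principal component model to spectra
#'
#' Mean-centred PCA (no variance scaling: transmittance values share one
#' physical unit). Loadings are the leading right singular vectors of the
#' centred data matrix; each loading's sign is fixed so its largest-magnitude
#' element is positive, making outputs reproducible across SVD backends.
#'
#' @param x A `spectra_set`, or a plain numeric matrix (samples in rows).
#' @param k Number of components to retain,
#'   `1 <= k <= min(n_samples - 1, n_points)`.
#' @return An object of class `spectra_pca` with fields `mean` (centring
#'   vector), `loadings` (`n_points x k`, orthonormal columns),
#'   `explained_variance_ratio` (first `k` fractions of total variance,
#'   non-increasing), `sdev` (all singular-value-derived standard
#'   deviations), and `k`.
#' @seealso [pca_transform()], [pca_reconstruct()]
#' @export
pca_fit <- function(x, k) {
  m <- if (inherits(x, "spectra_set")) x$values else as.matrix(x)
  n <- nrow(m); p <- ncol(m)
  k <- as.integer(k)
  kmax <- min(n - 1L, p)
  if (k < 1L || k > kmax)
    stop("k must be in 1..", kmax, " for ", n, " samples x ", p, " points",
         call. = FALSE)
  mu <- colMeans(m)
  cm <- sweep(m, 2L, mu)
  sv <- svd(cm, nu = 0L, nv = kmax)
  d2 <- sv$d[seq_len(kmax)]^2
  evr_all <- if (sum(d2) > 0) d2 / sum(d2) else rep(0, kmax)
  load <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |element| of each loading made positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(mean = mu, loadings = load,
                 explained_variance_ratio = evr_all[seq_len(k)],
                 sdev = sv$d[seq_len(kmax)] / sqrt(max(n - 1L, 1L)),
                 k = k, n_points = p),
            class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat("<spectra_pca> ", x$k, " components over ", x$n_points, " points\n", sep = "")
  evr <- round(100 * x$explained_variance_ratio, 2)
  cat("  explained variance (%):", paste(evr, collapse = ", "), "\n")
  invisible(x)
}

#' Project spectra onto a fitted principal component model
#'
#' @param model A `spectra_pca` from [pca_fit()].
#' @param x A `spectra_set` or numeric matrix on the same grid the model was
#'   fitted on.
#' @return Numeric score matrix, `n_samples x k`.
#' @export
pca_transform <- function(model, x) {
  if (!inherits(model, "spectra_pca")) stop("expected a 'spectra_pca' model", call. = FALSE)
  m <- if (inherits(x, "spectra_set")) x$values else as.matrix(x)
  if (ncol(m) != model$n_points)
    stop("grid mismatch: model fitted on ", model$n_points,
         " points, data has ", ncol(m), call. = FALSE)
  sweep(m, 2L, model$mean) %*% model$loadings
}

#' @export
predict.spectra_pca <- function(object, newdata, ...) pca_transform(object, newdata)

#' Reconstruct spectra from principal component scores
#'
#' @param model A `spectra_pca`.
#' @param scores Score matrix (`n_samples x k`).
#' @return Numeric matrix of reconstructed intensities.
#' @export
pca_reconstruct <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != model$k)
    stop("scores must have ", model$k, " columns", call. = FALSE)
  sweep(scores %*% t(model$loadings), 2L, model$mean, `+`)
}

#' Serialize a PCA model to JSON
#'
#' Writes the centring vector, loadings and explained-variance ratios as a
#' single JSON document readable by [pca_read_json()].
#'
#' @param model A `spectra_pca`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
pca_write_json <- function(model, path) {
  obj <- list(mean = model$mean,
              loadings = model$loadings,
              explained_variance_ratio = model$explained_variance_ratio,
              sdev = model$sdev, k = model$k, n_points = model$n_points)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PCA model written by [pca_write_json()]
#'
#' @param path JSON path.
#' @return A `spectra_pca`.
#' @export
pca_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(obj$mean),
                 loadings = as.matrix(obj$loadings),
                 explained_variance_ratio = as.numeric(obj$explained_variance_ratio),
                 sdev = as.numeric(obj$sdev),
                 k = as.integer(obj$k), n_points = as.integer(obj$n_points)),
            class = "spectra_pca")
}
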