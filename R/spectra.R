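#' Construct a set of wavenumber-gridded spectra
#'
#' A `spectra_set` is the package's container for NIR spectra: a numeric
#' matrix of intensities (one row per sample) on a shared, strictly monotone
#' wavenumber grid, together with an intensity mode flag and optional integer
#' class labels.
#'
#' @param values Numeric matrix, `n_samples x n_points`, one spectrum per row.
#'   A single spectrum may be given as a numeric vector.
#' @param wavenumbers Numeric vector of grid positions in cm^-1, strictly
#'   monotone (either direction); length must equal `ncol(values)`.
#' @param mode Either `"absorbance"` or `"transmittance"`. Absorbance values
#'   must be non-negative; transmittance values must lie in \[0, 1\] (a small
#'   round-off tolerance at the bounds is accepted and clipped).
#' @param sample_id Character vector of sample identifiers (default
#'   `"s1" ... "sn"`).
#' @param label Optional integer class labels in `1..L`, one per sample.
#'
#' @return An object of class `spectra_set` with fields `values`,
#'   `wavenumbers`, `mode`, `sample_id`, `label`.
#' @examples
#' s <- spectra_set(matrix(runif(20), 2, 10), seq(10000, 9100, by = -100),
#'                  mode = "transmittance", label = c(1L, 2L))
#' s
#' @export
spectra_set <- function(values, wavenumbers, mode = c("absorbance", "transmittance"),
                        sample_id = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 grid points", call. = FALSE)
  if (ncol(values) != length(wavenumbers))
    stop("ncol(values) [", ncol(values), "] does not match grid length [",
         length(wavenumbers), "]", call. = FALSE)
  dw <- diff(wavenumbers)
  if (!(all(dw > 0) || all(dw < 0)))
    stop("wavenumber grid must be strictly monotone", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("spectral values must be finite and non-missing", call. = FALSE)
  tol <- 1e-9
  if (mode == "transmittance") {
    if (any(values < -tol) || any(values > 1 + tol))
      stop("transmittance values must lie in [0, 1]", call. = FALSE)
    values[values < 0] <- 0
    values[values > 1] <- 1
  } else {
    if (any(values < -tol))
      stop("absorbance values must be non-negative", call. = FALSE)
    values[values < 0] <- 0
  }
  n <- nrow(values)
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n)
    stop("sample_id length must equal the number of spectra", call. = FALSE)
  if (!is.null(label)) {
    label <- as.integer(label)
    if (length(label) != n)
      stop("label length must equal the number of spectra", call. = FALSE)
    if (anyNA(label) || any(label < 1L))
      stop("labels must be positive integers in 1..L", call. = FALSE)
  }
  rownames(values) <- sample_id
  structure(list(values = values, wavenumbers = wavenumbers, mode = mode,
                 sample_id = sample_id, label = label),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat("<spectra_set> ", nrow(x$values), " spectra x ", ncol(x$values),
      " points, mode = ", x$mode, "\n", sep = "")
  cat("  grid: ", format(x$wavenumbers[1]), " -> ",
      format(x$wavenumbers[length(x$wavenumbers)]), " cm^-1\n", sep = "")
  if (!is.null(x$label)) {
    tab <- table(x$label)
    cat("  labels: ", paste0(names(tab), " (n=", tab, ")", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.matrix.spectra_set <- function(x, ...) x$values

#' @export
dim.spectra_set <- function(x) dim(x$values)

#' Subset a spectra_set by sample
#'
#' @param x A `spectra_set`.
#' @param i Row (sample) index.
#' @param ... Unused.
#' @return A `spectra_set` containing the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$values[i, , drop = FALSE], x$wavenumbers, x$mode,
              sample_id = x$sample_id[i],
              label = if (!is.null(x$label)) x$label[i])
}

n_spectra <- function(x) nrow(x$values)

stop_if_not_spectra <- function(x) {
  if (!inherits(x, "spectra_set"))
    stop("expected a 'spectra_set' object", call. = FALSE)
  invisible(x)
}

#' Convert absorbance spectra to transmittance
#'
#' Applies the Beer-Lambert relation `T = 10^(-A)` pointwise, producing
#' fractional transmittance in \[0, 1\].
#'
#' @param x A `spectra_set` in absorbance mode.
#' @return A `spectra_set` in transmittance mode on the same grid.
#' @seealso [transmittance_to_absorbance()] for the inverse.
#' @examples
#' a <- spectra_set(matrix(c(0, 1, 2), 1), c(9000, 8000, 7000), "absorbance")
#' absorbance_to_transmittance(a)$values   # 1, 0.1, 0.01
#' @export
absorbance_to_transmittance <- function(x) {
  stop_if_not_spectra(x)
  if (x$mode != "absorbance")
    stop("mode mismatch: expected absorbance spectra, got ", x$mode, call. = FALSE)
  spectra_set(10^(-x$values), x$wavenumbers, "transmittance",
              sample_id = x$sample_id, label = x$label)
}

#' Convert transmittance spectra to absorbance
#'
#' Applies `A = -log10(T)`. Zero transmittance values are floored at
#' `floor_eps` before taking the logarithm; the number of floored points is
#' reported as a warning.
#'
#' @param x A `spectra_set` in transmittance mode.
#' @param floor_eps Floor applied to zero transmittance before the log
#'   (default `1e-10`).
#' @return A `spectra_set` in absorbance mode. Round-tripping through
#'   [absorbance_to_transmittance()] is the identity to within 1e-12 for
#'   values above the floor.
#' @export
transmittance_to_absorbance <- function(x, floor_eps = 1e-10) {
  stop_if_not_spectra(x)
  if (x$mode != "transmittance")
    stop("mode mismatch: expected transmittance spectra, got ", x$mode, call. = FALSE)
  v <- x$values
  n_floored <- sum(v < floor_eps)
  if (n_floored > 0) {
    v[v < floor_eps] <- floor_eps
    warning(n_floored, " zero/near-zero transmittance value(s) floored at ",
            format(floor_eps), " before log", call. = FALSE)
  }
  spectra_set(-log10(v), x$wavenumbers, "absorbance",
              sample_id = x$sample_id, label = x$label)
}

#' Average replicate scans into one spectrum
#'
#' Instrument protocols often scan each sample several times and keep the
#' average as the sample's spectrum. This takes the pointwise arithmetic mean
#' over all spectra in `x`.
#'
#' @param x A `spectra_set` whose rows are replicate scans of one sample.
#' @param sample_id Identifier for the averaged spectrum; defaults to the
#'   longest common prefix of the replicate ids (or the first id if the
#'   prefix is empty).
#' @return A one-spectrum `spectra_set` on the same grid and mode.
#' @export
average_replicates <- function(x, sample_id = NULL) {
  stop_if_not_spectra(x)
  if (n_spectra(x) < 1L) stop("need at least one replicate", call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- common_prefix(x$sample_id)
    if (!nzchar(sample_id)) sample_id <- x$sample_id[1]
  }
  lab <- if (!is.null(x$label)) {
    if (length(unique(x$label)) > 1L)
      stop("replicates carry conflicting class labels", call. = FALSE)
    x$label[1]
  }
  spectra_set(colMeans(x$values), x$wavenumbers, x$mode,
              sample_id = sample_id, label = lab)
}

common_prefix <- function(ids) {
  if (length(ids) == 1L) return(ids)
  chars <- strsplit(ids, "")
  k <- min(lengths(chars))
  out <- 0L
  for (j in seq_len(k)) {
    cj <- vapply(chars, `[`, "", j)
    if (length(unique(cj)) > 1L) break
    out <- j
  }
  substr(ids[1], 1L, out)
}

#' Combine spectra sets sharing one grid and mode
#'
#' @param ... `spectra_set` objects on identical grids with identical mode.
#' @return A single `spectra_set` with the rows of all inputs.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  lapply(sets, stop_if_not_spectra)
  g <- sets[[1]]$wavenumbers
  m <- sets[[1]]$mode
  for (s in sets[-1]) {
    if (!identical(s$mode, m)) stop("cannot mix modes", call. = FALSE)
    if (length(s$wavenumbers) != length(g) || any(s$wavenumbers != g))
      stop("cannot mix wavenumber grids", call. = FALSE)
  }
  labs <- lapply(sets, `[[`, "label")
  has_lab <- !vapply(labs, is.null, TRUE)
  if (any(has_lab) && !all(has_lab))
    stop("either all or none of the sets may carry labels", call. = FALSE)
  spectra_set(do.call(rbind, lapply(sets, `[[`, "values")), g, m,
              sample_id = unlist(lapply(sets, `[[`, "sample_id")),
              label = if (all(has_lab)) unlist(labs))
}

#' Read a spectra table from delimited text
#'
#' The expected dialect is a header row `sample_id,label,w1,...,wN` where the
#' `wi` are numeric wavenumber headers in cm^-1 (monotone in either
#' direction), followed by one row per sample. An empty `label` column is
#' allowed (unlabelled data).
#'
#' @param path File path.
#' @param mode Intensity mode stored in the file.
#' @param sep Field delimiter (default comma).
#' @return A `spectra_set`.
#' @seealso [write_spectra_table()]
#' @export
read_spectra_table <- function(path, mode = c("absorbance", "transmittance"),
                               sep = ",") {
  mode <- match.arg(mode)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("spectra table needs a header and at least one row", call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  hdr <- fields[[1]]
  if (length(hdr) < 4L || hdr[1] != "sample_id" || hdr[2] != "label")
    stop("header must start with 'sample_id', 'label' followed by wavenumbers", call. = FALSE)
  wn <- suppressWarnings(as.numeric(hdr[-(1:2)]))
  if (anyNA(wn))
    stop("non-numeric wavenumber header at column ",
         which(is.na(wn))[1] + 2L, call. = FALSE)
  p <- length(wn)
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, n, p)
  ids <- character(n)
  labs <- rep(NA_integer_, n)
  for (r in seq_len(n)) {
    row <- fields[[r + 1L]]
    if (length(row) != p + 2L)
      stop("row ", r, ": expected ", p + 2L, " fields, found ", length(row), call. = FALSE)
    ids[r] <- row[1]
    if (nzchar(row[2])) {
      lv <- suppressWarnings(as.integer(row[2]))
      if (is.na(lv)) stop("row ", r, ": non-integer label '", row[2], "'", call. = FALSE)
      labs[r] <- lv
    }
    v <- suppressWarnings(as.numeric(row[-(1:2)]))
    if (anyNA(v))
      stop("row ", r, ", column ", which(is.na(v))[1] + 2L,
           ": non-numeric value", call. = FALSE)
    vals[r, ] <- v
  }
  label <- if (all(is.na(labs))) NULL else {
    if (anyNA(labs)) stop("labels must be present for all rows or none", call. = FALSE)
    labs
  }
  spectra_set(vals, wn, mode, sample_id = ids, label = label)
}

#' Write a spectra table as delimited text
#'
#' Inverse of [read_spectra_table()]; values are written at full precision
#' (17 significant digits) so that write-then-read round-trips the data.
#'
#' @param x A `spectra_set`.
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(x, path, sep = ",") {
  stop_if_not_spectra(x)
  hdr <- paste(c("sample_id", "label",
                 formatC(x$wavenumbers, format = "g", digits = 17)),
               collapse = sep)
  lab <- if (is.null(x$label)) rep("", n_spectra(x)) else as.character(x$label)
  body <- vapply(seq_len(n_spectra(x)), function(r) {
    paste(c(x$sample_id[r], lab[r],
            formatC(x$values[r, ], format = "g", digits = 17)), collapse = sep)
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
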