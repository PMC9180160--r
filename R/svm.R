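#' SVM hyperparameter pair (c, g)
#'
#' Bundles the soft-margin penalty `c` and the RBF kernel width `g`. The
#' kernel is `K(x, y) = exp(-||x - y||^2 / (2 g^2))`: large `g` means a wide,
#' smooth kernel; `c` controls the tolerance for misclassified training
#' samples.
#'
#' @param c Penalty parameter, finite and `> 0`.
#' @param g Kernel width parameter, finite and `> 0`.
#' @return An object of class `svm_params`.
#' @export
svm_params <- function(c = 2, g = 1) {
  c <- as.numeric(c); g <- as.numeric(g)
  if (length(c) != 1L || !is.finite(c) || c <= 0)
    stop("c must be a single finite value > 0", call. = FALSE)
  if (length(g) != 1L || !is.finite(g) || g <= 0)
    stop("g must be a single finite value > 0", call. = FALSE)
  structure(list(c = c, g = g), class = "svm_params")
}

#' @export
print.svm_params <- function(x, ...) {
  cat("<svm_params> c =", format(x$c), " g =", format(x$g), "\n")
  invisible(x)
}

#' Map the kernel width g to the solver's gamma parameterization
#'
#' The package's RBF kernel is written `exp(-||x-y||^2 / (2 g^2))` while
#' libsvm-style solvers use `exp(-gamma ||x-y||^2)`; the two coincide for
#' `gamma = 1 / (2 g^2)`. This is the single mapping used everywhere a
#' solver is invoked.
#'
#' @param g Kernel width parameter `> 0`.
#' @return The equivalent `gamma`.
#' @export
gamma_from_g <- function(g) {
  if (any(g <= 0)) stop("g must be > 0", call. = FALSE)
  1 / (2 * g^2)
}

#' RBF kernel value between two feature vectors
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param g Kernel width parameter `> 0`.
#' @return `exp(-||x1 - x2||^2 / (2 g^2))`, in `(0, 1]`; equals 1 iff
#'   `x1 == x2`.
#' @export
rbf_kernel <- function(x1, x2, g) {
  if (length(x1) != length(x2))
    stop("x1 and x2 must have equal length", call. = FALSE)
  exp(-gamma_from_g(g) * sum((x1 - x2)^2))
}

#' Train a one-vs-rest multiclass RBF-SVM
#'
#' Builds the multiclass model as `L` explicit binary soft-margin RBF
#' classifiers, classifier `l` trained on class `l` (positive) versus all
#' other classes (negative), all with the same `(c, g)`. Prediction assigns
#' the class whose binary decision value is largest. Quadratic-programming
#' solving is delegated to libsvm via \pkg{e1071}; the kernel
#' parameterization, decision scheme and tie rule live here.
#'
#' @param x Numeric feature matrix (`n_samples x n_features`), typically PCA
#'   scores.
#' @param labels Integer class labels in `1..L`; every class in `1..L`
#'   (with `L = max(labels)`) must be present.
#' @param params An [svm_params()] pair.
#' @param balance_classes If `TRUE`, each binary problem reweights the
#'   positive class by the inverse class frequency. Default `FALSE`: the
#'   natural one-vs-rest imbalance is left as-is.
#' @return An object of class `ovr_svm` with the `L` binary fits, `params`,
#'   `class_count` and per-class support-vector counts.
#' @examples
#' f <- generate_separable_features(3, 10, 2, separation = 10, seed = 1)
#' m <- train_ovr(f$x, f$labels, svm_params(2, 1))
#' mean(predict(m, f$x) == f$labels)
#' @export
train_ovr <- function(x, labels, params = svm_params(),
                      balance_classes = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  if (nrow(x) != length(labels))
    stop("nrow(x) must equal length(labels)", call. = FALSE)
  if (!inherits(params, "svm_params")) params <- do.call(svm_params, as.list(params))
  L <- max(labels)
  present <- sort(unique(labels))
  missing_cls <- setdiff(seq_len(L), present)
  if (L < 2L)
    stop("need at least 2 classes present in the training labels", call. = FALSE)
  if (length(missing_cls) > 0L)
    stop("class(es) absent from training labels: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  gam <- gamma_from_g(params$g)
  fits <- vector("list", L)
  for (l in seq_len(L)) {
    y <- factor(ifelse(labels == l, "pos", "neg"), levels = c("pos", "neg"))
    cw <- NULL
    if (balance_classes) {
      tab <- table(y)
      cw <- as.numeric(length(y) / (2 * tab))
      names(cw) <- names(tab)
    }
    fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = params$c, gamma = gam, scale = FALSE,
                      class.weights = cw, fitted = FALSE)
    # libsvm orders decision values by first label seen in the data, not by
    # factor level; flip so "pos" always scores positive
    fits[[l]] <- list(fit = fit, flip = fit$labels[1] == 2L)
  }
  structure(list(binary_models = fits, params = params, class_count = L,
                 n_features = ncol(x),
                 support_counts = vapply(fits, function(f) f$fit$tot.nSV, 0L)),
            class = "ovr_svm")
}

#' @export
print.ovr_svm <- function(x, ...) {
  cat("<ovr_svm> ", x$class_count, " one-vs-rest RBF classifiers, c = ",
      format(x$params$c), ", g = ", format(x$params$g), "\n", sep = "")
  cat("  support vectors per class:",
      paste(x$support_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Per-class decision values of a one-vs-rest SVM
#'
#' @param model An `ovr_svm`.
#' @param x Feature matrix with the training dimensionality.
#' @return Numeric matrix `n_samples x L`: signed decision-function values,
#'   column `l` from the class-`l`-vs-rest classifier (positive means
#'   "looks like class l").
#' @export
predict_scores <- function(model, x) {
  if (!inherits(model, "ovr_svm")) stop("expected an 'ovr_svm' model", call. = FALSE)
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop("feature dimension mismatch: model trained on ", model$n_features,
         ", data has ", ncol(x), call. = FALSE)
  out <- matrix(NA_real_, nrow(x), model$class_count)
  for (l in seq_len(model$class_count)) {
    bm <- model$binary_models[[l]]
    pr <- predict(bm$fit, x, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    out[, l] <- if (bm$flip) -dv else dv
  }
  out
}

#' Class labels from a one-vs-rest SVM by the max-score rule
#'
#' @inheritParams predict_scores
#' @return Integer labels in `1..L`: the argmax of the decision values, ties
#'   broken toward the lowest class index.
#' @export
predict_labels <- function(model, x) {
  sc <- predict_scores(model, x)
  max.col(sc, ties.method = "first")
}

#' @export
predict.ovr_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") predict_scores(object, newdata)
  else predict_labels(object, newdata)
}

#' Classification accuracy
#'
#' @param pred,truth Equal-length label vectors.
#' @return Fraction of exact matches in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1L)
    stop("pred and truth must have equal length >= 1", call. = FALSE)
  mean(pred == truth)
}

#' Summarize a one-vs-rest SVM model as JSON
#'
#' @param model An `ovr_svm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
ovr_write_json <- function(model, path) {
  obj <- list(type = "ovr_svm", class_count = model$class_count,
              c = model$params$c, g = model$params$g,
              n_features = model$n_features,
              support_counts = as.integer(model$support_counts))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
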