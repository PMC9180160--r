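#' Fit the full NIR classification pipeline to labelled spectra
#'
#' The headline fitting interface: takes labelled absorbance (or
#' transmittance) spectra and fits the complete chain — transmittance
#' conversion, Savitzky-Golay smoothing, PCA reduction to `pc` components,
#' and a one-vs-rest RBF-SVM, optionally with `(c, g)` tuned by a particle
#' swarm (`tune = "pso"`) or comprehensive-learning particle swarm
#' (`tune = "clpso"`).
#'
#' @param set A labelled `spectra_set`.
#' @param pc Number of principal components used as SVM inputs (default
#'   16).
#' @param tune `"none"` (default; uses `params` as given), `"pso"` or
#'   `"clpso"`.
#' @param params Fixed [svm_params()] used when `tune = "none"` (default
#'   `c = 2, g = 1`).
#' @param sg_frame,sg_order Savitzky-Golay settings (defaults 21, 2).
#' @param swarm A [swarm_control()] for the tuned variants.
#' @param fitness,cv_folds Swarm fitness protocol, as in [tune_svm()].
#' @return An object of class `spectra_svm` holding the preprocessing
#'   settings, the fitted `spectra_pca`, the `ovr_svm`, the final
#'   [svm_params()], and (for tuned fits) the `svm_tuning` record.
#' @examples
#' set <- generate_tea_spectra(synth_config(seed = 4))
#' fit <- spectra_svm(set, pc = 16)
#' fit
#' mean(predict(fit, set) == set$label)
#' @seealso [run_rotation_evaluation()] for held-out evaluation;
#'   [compare_methods()] for the four-method comparison.
#' @export
spectra_svm <- function(set, pc = 16L, tune = c("none", "pso", "clpso"),
                        params = svm_params(2, 1),
                        sg_frame = 21L, sg_order = 2L,
                        swarm = swarm_control(),
                        fitness = c("cv", "train"), cv_folds = 5L) {
  tune <- match.arg(tune)
  fitness <- match.arg(fitness)
  stop_if_not_spectra(set)
  if (is.null(set$label)) stop("set must carry class labels", call. = FALSE)
  if (set$mode == "absorbance") set <- absorbance_to_transmittance(set)
  sm <- sg_smooth(set, frame_length = sg_frame, poly_order = sg_order)
  pca <- pca_fit(sm, pc)
  scores <- pca_transform(pca, sm)
  tuning <- NULL
  if (tune != "none") {
    tuning <- tune_svm(scores, sm$label, control = swarm,
                       variant = if (tune == "pso") "pso" else "clpso",
                       fitness = fitness, cv_folds = cv_folds)
    params <- tuning$params
  }
  model <- train_ovr(scores, sm$label, params)
  structure(list(pca = pca, model = model, params = params, tuning = tuning,
                 tune = tune, pc = as.integer(pc),
                 sg_frame = as.integer(sg_frame),
                 sg_order = as.integer(sg_order),
                 class_count = model$class_count,
                 train_accuracy = accuracy(predict_labels(model, scores),
                                           sm$label),
                 wavenumbers = set$wavenumbers),
            class = "spectra_svm")
}

preprocess_like <- function(object, set) {
  stop_if_not_spectra(set)
  if (set$mode == "absorbance") set <- absorbance_to_transmittance(set)
  if (length(set$wavenumbers) != length(object$wavenumbers) ||
      any(set$wavenumbers != object$wavenumbers))
    stop("new spectra are not on the training wavenumber grid", call. = FALSE)
  sm <- sg_smooth(set, frame_length = object$sg_frame,
                  poly_order = object$sg_order)
  pca_transform(object$pca, sm)
}

#' @export
predict.spectra_svm <- function(object, newdata,
                                type = c("class", "score"), ...) {
  type <- match.arg(type)
  scores <- preprocess_like(object, newdata)
  if (type == "score") predict_scores(object$model, scores)
  else predict_labels(object$model, scores)
}

#' @export
print.spectra_svm <- function(x, ...) {
  cat("<spectra_svm> ", x$class_count, "-class RBF-SVM on ", x$pc,
      " principal components\n", sep = "")
  cat("  tuning: ", if (x$tune == "none") "none (fixed parameters)"
      else toupper(x$tune), "; c = ", format(x$params$c),
      ", g = ", format(x$params$g), "\n", sep = "")
  cat("  training accuracy: ", sprintf("%.2f%%", 100 * x$train_accuracy),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.spectra_svm <- function(object, ...) {
  cat("Pipeline: transmittance -> Savitzky-Golay (frame ", object$sg_frame,
      ", order ", object$sg_order, ") -> PCA(", object$pc,
      ") -> one-vs-rest RBF-SVM\n", sep = "")
  print(object)
  evr <- object$pca$explained_variance_ratio
  cat("  PCA explained variance (%): ",
      paste(sprintf("%.1f", 100 * evr[seq_len(min(5, length(evr)))]),
            collapse = ", "),
      if (length(evr) > 5) ", ...", "\n", sep = "")
  if (!is.null(object$tuning)) {
    cat("  swarm: ", object$tuning$variant, ", fitness = ",
        object$tuning$fitness, ", best fitness = ",
        format(object$tuning$result$best_fitness), "\n", sep = "")
  }
  cat("  support vectors per class: ",
      paste(object$model$support_counts, collapse = ", "), "\n", sep = "")
  invisible(object)
}
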