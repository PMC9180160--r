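#' Control settings for the rotation evaluation protocol
#'
#' Bundles the preprocessing, fixed SVM parameters, swarm settings and
#' protocol switches used by [run_rotation_evaluation()], [pc_sweep()] and
#' [compare_methods()].
#'
#' @param sg_frame,sg_order Savitzky-Golay window and polynomial order
#'   (defaults 21 and 2).
#' @param params Fixed [svm_params()] for the untuned SVM (default
#'   `c = 2, g = 1`).
#' @param swarm A [swarm_control()] for the tuned methods; its `seed` field
#'   is overridden per fold (derived from `seed` below).
#' @param fitness Swarm fitness protocol: `"cv"` (default, stratified
#'   cross-validation within the training partition) or `"train"`
#'   (resubstitution accuracy, the paper-faithful reading).
#' @param cv_folds Folds for the `"cv"` fitness (default 5).
#' @param global_pca If `TRUE`, PCA is fitted once on all samples before
#'   splitting (paper-faithful but leaks test information); default `FALSE`
#'   fits PCA on each fold's training partition only.
#' @param seed Integer seed driving fold-level tuning randomness.
#' @return An object of class `eval_control`.
#' @export
eval_control <- function(sg_frame = 21L, sg_order = 2L,
                         params = svm_params(2, 1),
                         swarm = swarm_control(),
                         fitness = c("cv", "train"), cv_folds = 5L,
                         global_pca = FALSE, seed = 1L) {
  structure(list(sg_frame = as.integer(sg_frame), sg_order = as.integer(sg_order),
                 params = params, swarm = swarm,
                 fitness = match.arg(fitness), cv_folds = as.integer(cv_folds),
                 global_pca = isTRUE(global_pca), seed = seed),
            class = "eval_control")
}

eval_methods <- c("svm_fixed", "plsda", "pso_svm", "clpso_svm")

# small deterministic seed derivation, kept under 2^31
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  k <- as.numeric(seed)
  for (u in c(...)) k <- (k * 69069 + as.numeric(u) * 12345 + 1) %% 2147483647
  as.integer(k)
}

#' Stratified rotation fold plan
#'
#' Randomly assigns samples to `G` mutually exclusive, exhaustive groups.
#' With `stratified = TRUE` (default) each class is dealt round-robin across
#' groups after shuffling, so per-class counts across groups differ by at
#' most one — 120 samples of 6 balanced classes in 4 groups gives 30 samples
#' per group, 5 per class.
#'
#' @param labels Class labels (any vector; used only for stratification and
#'   length).
#' @param G Number of groups (default 4), `2 <= G <= n`.
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Optional integer seed.
#' @return An object of class `fold_plan` with `groups` (integer `1..G` per
#'   sample), `G`, `stratified`, `seed`.
#' @export
make_rotation_folds <- function(labels, G = 4L, stratified = TRUE, seed = NULL) {
  n <- length(labels)
  G <- as.integer(G)
  if (G < 2L) stop("G must be >= 2", call. = FALSE)
  if (G > n) stop("G (", G, ") exceeds the number of samples (", n, ")",
                  call. = FALSE)
  groups <- with_seed(seed, {
    if (stratified) {
      g <- integer(n)
      offset <- 0L
      for (l in unique(labels)) {
        idx <- which(labels == l)
        idx <- idx[sample.int(length(idx))]
        # rotate the starting group across classes so remainders spread
        g[idx] <- ((offset + seq_along(idx) - 1L) %% G) + 1L
        offset <- offset + length(idx)
      }
      g
    } else {
      ((sample.int(n) - 1L) %% G) + 1L
    }
  })
  structure(list(groups = groups, G = G, stratified = isTRUE(stratified),
                 seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> ", length(x$groups), " samples in ", x$G, " groups",
      if (x$stratified) " (stratified)", "\n", sep = "")
  print(table(group = x$groups))
  invisible(x)
}

# shared preprocessing: absorbance -> transmittance, then SG smoothing
preprocess_for_eval <- function(set, control) {
  stop_if_not_spectra(set)
  if (set$mode == "absorbance") set <- absorbance_to_transmittance(set)
  sg_smooth(set, frame_length = control$sg_frame, poly_order = control$sg_order)
}

fit_fold_method <- function(method, train_x, train_y, test_x, pc_count,
                            control, fold_seed) {
  if (method == "plsda") {
    m <- plsda_fit(train_x, train_y, n_components = pc_count)
    return(list(train_pred = plsda_predict(m, train_x),
                test_pred = plsda_predict(m, test_x),
                c = NA_real_, g = NA_real_))
  }
  params <- control$params
  if (method %in% c("pso_svm", "clpso_svm")) {
    sw <- control$swarm
    sw$seed <- fold_seed
    tuned <- tune_svm(train_x, train_y, control = sw,
                      variant = if (method == "pso_svm") "pso" else "clpso",
                      fitness = control$fitness, cv_folds = control$cv_folds)
    params <- tuned$params
  }
  m <- train_ovr(train_x, train_y, params)
  list(train_pred = predict_labels(m, train_x),
       test_pred = predict_labels(m, test_x),
       c = params$c, g = params$g)
}

#' Rotation evaluation of one method at one PC count
#'
#' Implements the rotation protocol: spectra are converted to transmittance
#' and Savitzky-Golay smoothed once; then, for each group of the plan in
#' turn, that group is held out, PCA is fitted on the remaining training
#' partition only (unless `control$global_pca`), both partitions are
#' projected, the classifier is trained (with `(c, g)` tuned inside the
#' training partition for the swarm methods; fixed `control$params` for
#' `svm_fixed`), and accuracy is measured on the held-out group. PLS-DA
#' consumes the smoothed spectra directly, `pc_count` acting as its number
#' of latent variables.
#'
#' @param set A labelled `spectra_set` (absorbance or transmittance).
#' @param method One of `"svm_fixed"`, `"plsda"`, `"pso_svm"`,
#'   `"clpso_svm"`.
#' @param pc_count Number of principal components (or PLS latent variables).
#' @param plan A [make_rotation_folds()] plan for the set.
#' @param control An [eval_control()].
#' @return A list of class `rotation_result`: `folds` (data frame with
#'   `fold`, `train_acc`, `test_acc`, `c`, `g`), `mean_train`, `mean_test`,
#'   `method`, `pc_count`, and `details` (per fold: the PCA centring vector
#'   and test indices, for leakage auditing).
#' @export
run_rotation_evaluation <- function(set, method, pc_count, plan,
                                    control = eval_control()) {
  method <- match.arg(method, eval_methods)
  if (!inherits(plan, "fold_plan")) stop("plan must be a 'fold_plan'", call. = FALSE)
  if (is.null(set$label)) stop("set must carry class labels", call. = FALSE)
  if (length(plan$groups) != n_spectra(set))
    stop("plan covers ", length(plan$groups), " samples but set has ",
         n_spectra(set), call. = FALSE)
  sm <- preprocess_for_eval(set, control)
  labels <- sm$label
  global_model <- if (control$global_pca && method != "plsda")
    pca_fit(sm, pc_count)
  folds <- data.frame(fold = seq_len(plan$G), train_acc = NA_real_,
                      test_acc = NA_real_, c = NA_real_, g = NA_real_)
  details <- vector("list", plan$G)
  for (f in seq_len(plan$G)) {
    te <- plan$groups == f
    tr <- !te
    fold_seed <- derive_seed(control$seed, match(method, eval_methods),
                             pc_count, f)
    res <- tryCatch({
      if (method == "plsda") {
        train_x <- sm$values[tr, , drop = FALSE]
        test_x <- sm$values[te, , drop = FALSE]
        pca_mean <- NULL
      } else {
        pca <- if (control$global_pca) global_model
               else pca_fit(sm[which(tr)], pc_count)
        train_x <- pca_transform(pca, sm[which(tr)])
        test_x <- pca_transform(pca, sm[which(te)])
        pca_mean <- pca$mean
      }
      out <- fit_fold_method(method, train_x, labels[tr], test_x, pc_count,
                             control, fold_seed)
      out$pca_mean <- pca_mean
      out
    }, error = function(e)
      stop("fold ", f, " (", method, ", pc=", pc_count, "): ",
           conditionMessage(e), call. = FALSE))
    folds$train_acc[f] <- accuracy(res$train_pred, labels[tr])
    folds$test_acc[f] <- accuracy(res$test_pred, labels[te])
    folds$c[f] <- res$c
    folds$g[f] <- res$g
    details[[f]] <- list(pca_mean = res$pca_mean, test_idx = which(te))
  }
  structure(list(folds = folds,
                 mean_train = mean(folds$train_acc),
                 mean_test = mean(folds$test_acc),
                 method = method, pc_count = pc_count, details = details),
            class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat("<rotation_result> ", x$method, ", pc = ", x$pc_count, "\n", sep = "")
  print(x$folds, row.names = FALSE)
  cat("  mean train = ", format(round(x$mean_train, 4)),
      ", mean test = ", format(round(x$mean_test, 4)), "\n", sep = "")
  invisible(x)
}

#' Sweep the rotation evaluation over a range of PC counts
#'
#' @inheritParams run_rotation_evaluation
#' @param pc_range Integer vector of PC counts to evaluate (default
#'   `1:25`).
#' @return A list of class `pc_sweep`: `table` (one row per PC count with
#'   mean train/test accuracy), `folds` (long per-fold data frame),
#'   `best_pc` (argmax of mean test accuracy, ties toward the smallest
#'   count), `best_mean_test`, `method`.
#' @export
pc_sweep <- function(set, method, pc_range = 1:25, plan,
                     control = eval_control()) {
  method <- match.arg(method, eval_methods)
  pc_range <- as.integer(pc_range)
  if (length(pc_range) < 1L) stop("pc_range must be non-empty", call. = FALSE)
  runs <- lapply(pc_range, function(k)
    run_rotation_evaluation(set, method, k, plan, control))
  tab <- data.frame(pc = pc_range,
                    mean_train = vapply(runs, `[[`, 0, "mean_train"),
                    mean_test = vapply(runs, `[[`, 0, "mean_test"))
  long <- do.call(rbind, lapply(runs, function(r)
    cbind(pc = r$pc_count, r$folds)))
  best_i <- which.max(tab$mean_test)   # which.max takes the first maximum
  structure(list(table = tab, folds = long,
                 best_pc = tab$pc[best_i],
                 best_mean_test = tab$mean_test[best_i],
                 best_mean_train = tab$mean_train[best_i],
                 method = method),
            class = "pc_sweep")
}

#' @export
print.pc_sweep <- function(x, ...) {
  cat("<pc_sweep> ", x$method, " over pc = ",
      paste(range(x$table$pc), collapse = ".."), "\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("  best pc = ", x$best_pc, " (mean test accuracy ",
      format(round(x$best_mean_test, 4)), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.pc_sweep <- function(x, ...) {
  graphics::plot(x$table$pc, 100 * x$table$mean_test, type = "b",
                 xlab = "number of PCs", ylab = "mean test accuracy (%)",
                 main = x$method, ...)
  invisible(x)
}

#' Compare the four classification methods
#'
#' Runs [pc_sweep()] for the fixed-parameter SVM, PLS-DA, PSO-tuned SVM and
#' CLPSO-tuned SVM (in that order) on one fold plan, and reports each
#' method's best PC count with its mean train and test accuracy — the
#' four-row comparison table of the evaluation protocol.
#'
#' @inheritParams pc_sweep
#' @return A list of class `method_comparison`: `table` (four rows: method,
#'   best_pc, train_accuracy, test_accuracy) and `sweeps` (the four
#'   `pc_sweep` objects, named).
#' @export
compare_methods <- function(set, pc_range = 1:25, plan,
                            control = eval_control()) {
  sweeps <- lapply(eval_methods, function(m)
    pc_sweep(set, m, pc_range, plan, control))
  names(sweeps) <- eval_methods
  tab <- data.frame(method = c("SVM", "PLS-DA", "PSO-SVM", "CLPSO-SVM"),
                    best_pc = vapply(sweeps, `[[`, 0L, "best_pc"),
                    train_accuracy = vapply(sweeps, `[[`, 0, "best_mean_train"),
                    test_accuracy = vapply(sweeps, `[[`, 0, "best_mean_test"),
                    row.names = NULL)
  structure(list(table = tab, sweeps = sweeps), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  tab <- x$table
  tab$train_accuracy <- sprintf("%.2f%%", 100 * tab$train_accuracy)
  tab$test_accuracy <- sprintf("%.2f%%", 100 * tab$test_accuracy)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a method-comparison table as CSV
#'
#' @param comparison A `method_comparison`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}
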