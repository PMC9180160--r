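#' Fit a PLS-DA classifier (NIPALS PLS2)
#'
#' Partial least squares discriminant analysis: the class labels are coded
#' as a one-hot indicator matrix, both blocks are mean-centred (no variance
#' scaling), and a NIPALS PLS2 decomposition with `n_components` latent
#' variables is fitted. Prediction regresses the indicator block on the
#' latent scores and assigns the class of the largest predicted indicator
#' column.
#'
#' @param x Feature matrix (`n_samples x n_features`).
#' @param labels Integer class labels `1..L`, all classes present.
#' @param n_components Latent variables to retain,
#'   `1 <= n_components <= min(n_samples - 1, n_features)`.
#' @param tol NIPALS convergence tolerance on the score vector (default
#'   1e-10).
#' @param max_nipals Iteration cap per component (default 500).
#' @return An object of class `plsda` with the centring vectors, the
#'   X-weights `W`, X-loadings `P`, Y-loadings `Q`, scores `Tmat`, and the
#'   regression coefficients `B` mapping centred X to centred indicators.
#' @examples
#' f <- generate_separable_features(3, 8, 4, separation = 8, seed = 2)
#' m <- plsda_fit(f$x, f$labels, n_components = 3)
#' mean(plsda_predict(m, f$x) == f$labels)
#' @export
plsda_fit <- function(x, labels, n_components, tol = 1e-10, max_nipals = 500L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  n <- nrow(x); p <- ncol(x)
  if (n != length(labels)) stop("nrow(x) must equal length(labels)", call. = FALSE)
  L <- max(labels)
  if (length(setdiff(seq_len(L), unique(labels))) > 0L || L < 2L)
    stop("all classes 1..L (L >= 2) must be present", call. = FALSE)
  a_max <- min(n - 1L, p)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > a_max)
    stop("n_components must be in 1..", a_max, call. = FALSE)
  Y <- matrix(0, n, L)
  Y[cbind(seq_len(n), labels)] <- 1
  x_mean <- colMeans(x); y_mean <- colMeans(Y)
  E <- sweep(x, 2L, x_mean)
  F_ <- sweep(Y, 2L, y_mean)
  W <- matrix(0, p, n_components)   # X weights
  P <- matrix(0, p, n_components)   # X loadings
  Q <- matrix(0, L, n_components)   # Y loadings (regression of F on t)
  Tmat <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    # start u at the F column with the largest variance
    u <- F_[, which.max(apply(F_, 2L, stats::var))]
    if (sum(u^2) < .Machine$double.eps) u <- E[, which.max(colSums(E^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_nipals)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) break
      w <- w / nw
      t_ <- E %*% w
      q <- crossprod(F_, t_) / sum(t_^2)
      u <- F_ %*% q / sum(q^2)
      if (sqrt(sum((t_ - t_old)^2)) < tol * sqrt(sum(t_^2))) break
      t_old <- t_
    }
    t_ <- as.numeric(E %*% w)
    tt <- sum(t_^2)
    if (tt < .Machine$double.eps) {
      # no variance left; truncate
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[, seq_len(a - 1L), drop = FALSE]
      Tmat <- Tmat[, seq_len(a - 1L), drop = FALSE]
      n_components <- a - 1L
      break
    }
    p_a <- as.numeric(crossprod(E, t_)) / tt
    q_a <- as.numeric(crossprod(F_, t_)) / tt
    E <- E - tcrossprod(t_, p_a)
    F_ <- F_ - tcrossprod(t_, q_a)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q_a; Tmat[, a] <- t_
  }
  # coefficients for centred data: B = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, Q = Q,
                 Tmat = Tmat, B = B, n_components = n_components,
                 class_count = L, n_features = p),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("<plsda> ", x$n_components, " latent variables, ", x$class_count,
      " classes, ", x$n_features, " features\n", sep = "")
  invisible(x)
}

#' Continuous class-indicator predictions of a PLS-DA model
#'
#' @param model A `plsda` fit.
#' @param x Feature matrix with the training dimensionality.
#' @return Numeric matrix `n_samples x L` of predicted indicator values.
#' @export
plsda_scores <- function(model, x) {
  if (!inherits(model, "plsda")) stop("expected a 'plsda' model", call. = FALSE)
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop("feature dimension mismatch: model trained on ", model$n_features,
         ", data has ", ncol(x), call. = FALSE)
  sweep(sweep(x, 2L, model$x_mean) %*% model$B, 2L, model$y_mean, `+`)
}

#' Class labels from a PLS-DA model
#'
#' @inheritParams plsda_scores
#' @return Integer labels `1..L`: argmax over predicted indicator columns,
#'   ties broken toward the lowest class index.
#' @export
plsda_predict <- function(model, x) {
  max.col(plsda_scores(model, x), ties.method = "first")
}

#' @export
predict.plsda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") plsda_scores(object, newdata)
  else plsda_predict(object, newdata)
}

#' Summarize a PLS-DA model as JSON
#'
#' @param model A `plsda`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
plsda_write_json <- function(model, path) {
  obj <- list(type = "plsda", class_count = model$class_count,
              n_components = model$n_components, n_features = model$n_features)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
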