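#' Swarm optimizer configuration
#'
#' Settings for the basic particle swarm optimizer (PSO) and the
#' comprehensive-learning variant (CLPSO). Defaults follow the common
#' SVM-tuning setup: 40 particles, 40 iterations, acceleration factors
#' 1.49445, inertia weight scheduled linearly from 0.9 down to 0.4, and
#' learning-probability parameters a = 0, b = 0.5.
#'
#' @param pop Swarm size, `>= 2` (default 40).
#' @param max_iter Iteration budget, `>= 0` (default 40). `0` means the
#'   swarm is only initialized and evaluated once.
#' @param c1,c2 PSO acceleration factors toward the personal and global best
#'   (default 1.49445 each).
#' @param ca CLPSO acceleration factor toward the exemplar (default
#'   1.49445).
#' @param w_max,w_min Inertia-weight endpoints of the linear schedule
#'   (defaults 0.9 and 0.4); used by CLPSO always and by PSO only when
#'   `pso_inertia = TRUE`.
#' @param a_prob,b_prob Learning-probability parameters: particle `i` gets
#'   `Pc_i = a + b * (exp(10 (i-1)/(pop-1)) - 1) / (exp(10) - 1)`, so `Pc`
#'   ranges over `[a, a + b]`. Defaults 0 and 0.5.
#' @param bounds Two-column matrix (one row per dimension) of lower/upper
#'   position bounds. Default: the 2-D box `[-2, 2]^2`, i.e. `c` and `g`
#'   searched over four decades on the log10 scale.
#' @param v_max Per-dimension velocity cap; default `0.2 * (upper - lower)`.
#' @param refresh_gap Iterations a particle's personal best may stagnate
#'   before its CLPSO exemplars are reassigned (default 7).
#' @param pso_inertia Apply the inertia-weight schedule to basic PSO too
#'   (default `FALSE`: the basic update carries the previous velocity with
#'   implicit weight 1).
#' @param seed Optional integer seed; every stochastic draw of the run flows
#'   from it. `NULL` uses the current RNG stream.
#' @return An object of class `swarm_control`.
#' @export
swarm_control <- function(pop = 40L, max_iter = 40L,
                          c1 = 1.49445, c2 = 1.49445, ca = 1.49445,
                          w_max = 0.9, w_min = 0.4,
                          a_prob = 0, b_prob = 0.5,
                          bounds = cbind(c(-2, -2), c(2, 2)),
                          v_max = NULL, refresh_gap = 7L,
                          pso_inertia = FALSE, seed = NULL) {
  pop <- as.integer(pop); max_iter <- as.integer(max_iter)
  if (pop < 2L) stop("pop must be >= 2", call. = FALSE)
  if (max_iter < 0L) stop("max_iter must be >= 0", call. = FALSE)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a matrix with columns (lower, upper), lower < upper",
         call. = FALSE)
  if (a_prob < 0 || b_prob < 0 || a_prob + b_prob > 1)
    stop("need 0 <= a_prob and a_prob + b_prob <= 1", call. = FALSE)
  if (w_min > w_max) stop("need w_min <= w_max", call. = FALSE)
  if (is.null(v_max)) v_max <- 0.2 * (bounds[, 2] - bounds[, 1])
  v_max <- rep_len(as.numeric(v_max), nrow(bounds))
  if (any(v_max <= 0)) stop("v_max must be positive", call. = FALSE)
  structure(list(pop = pop, max_iter = max_iter, c1 = c1, c2 = c2, ca = ca,
                 w_max = w_max, w_min = w_min, a_prob = a_prob, b_prob = b_prob,
                 bounds = bounds, v_max = v_max,
                 refresh_gap = as.integer(refresh_gap),
                 pso_inertia = isTRUE(pso_inertia), seed = seed),
            class = "swarm_control")
}

#' Linearly decreasing inertia weight
#'
#' `w(k) = w_max - (w_max - w_min) * k / max_iter`: the weight starts at
#' `w_max` (global search) and falls linearly to `w_min` at the final
#' iteration (local search).
#'
#' @param k Iteration counter, `0 <= k <= max_iter`.
#' @param control A [swarm_control()].
#' @return The inertia weight, in `[w_min, w_max]`.
#' @export
inertia_weight <- function(k, control) {
  if (k < 0 || k > control$max_iter)
    stop("k must be in 0..max_iter", call. = FALSE)
  if (control$max_iter == 0L) return(control$w_max)
  control$w_max - (control$w_max - control$w_min) * k / control$max_iter
}

#' CLPSO learning probability of a particle
#'
#' `Pc_i = a + b * (exp(10 (i-1)/(pop-1)) - 1) / (exp(10) - 1)`, strictly
#' increasing in the particle index: low-index particles mostly refine their
#' own personal best, high-index particles learn aggressively from others.
#'
#' @param i Particle index, `1..pop`.
#' @param control A [swarm_control()] with `pop >= 2`.
#' @return `Pc_i`, in `[a_prob, a_prob + b_prob]`.
#' @export
learning_probability <- function(i, control) {
  if (control$pop < 2L)
    stop("learning probability undefined for pop < 2", call. = FALSE)
  if (any(i < 1L) || any(i > control$pop))
    stop("particle index out of 1..pop", call. = FALSE)
  control$a_prob + control$b_prob *
    (exp(10 * (i - 1) / (control$pop - 1)) - 1) / (exp(10) - 1)
}

# reflect positions into [lo, hi]; returns list(x, flipped)
reflect_into <- function(x, lo, hi) {
  flipped <- rep(FALSE, length(x))
  for (iter in 1:100) {
    below <- x < lo; above <- x > hi
    if (!any(below) && !any(above)) break
    x[below] <- 2 * lo[below] - x[below]
    x[above] <- 2 * hi[above] - x[above]
    flipped <- flipped | below | above
  }
  # pathological velocities: clamp whatever is still outside
  x <- pmin(pmax(x, lo), hi)
  list(x = x, flipped = flipped)
}

new_swarm <- function(control, d = nrow(control$bounds)) {
  lo <- control$bounds[, 1]; hi <- control$bounds[, 2]
  X <- t(vapply(seq_len(control$pop),
                function(i) stats::runif(d, lo, hi), numeric(d)))
  V <- t(vapply(seq_len(control$pop),
                function(i) stats::runif(d, -control$v_max, control$v_max),
                numeric(d)))
  list(X = X, V = V, pbest_X = X,
       pbest_fit = rep(-Inf, control$pop),
       exemplar = matrix(rep(seq_len(control$pop), d), control$pop, d),
       stagnation = integer(control$pop),
       Pc = learning_probability(seq_len(control$pop), control))
}

#' Assign comprehensive-learning exemplars for one particle
#'
#' For each dimension independently: with probability `Pc_i` a tournament of
#' two random particles drawn from the rest of the swarm is held and the one
#' with the better personal-best fitness becomes the exemplar for that
#' dimension; otherwise the particle learns from its own personal best. If
#' every dimension ended up self-referential, one randomly chosen dimension
#' is forced to a random other particle.
#'
#' @param i Particle index.
#' @param swarm Swarm state as built by [swarm_optimize()] (uses
#'   `pbest_fit`).
#' @param control A [swarm_control()].
#' @return Integer vector of exemplar particle indices, one per dimension.
#' @export
select_exemplar <- function(i, swarm, control) {
  d <- ncol(swarm$X)
  pc <- swarm$Pc[i]
  ex <- integer(d)
  others <- setdiff(seq_len(control$pop), i)
  for (dd in seq_len(d)) {
    if (stats::runif(1) < pc) {
      # tournament of two among the other particles (both of them when
      # only two remain in a pop-2 swarm)
      pair <- if (length(others) >= 2L) sample(others, 2L)
              else c(others, others)
      ex[dd] <- if (swarm$pbest_fit[pair[1]] >= swarm$pbest_fit[pair[2]])
        pair[1] else pair[2]
    } else {
      ex[dd] <- i
    }
  }
  if (all(ex == i)) {
    dd <- if (d == 1L) 1L else sample.int(d, 1L)
    others <- setdiff(seq_len(control$pop), i)
    ex[dd] <- if (length(others) == 1L) others else sample(others, 1L)
  }
  ex
}

#' One velocity/position update of the basic PSO
#'
#' Implements the classic update
#' `V' = V + c1 r1 (pbest - X) + c2 r2 (gbest - X)`, `X' = X + V'`, with
#' fresh uniform `r1, r2` per particle, velocities clamped to `±v_max` and
#' positions reflected back into the bounds. When `pso_inertia` is set in
#' the control, `V` is additionally damped by the inertia schedule at
#' iteration `k`.
#'
#' @param swarm Swarm state (`X`, `V`, `pbest_X`, ...).
#' @param gbest Global best position (numeric vector).
#' @param k Current iteration (used only when `pso_inertia = TRUE`).
#' @param control A [swarm_control()].
#' @param r1,r2 Optional fixed random factors (scalar or per-particle
#'   vector) — intended for verifying single updates against hand
#'   evaluation; `NULL` draws them uniformly.
#' @return The updated swarm state.
#' @export
pso_step <- function(swarm, gbest, k, control, r1 = NULL, r2 = NULL) {
  pop <- nrow(swarm$X); d <- ncol(swarm$X)
  if (is.null(r1)) r1 <- stats::runif(pop)
  if (is.null(r2)) r2 <- stats::runif(pop)
  r1 <- rep_len(r1, pop); r2 <- rep_len(r2, pop)
  w <- if (control$pso_inertia) inertia_weight(min(k, control$max_iter), control) else 1
  G <- matrix(gbest, pop, d, byrow = TRUE)
  V <- w * swarm$V +
    control$c1 * r1 * (swarm$pbest_X - swarm$X) +
    control$c2 * r2 * (G - swarm$X)
  Vmax <- matrix(control$v_max, pop, d, byrow = TRUE)
  V <- pmin(pmax(V, -Vmax), Vmax)
  Xnew <- swarm$X + V
  lo <- matrix(control$bounds[, 1], pop, d, byrow = TRUE)
  hi <- matrix(control$bounds[, 2], pop, d, byrow = TRUE)
  refl <- reflect_into(Xnew, lo, hi)
  V[refl$flipped] <- -V[refl$flipped]
  swarm$X <- matrix(refl$x, pop, d)
  swarm$V <- V
  swarm
}

#' One velocity/position update of comprehensive-learning PSO
#'
#' Per dimension `d`:
#' `V'_d = w(k) V_d + ca r_d (pbest[f_i(d), d] - X_d)`, `X' = X + V'`, with
#' a fresh uniform `r_d` per particle and dimension, exemplar indices
#' `f_i(d)` taken from the swarm state, and the same clamping/reflection as
#' [pso_step()].
#'
#' @param swarm Swarm state including `exemplar` assignments.
#' @param k Current iteration, driving the inertia schedule.
#' @param control A [swarm_control()].
#' @param r Optional fixed random factor matrix (`pop x d`), for verifying
#'   single updates; `NULL` draws fresh uniforms.
#' @return The updated swarm state.
#' @export
clpso_step <- function(swarm, k, control, r = NULL) {
  pop <- nrow(swarm$X); d <- ncol(swarm$X)
  if (is.null(r)) r <- matrix(stats::runif(pop * d), pop, d)
  r <- matrix(rep_len(as.numeric(r), pop * d), pop, d)
  w <- inertia_weight(min(k, control$max_iter), control)
  target <- matrix(NA_real_, pop, d)
  for (dd in seq_len(d))
    target[, dd] <- swarm$pbest_X[swarm$exemplar[, dd], dd]
  V <- w * swarm$V + control$ca * r * (target - swarm$X)
  Vmax <- matrix(control$v_max, pop, d, byrow = TRUE)
  V <- pmin(pmax(V, -Vmax), Vmax)
  Xnew <- swarm$X + V
  lo <- matrix(control$bounds[, 1], pop, d, byrow = TRUE)
  hi <- matrix(control$bounds[, 2], pop, d, byrow = TRUE)
  refl <- reflect_into(Xnew, lo, hi)
  V[refl$flipped] <- -V[refl$flipped]
  swarm$X <- matrix(refl$x, pop, d)
  swarm$V <- V
  swarm
}

eval_fitness <- function(fitness, X) {
  fit <- apply(X, 1L, function(p) {
    v <- tryCatch(fitness(p), error = function(e) NaN)
    if (length(v) != 1L || !is.finite(v)) NaN else as.numeric(v)
  })
  nonfinite <- sum(is.nan(fit))
  fit[is.nan(fit)] <- -Inf
  list(fit = fit, nonfinite = nonfinite)
}

#' Run a particle swarm optimization (maximization)
#'
#' Initializes `pop` particles uniformly in the bounded box, evaluates the
#' fitness, and iterates velocity/position updates for `max_iter`
#' iterations, tracking each particle's personal best and the swarm's global
#' best. `variant = "pso"` uses the classic personal/global-best update;
#' `variant = "clpso"` uses comprehensive learning: each dimension of each
#' particle follows the personal best of an exemplar particle chosen by
#' tournament with the particle's learning probability, exemplars being
#' reassigned after `refresh_gap` stagnant iterations, with a linearly
#' decreasing inertia weight.
#'
#' @param fitness Function mapping a position vector to a scalar score
#'   (maximized). Non-finite returns are scored `-Inf` and counted.
#' @param control A [swarm_control()]; `control$seed` drives all randomness.
#' @param variant `"clpso"` (default) or `"pso"`.
#' @return An object of class `swarm_result`: `best_position`,
#'   `best_fitness`, `trace` (global-best fitness after initialization and
#'   after each iteration, non-decreasing, length `max_iter + 1`),
#'   `trace_position`, `evaluations`, `nonfinite`, `variant`, and the final
#'   swarm state.
#' @examples
#' sphere <- function(p) -sum((p - 0.5)^2)
#' res <- swarm_optimize(sphere, swarm_control(pop = 20, max_iter = 30, seed = 1))
#' res$best_position
#' @export
swarm_optimize <- function(fitness, control = swarm_control(),
                           variant = c("clpso", "pso")) {
  variant <- match.arg(variant)
  with_seed(control$seed, {
    d <- nrow(control$bounds)
    swarm <- new_swarm(control, d)
    ev <- eval_fitness(fitness, swarm$X)
    swarm$pbest_fit <- ev$fit
    swarm$pbest_X <- swarm$X
    nonfinite <- ev$nonfinite
    evaluations <- control$pop
    gi <- which.max(swarm$pbest_fit)
    gbest_fit <- swarm$pbest_fit[gi]
    gbest_pos <- swarm$pbest_X[gi, ]
    if (variant == "clpso")
      for (i in seq_len(control$pop))
        swarm$exemplar[i, ] <- select_exemplar(i, swarm, control)
    trace <- numeric(control$max_iter + 1L)
    trace_pos <- matrix(NA_real_, control$max_iter + 1L, d)
    trace[1] <- gbest_fit
    trace_pos[1, ] <- gbest_pos
    if (control$max_iter > 0L) for (k in seq_len(control$max_iter)) {
      swarm <- if (variant == "pso")
        pso_step(swarm, gbest_pos, k, control)
      else
        clpso_step(swarm, k, control)
      ev <- eval_fitness(fitness, swarm$X)
      evaluations <- evaluations + control$pop
      nonfinite <- nonfinite + ev$nonfinite
      improved <- ev$fit > swarm$pbest_fit
      swarm$pbest_fit[improved] <- ev$fit[improved]
      swarm$pbest_X[improved, ] <- swarm$X[improved, ]
      swarm$stagnation <- ifelse(improved, 0L, swarm$stagnation + 1L)
      gi <- which.max(swarm$pbest_fit)
      if (swarm$pbest_fit[gi] > gbest_fit) {
        gbest_fit <- swarm$pbest_fit[gi]
        gbest_pos <- swarm$pbest_X[gi, ]
      }
      if (variant == "clpso") {
        stale <- which(swarm$stagnation >= control$refresh_gap)
        for (i in stale) {
          swarm$exemplar[i, ] <- select_exemplar(i, swarm, control)
          swarm$stagnation[i] <- 0L
        }
      }
      trace[k + 1L] <- gbest_fit
      trace_pos[k + 1L, ] <- gbest_pos
    }
    structure(list(best_position = gbest_pos, best_fitness = gbest_fit,
                   trace = trace, trace_position = trace_pos,
                   evaluations = evaluations, nonfinite = nonfinite,
                   variant = variant, swarm = swarm, control = control),
              class = "swarm_result")
  })
}

#' @export
print.swarm_result <- function(x, ...) {
  cat("<swarm_result> variant =", x$variant,
      "| best fitness =", format(x$best_fitness), "\n")
  cat("  best position:", paste(format(x$best_position), collapse = ", "), "\n")
  cat("  ", x$evaluations, " fitness evaluations over ",
      length(x$trace) - 1L, " iterations\n", sep = "")
  if (x$nonfinite > 0)
    cat("  (", x$nonfinite, " non-finite fitness values scored as -Inf)\n", sep = "")
  invisible(x)
}

#' @export
plot.swarm_result <- function(x, ...) {
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "s",
                 xlab = "iteration", ylab = "global best fitness",
                 main = paste0(toupper(x$variant), " convergence"), ...)
  invisible(x)
}

#' Write a swarm convergence trace as CSV
#'
#' One row per iteration: the global-best fitness and position. When the
#' optimizer ran on the log10 scale of `(c, g)` (as [tune_svm()] does), set
#' `log10_cg = TRUE` to emit the back-transformed `best_c`, `best_g`.
#'
#' @param result A `swarm_result`.
#' @param path Output CSV path.
#' @param log10_cg Interpret the two position dimensions as `log10(c)`,
#'   `log10(g)` (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path, log10_cg = TRUE) {
  pos <- result$trace_position
  df <- data.frame(iteration = seq_along(result$trace) - 1L,
                   gbest_fitness = result$trace)
  if (log10_cg && ncol(pos) == 2L) {
    df$best_c <- 10^pos[, 1]
    df$best_g <- 10^pos[, 2]
  } else {
    for (j in seq_len(ncol(pos))) df[[paste0("x", j)]] <- pos[, j]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tune SVM hyperparameters (c, g) with a particle swarm
#'
#' Runs [swarm_optimize()] over the log10-scaled `(c, g)` box, scoring each
#' position by the accuracy of a one-vs-rest RBF-SVM on the training
#' features. The default fitness is stratified k-fold cross-validation
#' accuracy within the training set; `fitness = "train"` scores plain
#' training accuracy (resubstitution) instead.
#'
#' @param x Training feature matrix (typically PCA scores).
#' @param labels Integer class labels `1..L`, all classes present.
#' @param control A [swarm_control()]; its `bounds` are interpreted on the
#'   log10 scale of `(c, g)`.
#' @param variant `"clpso"` (default) or `"pso"`.
#' @param fitness `"cv"` (default) or `"train"`.
#' @param cv_folds Folds for the cross-validated fitness (default 5; capped
#'   at the smallest class count).
#' @return A list of class `svm_tuning`: `params` (the best [svm_params()]),
#'   `result` (the `swarm_result`), `fitness`, `variant`.
#' @export
tune_svm <- function(x, labels, control = swarm_control(),
                     variant = c("clpso", "pso"),
                     fitness = c("cv", "train"), cv_folds = 5L) {
  variant <- match.arg(variant)
  fitness <- match.arg(fitness)
  x <- as.matrix(x)
  labels <- as.integer(labels)
  with_seed(control$seed, {
    fit_fun <- if (fitness == "train") {
      function(pos) {
        par <- svm_params(10^pos[1], 10^pos[2])
        m <- train_ovr(x, labels, par)
        accuracy(predict_labels(m, x), labels)
      }
    } else {
      nf <- min(as.integer(cv_folds), min(table(labels)))
      if (nf < 2L) stop("cross-validated fitness needs >= 2 samples per class",
                        call. = FALSE)
      fold <- stratified_assignment(labels, nf)
      function(pos) {
        par <- svm_params(10^pos[1], 10^pos[2])
        acc <- vapply(seq_len(nf), function(f) {
          tr <- fold != f
          m <- train_ovr(x[tr, , drop = FALSE], labels[tr], par)
          accuracy(predict_labels(m, x[!tr, , drop = FALSE]), labels[!tr])
        }, 0)
        mean(acc)
      }
    }
    inner <- control
    inner$seed <- NULL  # inherit this run's seeded stream
    res <- swarm_optimize(fit_fun, inner, variant = variant)
    structure(list(params = svm_params(10^res$best_position[1],
                                       10^res$best_position[2]),
                   result = res, fitness = fitness, variant = variant),
              class = "svm_tuning")
  })
}

#' @export
print.svm_tuning <- function(x, ...) {
  cat("<svm_tuning> variant =", x$variant, "| fitness =", x$fitness, "\n")
  cat("  best c =", format(x$params$c), " g =", format(x$params$g),
      " (fitness ", format(x$result$best_fitness), ")\n")
  invisible(x)
}

# stratified assignment of samples to nf folds, balanced within class
stratified_assignment <- function(labels, nf) {
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- which(labels == l)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(nf), length(idx))
  }
  fold
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
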