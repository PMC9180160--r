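test_that("the inertia weight decreases linearly between its endpoints", {
  ctrl <- swarm_control(max_iter = 40)
  expect_equal(inertia_weight(0, ctrl), 0.9)
  expect_equal(inertia_weight(40, ctrl), 0.4)
  expect_equal(inertia_weight(20, ctrl), 0.65)
  ks <- 0:40
  ws <- vapply(ks, inertia_weight, 0, control = ctrl)
  expect_true(all(diff(ws) < 0))
  expect_true(all(ws >= 0.4 - 1e-12 & ws <= 0.9 + 1e-12))
  expect_error(inertia_weight(-1, ctrl), "0..max_iter")
  expect_error(inertia_weight(41, ctrl), "0..max_iter")
})

test_that("the learning probability follows its exponential ramp", {
  ctrl <- swarm_control(pop = 40)
  expect_equal(learning_probability(1, ctrl), 0)
  expect_equal(learning_probability(40, ctrl), 0.5)
  # frozen high-precision evaluation of the ramp at i = 20, pop = 40
  expect_equal(learning_probability(20, ctrl), 0.0029410282961941,
               tolerance = 1e-12)
  pcs <- learning_probability(1:40, ctrl)
  expect_true(all(diff(pcs) > 0))
  expect_true(all(pcs >= 0 & pcs <= 0.5))
  expect_error(learning_probability(0, ctrl), "out of")
  expect_error(learning_probability(41, ctrl), "out of")
})

test_that("swarm_control validates its invariants", {
  expect_error(swarm_control(pop = 1), "pop")
  expect_error(swarm_control(max_iter = -1), "max_iter")
  expect_error(swarm_control(bounds = cbind(1, 0)), "bounds")
  expect_error(swarm_control(a_prob = 0.6, b_prob = 0.6), "a_prob")
  expect_error(swarm_control(w_max = 0.3, w_min = 0.4), "w_min")
  ctrl <- swarm_control(bounds = cbind(c(0, -1), c(10, 1)))
  expect_equal(ctrl$v_max, c(2, 0.4))
})

test_that("a single PSO update matches hand evaluation of the velocity rule", {
  ctrl <- swarm_control(pop = 2, max_iter = 5,
                        bounds = cbind(-100, 100), v_max = 50)
  swarm <- list(X = matrix(c(0, 0), 2, 1), V = matrix(c(1, 0), 2, 1),
                pbest_X = matrix(c(2, 0), 2, 1), pbest_fit = c(0, 0))
  out <- pso_step(swarm, gbest = 3, k = 0, ctrl, r1 = c(0.5, 0), r2 = c(0.5, 0))
  # V' = 1 + 1.49445*0.5*(2-0) + 1.49445*0.5*(3-0) = 4.736125; X' = V'
  expect_equal(out$V[1, 1], 4.736125, tolerance = 1e-12)
  expect_equal(out$X[1, 1], 4.736125, tolerance = 1e-12)

  # fixed point: X = pbest = gbest, V = 0
  fixed <- list(X = matrix(5, 2, 1), V = matrix(0, 2, 1),
                pbest_X = matrix(5, 2, 1), pbest_fit = c(0, 0))
  outf <- pso_step(fixed, gbest = 5, k = 0, ctrl, r1 = 0.7, r2 = 0.2)
  expect_equal(outf$X, fixed$X)
  expect_equal(outf$V, fixed$V)

  # r1 = r2 = 0: pure drift X' = X + V
  drift <- pso_step(swarm, gbest = 3, k = 0, ctrl, r1 = 0, r2 = 0)
  expect_equal(drift$X[1, 1], 1)
})

test_that("a single CLPSO update matches hand evaluation", {
  ctrl <- swarm_control(pop = 2, max_iter = 5, w_max = 0.9, w_min = 0.4,
                        bounds = cbind(-100, 100), v_max = 50)
  swarm <- list(X = matrix(c(0, 0), 2, 1), V = matrix(c(1, 0), 2, 1),
                pbest_X = matrix(c(2, 0), 2, 1), pbest_fit = c(1, 0),
                exemplar = matrix(1L, 2, 1))
  # k = 0 so the inertia weight is exactly w_max = 0.9
  out <- clpso_step(swarm, k = 0, ctrl, r = matrix(c(0.5, 0), 2, 1))
  # V' = 0.9*1 + 1.49445*0.5*(2-0) = 2.39445; X' = V'
  expect_equal(out$V[1, 1], 2.39445, tolerance = 1e-12)
  expect_equal(out$X[1, 1], 2.39445, tolerance = 1e-12)

  # all exemplar pbests equal X, V = 0: stationary
  fixed <- list(X = matrix(3, 2, 1), V = matrix(0, 2, 1),
                pbest_X = matrix(3, 2, 1), pbest_fit = c(0, 0),
                exemplar = matrix(c(2L, 1L), 2, 1))
  outf <- clpso_step(fixed, k = 0, ctrl, r = matrix(0.8, 2, 1))
  expect_equal(outf$X, fixed$X)

  # w = 0 erases velocity memory: update driven by the exemplar term only
  ctrl0 <- swarm_control(pop = 2, max_iter = 5, w_max = 0, w_min = 0,
                         bounds = cbind(-100, 100), v_max = 50)
  out0 <- clpso_step(swarm, k = 0, ctrl0, r = matrix(c(0.5, 0), 2, 1))
  expect_equal(out0$V[1, 1], 1.49445 * 0.5 * 2, tolerance = 1e-12)
})

test_that("exemplar selection follows the learning probability and forcing rule", {
  ctrl <- swarm_control(pop = 6, max_iter = 5, bounds = cbind(c(-1, -1), c(1, 1)))
  swarm <- list(X = matrix(0, 6, 2), pbest_fit = c(5, 3, 8, 1, 9, 2),
                Pc = rep(0, 6))
  # Pc = 0: all dimensions self, except one forced to another particle
  set.seed(1)
  for (rep in 1:20) {
    ex <- select_exemplar(2, swarm, ctrl)
    expect_equal(sum(ex != 2L), 1L)
    expect_true(all(ex[ex != 2L] %in% setdiff(1:6, 2)))
  }
  # Pc = 1: every exemplar is a tournament winner, never the worse of its pair
  swarm$Pc <- rep(1, 6)
  set.seed(2)
  worst <- which.min(swarm$pbest_fit)
  picks <- replicate(200, select_exemplar(1, swarm, ctrl))
  expect_false(any(picks == worst))   # fitness 1 can never win a tournament
  # pop = 2: tournaments always compare the only two particles
  ctrl2 <- swarm_control(pop = 2, max_iter = 5, bounds = cbind(c(-1, -1), c(1, 1)))
  sw2 <- list(X = matrix(0, 2, 2), pbest_fit = c(1, 7), Pc = c(1, 1))
  set.seed(3)
  expect_true(all(replicate(50, select_exemplar(1, sw2, ctrl2)) == 2L))
})

test_that("swarm runs keep positions in bounds with a monotone gbest trace", {
  for (variant in c("pso", "clpso")) {
    res <- swarm_optimize(sphere_fitness(), quick_control(seed = 7),
                          variant = variant)
    expect_true(all(diff(res$trace) >= 0))
    expect_equal(res$best_fitness, res$trace[length(res$trace)])
    lo <- res$control$bounds[, 1]; hi <- res$control$bounds[, 2]
    expect_true(all(t(res$swarm$X) >= lo - 1e-12))
    expect_true(all(t(res$swarm$X) <= hi + 1e-12))
  }
})

test_that("swarm bookkeeping: evaluations, trace length, degenerate fitness", {
  ctrl <- quick_control(seed = 2)
  ctrl$max_iter <- 1L
  res <- swarm_optimize(sphere_fitness(), ctrl, "clpso")
  expect_equal(res$evaluations, 2L * ctrl$pop)
  expect_length(res$trace, 2L)

  # constant fitness: flat trace at the initial best
  resc <- swarm_optimize(function(p) 1, quick_control(seed = 3), "pso")
  expect_true(all(resc$trace == 1))

  # non-finite fitness values are scored -Inf and counted
  bad <- function(p) if (p[1] > 0) NaN else -sum(p^2)
  resb <- swarm_optimize(bad, quick_control(seed = 4), "clpso")
  expect_gt(resb$nonfinite, 0)
  expect_true(is.finite(resb$best_fitness))

  # same seed, same result
  r1 <- swarm_optimize(sphere_fitness(), quick_control(seed = 11), "clpso")
  r2 <- swarm_optimize(sphere_fitness(), quick_control(seed = 11), "clpso")
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
})

test_that("CLPSO closes in on the sphere optimum", {
  hits <- vapply(1:5, function(s) {
    res <- swarm_optimize(sphere_fitness(c(0.3, -0.2)),
                          swarm_control(pop = 40, max_iter = 40,
                                        bounds = cbind(c(-5, -5), c(5, 5)),
                                        seed = s),
                          "clpso")
    res$best_fitness > -1e-2
  }, TRUE)
  expect_true(all(hits))
})

test_that("tune_svm finds separable parameters and is seed-deterministic", {
  f <- generate_separable_features(6, 8, 2, separation = 20, seed = 31)
  ctrl <- swarm_control(pop = 8, max_iter = 5, seed = 9)
  tuned <- tune_svm(f$x, f$labels, ctrl, variant = "clpso",
                    fitness = "train")
  expect_equal(tuned$result$best_fitness, 1)
  expect_gt(tuned$params$c, 0)
  expect_gt(tuned$params$g, 0)
  tuned2 <- tune_svm(f$x, f$labels, ctrl, variant = "clpso",
                     fitness = "train")
  expect_identical(tuned$params, tuned2$params)
  expect_identical(tuned$result$trace, tuned2$result$trace)

  # max_iter = 0: best of the random initialization only
  ctrl0 <- swarm_control(pop = 6, max_iter = 0, seed = 10)
  t0 <- tune_svm(f$x, f$labels, ctrl0, variant = "pso", fitness = "train")
  expect_length(t0$result$trace, 1L)
  expect_equal(t0$result$evaluations, 6L)

  # cross-validated fitness runs and stays within [0, 1]
  tcv <- tune_svm(f$x, f$labels, swarm_control(pop = 6, max_iter = 2, seed = 1),
                  variant = "clpso", fitness = "cv", cv_folds = 4)
  expect_gte(tcv$result$best_fitness, 0)
  expect_lte(tcv$result$best_fitness, 1)
})

test_that("convergence traces export as CSV with back-transformed (c, g)", {
  res <- swarm_optimize(sphere_fitness(), quick_control(seed = 5), "clpso")
  # interpret positions as log10(c), log10(g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, path, log10_cg = TRUE)
  df <- utils::read.csv(path)
  expect_named(df, c("iteration", "gbest_fitness", "best_c", "best_g"))
  expect_equal(nrow(df), length(res$trace))
  expect_equal(df$best_c, 10^res$trace_position[, 1])
})
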