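# shared fixtures built in code

# a small smooth absorbance set on a descending grid
tiny_absorbance_set <- function(n = 3, p = 40, seed = 42) {
  set.seed(seed)
  wn <- seq(10000, 4000, length.out = p)
  vals <- t(vapply(seq_len(n), function(i)
    0.2 + 0.1 * i * exp(-(wn - 8000)^2 / (2 * 500^2)) + runif(p, 0, 0.01),
    numeric(p)))
  spectra_set(vals, wn, "absorbance",
              sample_id = paste0("t", seq_len(n)),
              label = seq_len(n))
}

# benchmark objectives (maximization form)
sphere_fitness <- function(opt = c(0.3, -0.2)) {
  function(p) -sum((p - opt)^2)
}
rastrigin_fitness <- function() {
  # global maximum 0 at the origin
  function(p) -(10 * length(p) + sum(p^2 - 10 * cos(2 * pi * p)))
}

# small swarm control for quick deterministic runs
quick_control <- function(...) {
  swarm_control(pop = 10L, max_iter = 15L,
                bounds = cbind(c(-5, -5), c(5, 5)), ...)
}

# reduced-budget evaluation control for protocol tests (paper-scale swarms
# are supported but not needed to exercise the code paths)
quick_eval_control <- function(seed = 1L, ...) {
  eval_control(seed = seed,
               swarm = swarm_control(pop = 8L, max_iter = 6L),
               cv_folds = 3L, ...)
}
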