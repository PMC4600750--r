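# shared fixture builders: random emission mixtures, submodels and parameter
# sets for the inference tests (all callers set their own seed)

rand_mix <- function() {
  xshadow:::new_tmixture(c(0.2, 0.6, 0.2), c(-2, 0, 2) + rnorm(3, 0, 0.3),
                         runif(3, 0.5, 1.5), runif(3, 3, 30))
}

rand_sub <- function(M, N, miss_p = 0.1) {
  y <- matrix(rnorm(M * N, 0, 2), M, N)
  y[runif(M * N) < miss_p] <- NA
  rownames(y) <- paste0("p", seq_len(M))
  colnames(y) <- paste0("n", seq_len(N))
  xshadow:::build_submodel("g", y, runif(N),
                           replicate(N, rand_mix(), simplify = FALSE),
                           H = sample(c("up", "down"), N, replace = TRUE))
}

rand_params <- function() {
  f0 <- runif(1, 0.01, 0.4)
  f1 <- runif(1, f0, 0.95)
  simplex <- function() { v <- runif(3, 0.1, 1); v / sum(v) }
  structure(list(theta_D = runif(1, 0.1, 0.9), theta_F1_D1 = f1,
                 theta_F1_D0 = f0, theta_G_F0 = simplex(),
                 theta_G_F1_up = simplex(), theta_G_F1_down = simplex()),
            class = "xshadow_params")
}

rand_dataset <- function(n_genes = 8) {
  lapply(seq_len(n_genes), function(g) {
    rand_sub(sample(2:5, 1), sample(1:4, 1))
  })
}

# small simulated cohort + fit, reused by the method tests
small_sim_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      h <- sim_hyperparams(n_genes = 12, M = 10, N = 4, n_patients = 60,
                           delta = 3)
      sim <- simulate_xshadow_data(h, seed = 99)
      fit <- suppressMessages(
        xshadow(sim$mutations, sim$expression, graph = sim$graph,
                mode = "trans",
                config = xshadow_config(condition_graph = FALSE)))
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})
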