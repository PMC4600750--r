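test_that("D is d-separated from expression when F ignores it", {
  set.seed(21)
  sub <- rand_sub(3, 2, miss_p = 0)
  p <- rand_params()
  p$theta_F1_D1 <- p$theta_F1_D0 <- 0.3
  expect_equal(infer_posteriors(sub, p)$p_d, p$theta_D, tolerance = 1e-12)
})

test_that("uninformative emissions propagate the prior into P(F)", {
  ## all three component densities equal at every y: loc/scale/df identical
  mix <- xshadow:::new_tmixture(c(0.3, 0.4, 0.3), rep(0, 3), rep(1, 3),
                                rep(8, 3))
  y <- matrix(rnorm(6), 3, 2,
              dimnames = list(paste0("p", 1:3), c("n1", "n2")))
  sub <- xshadow:::build_submodel("g", y, c(0.7, 0.4), list(mix, mix),
                                  H = c("up", "down"))
  set.seed(22)
  p <- rand_params()
  prior_f <- p$theta_D * p$theta_F1_D1 + (1 - p$theta_D) * p$theta_F1_D0
  expect_equal(infer_posteriors(sub, p)$p_f, rep(prior_f, 3),
               tolerance = 1e-10)
})

test_that("single-leaf posterior matches the hand-computed 2x3 table", {
  mix <- xshadow:::new_tmixture(c(0.2, 0.6, 0.2), c(-2, 0, 2), rep(1, 3),
                                rep(10, 3))
  y <- matrix(1.5, 1, 1, dimnames = list("p1", "n1"))
  sub <- xshadow:::build_submodel("g", y, 0.8, list(mix), H = "up")
  p <- xshadow_params(theta_D = 0.4, theta_F1_D1 = 0.7, theta_F1_D0 = 0.2,
                      theta_G_F0 = c(0.1, 0.8, 0.1),
                      theta_G_F1_up = c(0.05, 0.35, 0.6))
  ## hand computation: densities of the three components at y
  dens <- sapply(1:3, function(k) exp(t_log_density(1.5, c(-2, 0, 2)[k], 1, 10)))
  cpd1 <- 0.8 * c(0.05, 0.35, 0.6) + 0.2 * c(0.1, 0.8, 0.1)
  L0 <- sum(c(0.1, 0.8, 0.1) * dens)
  L1 <- sum(cpd1 * dens)
  pf1 <- 0.4 * 0.7 * L1 + 0.6 * 0.2 * L1
  pf0 <- 0.4 * 0.3 * L0 + 0.6 * 0.8 * L0
  inf <- infer_posteriors(sub, p)
  expect_equal(inf$p_f, pf1 / (pf1 + pf0), tolerance = 1e-12)
  expect_equal(inf$p_d,
               (0.4 * 0.7 * L1 + 0.4 * 0.3 * L0) / (pf1 + pf0),
               tolerance = 1e-12)
})

test_that("belief propagation equals exhaustive enumeration on random submodels", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    sub <- rand_sub(sample(1:3, 1), sample(1:3, 1))
    p <- rand_params()
    a <- suppressWarnings(infer_posteriors(sub, p))
    b <- suppressWarnings(enumerate_posteriors(sub, p))
    worst <- max(worst, abs(a$p_d - b$p_d), max(abs(a$p_f - b$p_f)),
                 max(abs(a$p_g - b$p_g)), abs(a$logZ - b$logZ))
  }
  expect_lt(worst, 1e-8)
})

test_that("enumeration refuses oversized submodels", {
  set.seed(23)
  sub <- rand_sub(4, 4)
  expect_error(enumerate_posteriors(sub, rand_params()),
               class = "xshadow_guard_error")
})

test_that("deterministic emissions force the regulation posterior", {
  mix <- xshadow:::new_tmixture(c(1 / 3, 1 / 3, 1 / 3), c(-50, 0, 50),
                                rep(0.5, 3), rep(20, 3))
  y <- matrix(50, 1, 1, dimnames = list("p1", "n1"))
  sub <- xshadow:::build_submodel("g", y, 1, list(mix), H = "up")
  set.seed(24)
  inf <- infer_posteriors(sub, rand_params())
  expect_gt(inf$p_g[1, 1, 3], 0.999)
})

test_that("all-missing submodels return prior marginals with a warning", {
  set.seed(25)
  sub <- rand_sub(2, 2, miss_p = 0)
  sub$miss[] <- TRUE
  sub$ldens[] <- 0
  p <- rand_params()
  expect_warning(inf <- infer_posteriors(sub, p), "prior")
  expect_equal(inf$p_d, p$theta_D)
})

test_that("probabilities are normalised and inside the unit interval", {
  set.seed(26)
  for (i in 1:20) {
    sub <- rand_sub(sample(1:4, 1), sample(1:4, 1))
    inf <- suppressWarnings(infer_posteriors(sub, rand_params()))
    expect_true(all(inf$p_f >= 0 & inf$p_f <= 1))
    expect_true(inf$p_d >= 0 && inf$p_d <= 1)
    sums <- apply(inf$p_g, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
  }
})

test_that("EM objective is monotone and submodel order does not matter", {
  set.seed(27)
  subs <- rand_dataset(8)
  em <- em_fit(subs, max_iter = 30)
  expect_true(all(diff(em$objective) >= -1e-8))
  em_perm <- em_fit(subs[sample(length(subs))], max_iter = 30)
  expect_equal(unclass(em$params), unclass(em_perm$params), tolerance = 1e-10)
})

test_that("starting EM at the generative parameters barely moves them", {
  set.seed(28)
  truth <- xshadow_params(theta_D = 0.5, theta_F1_D1 = 0.85,
                          theta_F1_D0 = 0.1,
                          theta_G_F0 = c(0.05, 0.9, 0.05),
                          theta_G_F1_up = c(0.05, 0.45, 0.5))
  ## simulate directly from the model with known emissions and directions
  mix <- xshadow:::new_tmixture(c(0.1, 0.8, 0.1), c(-3, 0, 3), rep(1, 3),
                                rep(15, 3))
  subs <- lapply(1:150, function(g) {
    M <- 20; N <- 8
    d <- rbinom(1, 1, truth$theta_D)
    f <- rbinom(M, 1, if (d == 1) truth$theta_F1_D1 else truth$theta_F1_D0)
    H <- sample(c("up", "down"), N, TRUE)
    y <- matrix(0, M, N, dimnames = list(paste0("p", 1:M), paste0("n", 1:N)))
    for (n in 1:N) {
      tab1 <- if (H[n] == "up") truth$theta_G_F1_up else rev(truth$theta_G_F1_up)
      g_st <- ifelse(f == 1,
                     sample(1:3, M, TRUE, tab1),
                     sample(1:3, M, TRUE, truth$theta_G_F0))
      y[, n] <- rt(M, 15) + c(-3, 0, 3)[g_st]
    }
    xshadow:::build_submodel(paste0("g", g), y, rep(1, N),
                             replicate(N, mix, simplify = FALSE), H = H)
  })
  em1 <- em_fit(subs, init = truth, max_iter = 1, pseudo = 0.5)
  expect_lt(abs(em1$params$theta_F1_D1 - truth$theta_F1_D1), 0.02)
  expect_lt(abs(em1$params$theta_F1_D0 - truth$theta_F1_D0), 0.02)
  expect_lt(abs(em1$params$theta_D - truth$theta_D), 0.05)
  expect_lt(max(abs(em1$params$theta_G_F0 - truth$theta_G_F0)), 0.02)
})

test_that("mutation posteriors are calibrated under the generative model", {
  h <- sim_hyperparams(n_genes = 100, M = 20, N = 8, n_patients = 150,
                       delta = 2)
  sim <- simulate_xshadow_data(h, seed = 29)
  fit <- suppressMessages(
    xshadow(sim$mutations, sim$expression, graph = sim$graph, mode = "trans",
            config = xshadow_config(condition_graph = FALSE)))
  m <- fit$mutations
  expect_gte(nrow(m), 2000)
  key <- paste(m$gene, m$patient)
  f_true <- sim$truth$F$f[match(key, paste(sim$truth$F$gene,
                                           sim$truth$F$patient))]
  bin <- m$p_f >= 0.8
  expect_gte(mean(f_true[bin]), 0.7)
})
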