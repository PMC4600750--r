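test_that("edge weights mix the dysregulated and null regulation tables", {
  p <- xshadow_params(theta_G_F0 = c(0.05, 0.9, 0.05),
                      theta_G_F1_up = c(0.05, 0.45, 0.5))
  ## w = 1: dysregulated table exactly
  expect_equal(effective_G_cpd(p, 1, "up")$F1, p$theta_G_F1_up)
  ## w = 0: neighbour uninformative
  expect_equal(effective_G_cpd(p, 0, "up")$F1, p$theta_G_F0)
  ## w = 0.5 hand value
  expect_equal(effective_G_cpd(p, 0.5, "up")$F1, c(0.05, 0.675, 0.275))
  expect_error(effective_G_cpd(p, 1.2, "up"), class = "xshadow_domain_error")
})

test_that("effective tables are simplexes across the weight grid", {
  set.seed(11)
  p <- rand_params()
  for (w in seq(0, 1, length.out = 101)) {
    for (H in c("up", "down")) {
      tab <- effective_G_cpd(p, w, H)
      expect_equal(sum(tab$F1), 1, tolerance = 1e-12)
      expect_true(all(tab$F1 >= 0))
    }
  }
})

test_that("joint log-probability reduces to emissions under deterministic tables", {
  set.seed(12)
  sub <- rand_sub(2, 2, miss_p = 0)
  sub$H <- c("up", "up")
  sub$Hm[] <- "up"
  sub$w <- c(1, 1)
  p <- xshadow_params(theta_D = 0.5, theta_F1_D1 = 1 - 1e-12,
                      theta_F1_D0 = 1e-12,
                      theta_G_F1_up = c(1e-12, 1e-12, 1))
  p$theta_G_F1_up <- p$theta_G_F1_up / sum(p$theta_G_F1_up)
  g <- matrix(3L, 2, 2)  # all 'up'
  lp <- joint_log_prob(sub, p, d = 1, f = c(1, 1), g_states = g)
  expected <- log(0.5) + sum(sub$ldens[, , 3])
  expect_equal(lp, expected, tolerance = 1e-9)
})

test_that("exponentiated joint sums to the marginal likelihood", {
  set.seed(13)
  sub <- rand_sub(2, 2, miss_p = 0)
  p <- rand_params()
  tot <- -Inf
  grid <- as.matrix(expand.grid(rep(list(1:3), 4)))
  for (d in 0:1) for (f1 in 0:1) for (f2 in 0:1)
    for (r in seq_len(nrow(grid)))
      tot <- xshadow:::logaddexp(tot,
        joint_log_prob(sub, p, d, c(f1, f2), matrix(grid[r, ], 2, 2)))
  expect_equal(tot, infer_posteriors(sub, p)$logZ, tolerance = 1e-8)
})

test_that("joint is additive over patients given fixed d", {
  set.seed(14)
  sub1 <- rand_sub(1, 2, miss_p = 0)
  ## duplicate the patient: M = 2 with identical rows
  y2 <- rbind(sub1$y, sub1$y)
  rownames(y2) <- c("p1", "p2")
  mixes <- replicate(2, rand_mix(), simplify = FALSE)
  ## rebuild both so they share mixtures
  a <- xshadow:::build_submodel("g", sub1$y, sub1$w, mixes, H = sub1$H)
  b <- xshadow:::build_submodel("g", y2, sub1$w, mixes, H = sub1$H)
  p <- rand_params()
  g1 <- matrix(c(1L, 3L), 1, 2)
  lp1 <- joint_log_prob(a, p, 1, 1, g1)
  lp2 <- joint_log_prob(b, p, 1, c(1, 1), rbind(g1, g1))
  ## removing the shared P(D) term, the duplicated joint is twice the single
  expect_equal(lp2 - log(p$theta_D), 2 * (lp1 - log(p$theta_D)),
               tolerance = 1e-9)
})

test_that("invalid latent assignments are rejected", {
  set.seed(15)
  sub <- rand_sub(2, 2)
  p <- rand_params()
  expect_error(joint_log_prob(sub, p, 2, c(0, 0), matrix(1L, 2, 2)),
               class = "xshadow_domain_error")
  expect_error(joint_log_prob(sub, p, 1, c(0, 0), matrix(4L, 2, 2)),
               class = "xshadow_domain_error")
  expect_error(joint_log_prob(sub, p, 1, 0, matrix(1L, 2, 2)),
               class = "xshadow_domain_error")
})

test_that("direction estimation follows the dominant responsibility with up ties", {
  ## dominance: responsibilities strongly favour 'up'
  mixes <- list(xshadow:::new_tmixture(c(0.2, 0.6, 0.2), c(-3, 0, 3),
                                       rep(0.5, 3), rep(10, 3)))
  y <- matrix(rep(3, 5), 5, 1, dimnames = list(paste0("p", 1:5), "n1"))
  sub <- xshadow:::build_submodel("g", y, 1, mixes)
  expect_equal(unname(sub$H), "up")
  y2 <- matrix(rep(-3, 5), 5, 1, dimnames = list(paste0("p", 1:5), "n1"))
  expect_equal(unname(xshadow:::build_submodel("g", y2, 1, mixes)$H), "down")
  ## exact tie (y at the symmetric centre) resolves to up
  y3 <- matrix(0, 4, 1, dimnames = list(paste0("p", 1:4), "n1"))
  expect_equal(unname(xshadow:::build_submodel("g", y3, 1, mixes)$H), "up")
})

test_that("true directions are recovered from strongly dysregulated data", {
  set.seed(16)
  h <- sim_hyperparams(n_genes = 15, M = 30, N = 10, n_patients = 120,
                       delta = 3)
  sim <- simulate_xshadow_data(h, seed = 16)
  fit <- suppressMessages(
    xshadow(sim$mutations, sim$expression, graph = sim$graph, mode = "trans",
            config = xshadow_config(condition_graph = FALSE)))
  ## directions are only expressed in the data for genes whose mutations
  ## truly impact expression; restrict the check to those
  d1 <- names(sim$truth$D)[sim$truth$D == 1]
  dirs <- fit$directions[fit$directions$gene %in% d1, ]
  key <- paste(dirs$gene, dirs$neighbour)
  truth <- sim$truth$H
  ht <- truth$h[match(key, paste(truth$gene, truth$neighbour))]
  expect_gte(mean(dirs$h == ht), 0.9)
})
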