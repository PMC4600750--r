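test_that("t log-density matches quadrature normalisation and symmetry", {
  ## density integrates to 1 (independent numerical-integration check)
  f <- function(y) exp(t_log_density(y, loc = 0, scale = 1, df = 3))
  expect_equal(integrate(f, -Inf, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  ## value at y = 2 agrees with the quadrature-normalised curve via stats::dt
  expect_equal(t_log_density(2, 0, 1, 3), dt(2, df = 3, log = TRUE),
               tolerance = 1e-12)
  ## symmetry about the location
  d <- runif(20, 0, 5)
  expect_equal(t_log_density(1.3 + d, 1.3, 0.7, 5),
               t_log_density(1.3 - d, 1.3, 0.7, 5))
  ## scale/df domain errors
  expect_error(t_log_density(0, 0, -1, 3), class = "xshadow_domain_error")
  expect_error(t_log_density(0, 0, 1, 0), class = "xshadow_domain_error")
})

test_that("large df approaches the Gaussian log-density", {
  ## the exact t log-density at df = 1e6 deviates from the Gaussian by
  ## ~y^4/(4 df) in absolute terms, so the absolute check holds in the bulk
  ## and the far tails agree to 1e-4 relative
  y <- seq(-4, 4, by = 0.05)
  expect_lt(max(abs(t_log_density(y, 0, 1, 1e6) - dnorm(y, log = TRUE))), 1e-4)
  y2 <- seq(-10, 10, by = 0.05)
  expect_equal(t_log_density(y2, 0, 1, 1e6), dnorm(y2, log = TRUE),
               tolerance = 1e-4)
  expect_equal(t_log_density(y2, 1.5, 2, 1e6), dnorm(y2, 1.5, 2, log = TRUE),
               tolerance = 1e-4)
})

test_that("a single-population gene is fitted as dominantly neutral", {
  ok <- 0
  for (s in 1:5) {
    set.seed(s)
    m <- fit_t_mixture(rnorm(1000))
    if (m$weight["neutral"] >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 3)  # majority of seeds
})

test_that("well-separated three-component structure is recovered", {
  set.seed(2)
  comp <- sample(1:3, 5000, TRUE, c(0.2, 0.6, 0.2))
  y <- rt(5000, 5) + c(-3, 0, 3)[comp]
  m <- fit_t_mixture(y)
  expect_lt(max(abs(m$loc - c(-3, 0, 3))), 0.2)
  tr <- attr(m, "objective_trace")
  expect_true(all(diff(tr) >= -1e-8))
})

test_that("degenerate and undersized inputs are handled", {
  expect_error(fit_t_mixture(rep(2, 100)),
               class = "xshadow_degenerate_data_error")
  expect_warning(m <- fit_t_mixture(rnorm(10)), "fewer than 30")
  expect_equal(unname(m$weight), c(0, 1, 0))
  expect_true(m$degenerate)
})

test_that("compiled and reference EM kernels agree", {
  set.seed(4)
  y <- rt(300, 6) + sample(c(-2, 0, 2), 300, TRUE, c(0.15, 0.7, 0.15))
  a <- fit_t_mixture(y, engine = "cpp")
  b <- fit_t_mixture(y, engine = "r")
  expect_equal(a$loc, b$loc, tolerance = 0.05)
  expect_equal(a$weight, b$weight, tolerance = 0.02)
  expect_equal(a$loglik, b$loglik, tolerance = 0.05)
})

test_that("label order of the starting point does not change the fit", {
  set.seed(6)
  y <- rt(400, 8) + sample(c(-2, 0, 2), 400, TRUE, c(0.2, 0.6, 0.2))
  init <- list(weight = c(0.2, 0.6, 0.2), loc = c(-1.5, 0, 1.5),
               scale = c(1, 1, 1), df = c(10, 10, 10))
  perm <- c(3, 1, 2)
  init_p <- lapply(init, `[`, perm)
  a <- fit_t_mixture(y, init = init)
  b <- fit_t_mixture(y, init = init_p)
  a_ml <- fit_t_mixture(y, init = init, shared_dispersion = FALSE,
                        weight_prior = c(1, 1, 1))
  b_ml <- fit_t_mixture(y, init = init_p, shared_dispersion = FALSE,
                        weight_prior = c(1, 1, 1))
  for (fld in c("weight", "loc", "scale", "df"))
    expect_equal(a_ml[[fld]], b_ml[[fld]], tolerance = 1e-6)
  for (fld in c("weight", "loc", "scale", "df"))
    expect_equal(a[[fld]], b[[fld]], tolerance = 1e-6)
})

test_that("mixture responsibilities normalise and match brute force", {
  set.seed(8)
  for (i in 1:1000) {
    mix <- rand_mix()
    y <- rnorm(1, 0, 4)
    p <- tmix_posterior(mix, y)
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  ## direct recomputation on a batch
  mix <- rand_mix()
  y <- rnorm(50, 0, 4)
  p <- tmix_posterior(mix, y)
  raw <- sapply(1:3, function(k)
    mix$weight[k] * exp(t_log_density(y, mix$loc[k], mix$scale[k], mix$df[k])))
  expect_equal(unname(p), unname(raw / rowSums(raw)), tolerance = 1e-10)
})

test_that("responsibilities have the expected modes and tails", {
  mix <- xshadow:::new_tmixture(rep(1 / 3, 3), c(-5, 0, 5), rep(1, 3),
                                rep(100, 3))
  expect_equal(unname(which.max(tmix_posterior(mix, 0))), 2)
  expect_gt(tmix_posterior(mix, 5 + 20)[, "up"], 0.999)
  expect_gt(tmix_posterior(mix, -5 - 20)[, "down"], 0.999)
})
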