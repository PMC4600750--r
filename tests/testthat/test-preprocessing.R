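test_that("expressed-gene calls separate clear high/low populations", {
  set.seed(31)
  expr <- cbind(matrix(rnorm(500 * 80, 2, 0.5), 80),
                matrix(rnorm(500 * 80, 10, 0.5), 80))
  colnames(expr) <- paste0("g", 1:1000)
  rownames(expr) <- paste0("p", 1:80)
  calls <- detect_expressed_genes(expr)
  truth <- rep(c(FALSE, TRUE), each = 500)
  expect_gte(mean(calls$is_expressed == truth), 0.99)
  expect_true(all(calls$posterior_high >= 0 & calls$posterior_high <= 1))
  expect_equal(nrow(calls), ncol(expr))
})

test_that("boxplot-rule outliers get posterior 1 or 0 directly", {
  set.seed(32)
  expr <- matrix(rnorm(60 * 100, 5, 0.3), 60, 100,
                 dimnames = list(paste0("p", 1:60), paste0("g", 1:100)))
  expr[, 1] <- 50    # far above the upper Tukey fence
  expr[, 2] <- -40   # far below the lower fence
  calls <- detect_expressed_genes(expr)
  expect_equal(calls$outlier_flag[1], "high")
  expect_equal(calls$posterior_high[1], 1)
  expect_equal(calls$outlier_flag[2], "low")
  expect_equal(calls$posterior_high[2], 0)
})

test_that("degenerate expression matrices are refused", {
  expr <- matrix(1, 10, 100,
                 dimnames = list(paste0("p", 1:10), paste0("g", 1:100)))
  expect_error(detect_expressed_genes(expr),
               class = "xshadow_mixture_unfit_error")
  expr2 <- matrix(rnorm(10 * 20), 10, 20,
                  dimnames = list(paste0("p", 1:10), paste0("g", 1:20)))
  expect_error(detect_expressed_genes(expr2),
               class = "xshadow_mixture_unfit_error")
})

test_that("GP regression removes the dosage signal from expression", {
  set.seed(33)
  x <- rnorm(200)
  y <- 2 * x + rnorm(200, 0, 0.1)
  r <- compensate_cnv_cis(y, x)
  expect_lt(abs(cor(r$residuals, x)), 0.1)
  expect_lt(abs(mean(r$residuals)), 0.05)
  ## expression independent of copy number keeps its variance
  y2 <- rnorm(200)
  r2 <- compensate_cnv_cis(y2, x)
  expect_lt(abs(var(r2$residuals) / var(y2) - 1), 0.1)
})

test_that("GP residuals are invariant to patient order and degenerate input", {
  set.seed(34)
  x <- rnorm(60)
  y <- 1.5 * x + rnorm(60, 0, 0.2)
  r <- compensate_cnv_cis(y, x)
  o <- sample(60)
  r2 <- compensate_cnv_cis(y[o], x[o])
  expect_equal(r2$residuals, r$residuals[o], tolerance = 1e-10)
  ## constant copy number: centred expression exactly
  r3 <- compensate_cnv_cis(y, rep(2, 60))
  expect_identical(r3$constant_x, TRUE)
  expect_equal(r3$residuals, y - mean(y))
  expect_error(compensate_cnv_cis(y[1:5], x[1:5]),
               class = "xshadow_precondition_error")
})

test_that("graph conditioning keeps differentially expressed connected genes at weight 1", {
  set.seed(35)
  expr <- matrix(rnorm(100 * 20), 100, 20,
                 dimnames = list(paste0("p", 1:100), paste0("n", 1:20)))
  mut_pat <- paste0("p", 1:30)
  expr[mut_pat, 1:5] <- expr[mut_pat, 1:5] + 2  # ~2 SD shift in 5 genes
  mut <- xshadow:::as_mutation_table(
    data.frame(patient = mut_pat, gene = "G1", mut_class = "missense"))
  graph <- data.frame(gene_a = "G1", gene_b = paste0("n", 1:20),
                      weight = c(rep(0.8, 18), 0.3, 0.35))
  cg <- condition_influence_graph(graph, expr, mut)
  expect_setequal(cg$neighbour, paste0("n", 1:5))
  expect_true(all(cg$weight == 1))
  ## sub-floor edges never appear even without differential expression
  expect_false(any(c("n19", "n20") %in% cg$neighbour))
})

test_that("without differential expression the original weights are kept", {
  set.seed(36)
  expr <- matrix(rnorm(100 * 10), 100, 10,
                 dimnames = list(paste0("p", 1:100), paste0("n", 1:10)))
  mut <- xshadow:::as_mutation_table(
    data.frame(patient = paste0("p", 1:20), gene = "G1",
               mut_class = "missense"))
  w <- round(runif(10, 0.4, 1), 3)
  graph <- data.frame(gene_a = "G1", gene_b = paste0("n", 1:10), weight = w)
  cg <- condition_influence_graph(graph, expr, mut)
  expect_equal(nrow(cg), 10)
  expect_equal(sort(cg$weight), sort(w))
  expect_true(all(!cg$de_pass))
})

test_that("cross-cohort Fisher combination promotes recurrent genes", {
  pv <- data.frame(gene = "G1", neighbour = rep(c("a", "b"), each = 3),
                   p = c(0.01, 0.02, 0.03, 0.5, 0.6, 0.7))
  comb <- combine_de_pvalues(pv)
  ## hand check of Fisher's statistic for neighbour 'a'
  expect_equal(comb$p_combined[comb$neighbour == "a"],
               pchisq(-2 * sum(log(c(0.01, 0.02, 0.03))), df = 6,
                      lower.tail = FALSE))
  expect_lt(comb$fdr[comb$neighbour == "a"], 0.05)
  expect_gt(comb$fdr[comb$neighbour == "b"], 0.5)
})
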