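#' Call highly expressed genes from a cohort expression matrix
#'
#' Mutations in genes that are not expressed in a tumour type are unlikely to
#' be pathogenic, so such genes are filtered before modelling.  Each gene is
#' summarised by the 90th percentile of its expression across patients (the
#' high percentile guards against copy-number deletions dragging the summary
#' down; it is rare for a gene to be deleted in 90% of samples).  The
#' percentiles are modelled as a two-component Gaussian mixture
#' (highly / lowly expressed); before fitting, outliers by the boxplot rule
#' (Tukey fences at 1.5 IQR) are set aside and re-assigned posterior 1 (high
#' side) or 0 (low side).  A gene is called expressed when its posterior in
#' the higher-mean component is at least `posterior_threshold`.
#'
#' @param expr Patients-by-genes expression matrix, log2 scale.
#' @param posterior_threshold Posterior needed to call a gene expressed
#'   (default 0.8).
#' @return Data frame with one row per gene: `gene`, `percentile90`,
#'   `posterior_high`, `is_expressed`, `outlier_flag`.
#' @importFrom mclust Mclust mclustBIC
#' @export
detect_expressed_genes <- function(expr, posterior_threshold = 0.8) {
  if (ncol(expr) < 50)
    stop_xshadow("fewer than 50 genes; cannot fit the expressed-gene mixture",
                 "xshadow_mixture_unfit_error")
  q90 <- apply(expr, 2, stats::quantile, probs = 0.9, na.rm = TRUE, type = 7)
  if (diff(range(q90)) == 0)
    stop_xshadow("all genes have identical 90th-percentile expression",
                 "xshadow_mixture_unfit_error")
  fence <- tukey_fence(q90, 1.5)
  flag <- rep("none", length(q90))
  flag[q90 > fence["upper"]] <- "high"
  flag[q90 < fence["lower"]] <- "low"
  core <- q90[flag == "none"]
  if (length(unique(core)) < 2)
    stop_xshadow("no variation left after outlier removal",
                 "xshadow_mixture_unfit_error")
  fit <- mclust::Mclust(core, G = 2, modelNames = c("V", "E"), verbose = FALSE)
  if (is.null(fit))
    stop_xshadow("two-component Gaussian mixture failed to fit",
                 "xshadow_mixture_unfit_error")
  high_comp <- which.max(fit$parameters$mean)
  post <- rep(NA_real_, length(q90))
  post[flag == "none"] <- fit$z[, high_comp]
  post[flag == "high"] <- 1
  post[flag == "low"] <- 0
  data.frame(gene = colnames(expr), percentile90 = unname(q90),
             posterior_high = unname(post),
             is_expressed = unname(post >= posterior_threshold),
             outlier_flag = flag, stringsAsFactors = FALSE)
}

## ---- Gaussian-process compensation of copy-number cis effects -------------

# negative log marginal likelihood of a zero-mean GP with squared-exponential
# kernel plus noise, and its analytic gradient in log-hyperparameters
gp_nlml <- function(lpar, x, y, d2) {
  ell2 <- exp(2 * lpar[1]); s2 <- exp(2 * lpar[2]); sn2 <- exp(2 * lpar[3])
  n <- length(y)
  K <- s2 * exp(-d2 / (2 * ell2))
  Ky <- K + diag(sn2, n)
  ch <- tryCatch(chol(Ky), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = c(0, 0, 0)))
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  nlml <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + n / 2 * log(2 * pi)
  Kinv <- chol2inv(ch)
  W <- alpha %*% t(alpha) - Kinv      # d(lml)/dK_y = W / 2
  gl <- 0.5 * sum(W * (K * d2 / ell2))       # d/d log(ell)
  gs <- 0.5 * sum(W * (2 * K))               # d/d log(s)
  gn <- 0.5 * sum(diag(W)) * 2 * sn2         # d/d log(sn)
  list(value = nlml, gradient = -c(gl, gs, gn))
}

#' Remove copy-number cis effects from one gene's expression
#'
#' Before trans-effect analysis the direct dosage effect of copy-number
#' alterations on the same gene's expression is removed.  Expression is
#' regressed on the copy-number log2 ratio with Gaussian-process regression
#' (squared-exponential kernel plus noise); hyperparameters maximise the log
#' marginal likelihood by L-BFGS with analytic gradients, restarted from
#' three lengthscales (0.5, 1 and 2 times the SD of `x`).  The returned
#' residuals (observed minus posterior mean) carry whatever trans-regulation
#' remains.
#'
#' @param y Expression values (log2 scale).
#' @param x Copy-number log2 ratios, same length; at least 10 paired finite
#'   observations are required.
#' @return List: `residuals`, `gp` (lengthscale, signal and noise variances,
#'   achieved log marginal likelihood), `constant_x` flag.
#' @export
compensate_cnv_cis <- function(y, x) {
  keep <- is.finite(y) & is.finite(x)
  if (sum(keep) < 10)
    stop_xshadow("need at least 10 paired finite observations",
                 "xshadow_precondition_error")
  res <- rep(NA_real_, length(y))
  yk <- y[keep]; xk <- x[keep]
  ## canonicalise the observation order so the fit (and its optimiser path)
  ## is exactly invariant to how patients were ordered
  ord <- order(xk, yk)
  yk <- yk[ord]; xk <- xk[ord]
  inv <- order(ord)
  if (stats::sd(xk) == 0) {
    res[keep] <- (yk - mean(yk))[inv]
    return(list(residuals = res,
                gp = list(lengthscale = NA_real_, signal_var = NA_real_,
                          noise_var = NA_real_, lml = NA_real_),
                constant_x = TRUE))
  }
  ybar <- mean(yk)
  yc <- yk - ybar
  d2 <- outer(xk, xk, `-`)^2
  sy <- stats::sd(yc)
  best <- NULL
  for (mult in c(0.5, 1, 2)) {
    start <- log(c(mult * stats::sd(xk), sy, sy / 2))
    opt <- stats::optim(start, fn = function(p) gp_nlml(p, xk, yc, d2)$value,
                        gr = function(p) gp_nlml(p, xk, yc, d2)$gradient,
                        method = "L-BFGS-B", lower = rep(-8, 3),
                        upper = rep(8, 3))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ell2 <- exp(2 * best$par[1]); s2 <- exp(2 * best$par[2])
  sn2 <- exp(2 * best$par[3])
  K <- s2 * exp(-d2 / (2 * ell2))
  ch <- chol(K + diag(sn2, length(yc)))
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  post_mean <- as.vector(K %*% alpha)
  res[keep] <- (yc - post_mean)[inv]
  list(residuals = res,
       gp = list(lengthscale = sqrt(ell2), signal_var = s2, noise_var = sn2,
                 lml = -best$value),
       constant_x = FALSE)
}

#' Combine per-cohort differential-expression p-values
#'
#' Fisher's method pooled per (mutated gene, connected gene) pair, with
#' Benjamini-Hochberg adjustment across pairs.  Used by the cross-cohort
#' variant of influence-graph conditioning: a connected gene not
#' differentially expressed in the current cohort can still be promoted to
#' weight 1 if it is recurrently differentially expressed elsewhere.
#'
#' @param pvalues Data frame with columns `gene`, `neighbour`, `p` (several
#'   rows per pair, one per cohort).
#' @return Data frame `gene`, `neighbour`, `p_combined`, `fdr`.
#' @export
combine_de_pvalues <- function(pvalues) {
  stopifnot(all(c("gene", "neighbour", "p") %in% names(pvalues)))
  key <- paste(pvalues$gene, pvalues$neighbour, sep = "\r")
  comb <- vapply(split(pvalues$p, key), function(p) {
    p <- pmax(p[is.finite(p)], 1e-300)
    if (length(p) == 0) return(NA_real_)
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  }, 0)
  ab <- do.call(rbind, strsplit(names(comb), "\r", fixed = TRUE))
  data.frame(gene = ab[, 1], neighbour = ab[, 2], p_combined = unname(comb),
             fdr = stats::p.adjust(comb, "BH"), stringsAsFactors = FALSE)
}

#' Condition the influence graph on the observed cohort
#'
#' Builds each mutated gene's connected-gene set from the weighted influence
#' graph.  Edges below the confidence floor (default 0.4, the customary
#' median-confidence cutoff for such networks) are dropped.  Each remaining
#' connected gene is then tested for differential expression between patients
#' with and without a mutation in the gene (Welch two-sample t-test on log2
#' values, BH-adjusted within the gene's neighbourhood).  If any connected
#' genes pass at `alpha`, the neighbourhood is restricted to them with
#' weights set to 1; otherwise the original weighted neighbourhood is kept
#' unchanged.  With fewer than `min_mutated` mutated patients the test is
#' skipped and original weights are used.
#'
#' @param graph `influence_graph` data frame (or path readable by
#'   [read_influence_graph()]).
#' @param expr Patients-by-genes expression matrix.
#' @param mut `mutation_table` for the same cohort.
#' @param weight_floor Minimum edge confidence retained (default 0.4).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param min_mutated Minimum mutated patients required to run the test.
#' @param prior_pvalues Optional output of [combine_de_pvalues()] from other
#'   cohorts; pairs with `fdr <= cross_fdr` are also promoted to weight 1.
#' @param cross_fdr FDR threshold for the cross-cohort promotion.
#' @return Data frame `gene`, `neighbour`, `weight`, `de_pass` listing each
#'   mutated gene's conditioned neighbourhood.
#' @export
condition_influence_graph <- function(graph, expr, mut, weight_floor = 0.4,
                                      alpha = 0.05, min_mutated = 3,
                                      prior_pvalues = NULL, cross_fdr = 0.05) {
  graph <- read_influence_graph(graph)
  graph <- graph[graph$weight >= weight_floor, , drop = FALSE]
  genes <- unique(mut$gene)
  patients <- rownames(expr)
  out <- list()
  for (g in genes) {
    nb <- rbind(
      data.frame(neighbour = graph$gene_b[graph$gene_a == g],
                 weight = graph$weight[graph$gene_a == g]),
      data.frame(neighbour = graph$gene_a[graph$gene_b == g],
                 weight = graph$weight[graph$gene_b == g]))
    nb <- nb[nb$neighbour %in% colnames(expr), , drop = FALSE]
    if (nrow(nb) == 0) {
      message(sprintf("gene %s has no connected genes in the graph; skipped", g))
      next
    }
    mut_pat <- intersect(mut$patient[mut$gene == g], patients)
    other <- setdiff(patients, mut_pat)
    de_p <- rep(NA_real_, nrow(nb))
    if (length(mut_pat) >= min_mutated && length(other) >= 2) {
      for (i in seq_len(nrow(nb))) {
        a <- expr[mut_pat, nb$neighbour[i]]
        b <- expr[other, nb$neighbour[i]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) >= 2 && length(b) >= 2 &&
            (stats::sd(a) > 0 || stats::sd(b) > 0)) {
          de_p[i] <- tryCatch(stats::t.test(a, b)$p.value,
                              error = function(e) NA_real_)
        }
      }
    }
    de_q <- stats::p.adjust(de_p, "BH")
    pass <- !is.na(de_q) & de_q <= alpha
    if (!is.null(prior_pvalues)) {
      pp <- prior_pvalues[prior_pvalues$gene == g &
                            prior_pvalues$fdr <= cross_fdr, ]
      pass <- pass | nb$neighbour %in% pp$neighbour
    }
    if (any(pass)) {
      res <- data.frame(gene = g, neighbour = nb$neighbour[pass], weight = 1,
                        de_pass = TRUE, stringsAsFactors = FALSE)
    } else {
      res <- data.frame(gene = g, neighbour = nb$neighbour, weight = nb$weight,
                        de_pass = FALSE, stringsAsFactors = FALSE)
    }
    out[[g]] <- res
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), neighbour = character(0),
                      weight = numeric(0), de_pass = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
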