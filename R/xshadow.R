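#' Analysis configuration
#'
#' Collects the tunable constants of the analysis.  The reporting thresholds
#' (`p_d_threshold = 0.8`, `p_f_threshold = 0.5`) balance discovery of novel
#' genes against false positives; the `weight_floor = 0.4` keeps only
#' at-least-median-confidence interactions of the influence graph.
#'
#' @param p_d_threshold Gene-level posterior needed to call a gene as
#'   impacting expression.
#' @param p_f_threshold Mutation-level posterior needed to call a mutation
#'   impactful.
#' @param weight_floor Minimum influence-graph edge confidence.
#' @param em_max_iter,em_tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param mix_max_iter,mix_tol Same for the per-gene emission mixture fits.
#' @param include_silent Model synonymous/noncoding mutations too (excluded
#'   by default: they are not expected to carry expression impact).
#' @param filter_expressed Run the expressed-gene filter before modelling.
#' @param condition_graph Condition the influence graph on cohort
#'   differential expression (trans mode).
#' @param de_alpha,min_mutated_de Differential-expression threshold and
#'   minimum mutated patients for graph conditioning.
#' @param min_mutations_em Genes with fewer mutations are excluded from EM
#'   pooling (they contribute no recurrence signal) but are still scored
#'   with the fitted parameters.
#' @param force_H_down Force the self-direction to "down" in cis mode
#'   (loss-of-function analyses) instead of estimating it.
#' @param rng_seed Seed recorded in the fit and used for any randomised
#'   stage.
#' @return List of class `"xshadow_config"`.
#' @export
xshadow_config <- function(p_d_threshold = 0.8, p_f_threshold = 0.5,
                           weight_floor = 0.4, em_max_iter = 100,
                           em_tol = 1e-5, mix_max_iter = 150, mix_tol = 1e-5,
                           include_silent = FALSE, filter_expressed = FALSE,
                           condition_graph = TRUE, de_alpha = 0.05,
                           min_mutated_de = 3, min_mutations_em = 2,
                           force_H_down = FALSE, rng_seed = 1L) {
  stopifnot(p_d_threshold > 0, p_d_threshold < 1,
            p_f_threshold > 0, p_f_threshold < 1,
            em_tol > 0, mix_tol > 0)
  structure(list(p_d_threshold = p_d_threshold, p_f_threshold = p_f_threshold,
                 weight_floor = weight_floor, em_max_iter = em_max_iter,
                 em_tol = em_tol, mix_max_iter = mix_max_iter,
                 mix_tol = mix_tol, include_silent = include_silent,
                 filter_expressed = filter_expressed,
                 condition_graph = condition_graph, de_alpha = de_alpha,
                 min_mutated_de = min_mutated_de,
                 min_mutations_em = min_mutations_em,
                 force_H_down = force_H_down,
                 rng_seed = as.integer(rng_seed)),
            class = "xshadow_config")
}

#' Fit the mutation-impact model to a cohort
#'
#' The central fitting function.  Given a somatic mutation table, a
#' patients-by-genes expression matrix and (for trans mode) a weighted
#' influence graph, it runs the full analysis: cohort alignment, optional
#' expressed-gene filtering and copy-number compensation, influence-graph
#' conditioning, per-gene emission-mixture fitting, regulation-direction
#' estimation, EM parameter learning pooled across mutated genes, and exact
#' posterior inference.  In cis mode every mutated gene is connected only to
#' itself; in trans mode to its conditioned neighbourhood.
#'
#' @param mutations A `mutation_table` (or data frame with columns
#'   `patient`, `gene`, `mut_class`, optional `position`).
#' @param expression Patients-by-genes numeric matrix, log2 scale.
#' @param graph Influence-graph edge list (`gene_a`, `gene_b`, `weight`);
#'   required in trans mode.
#' @param cnv Optional patients-by-genes copy-number log2-ratio matrix; when
#'   supplied in trans mode, per-gene dosage effects are removed from
#'   expression by GP regression before modelling.
#' @param cnv_calls Optional discrete call matrix; non-neutral calls are
#'   encoded as additional mutation events (see [encode_cnv_events()]).
#' @param mode `"cis"` or `"trans"`.
#' @param config An [xshadow_config()].
#' @param init Starting [xshadow_params()] for EM.
#' @return An object of class `"xshadow"`; see [print.xshadow()],
#'   [summary.xshadow()], [coef.xshadow()], [predict.xshadow()],
#'   [plot.xshadow()] and [simulate.xshadow()].
#' @export
xshadow <- function(mutations, expression, graph = NULL, cnv = NULL,
                    cnv_calls = NULL, mode = c("cis", "trans"),
                    config = xshadow_config(), init = xshadow_params()) {
  mode <- match.arg(mode)
  cl <- match.call()
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  mut <- as_mutation_table(mutations)
  if (!is.null(cnv_calls)) {
    ev <- encode_cnv_events(cnv_calls)
    if (nrow(ev) > 0) mut <- as_mutation_table(rbind(mut, ev))
  }
  model_mut <- if (config$include_silent) mut else
    mut[!mut$mut_class %in% silent_classes, , drop = FALSE]
  if (nrow(model_mut) == 0)
    stop_xshadow("no modellable mutations after class filtering",
                 "xshadow_empty_error")
  al <- align_cohort(model_mut, expression, cnv)
  model_mut <- al$mut; expr <- al$expr; cnv <- al$cn
  tick("align")

  expressed_calls <- NULL
  if (config$filter_expressed) {
    expressed_calls <- detect_expressed_genes(expr)
    keep <- expressed_calls$gene[expressed_calls$is_expressed]
    expr <- expr[, colnames(expr) %in% keep, drop = FALSE]
    model_mut <- model_mut[!(model_mut$gene %in% expressed_calls$gene) |
                             model_mut$gene %in% keep, , drop = FALSE]
    tick("expressed_filter")
  }

  if (mode == "trans" && !is.null(cnv)) {
    shared <- intersect(colnames(expr), colnames(cnv))
    for (g in shared) {
      ok <- sum(is.finite(expr[, g]) & is.finite(cnv[, g]))
      if (ok >= 10)
        expr[, g] <- compensate_cnv_cis(expr[, g], cnv[, g])$residuals
    }
    tick("cnv_compensation")
  }

  ## neighbourhoods
  if (mode == "cis") {
    genes <- intersect(unique(model_mut$gene), colnames(expr))
    nbhd <- data.frame(gene = genes, neighbour = genes, weight = 1,
                       stringsAsFactors = FALSE)
  } else {
    if (is.null(graph))
      stop_xshadow("trans mode requires an influence graph", "xshadow_domain_error")
    graph <- read_influence_graph(graph)
    if (nrow(graph) == 0)
      stop_xshadow("influence graph has no edges", "xshadow_empty_error")
    nbhd <- if (config$condition_graph) {
      condition_influence_graph(graph, expr, model_mut,
                                weight_floor = config$weight_floor,
                                alpha = config$de_alpha,
                                min_mutated = config$min_mutated_de)
    } else {
      g2 <- graph[graph$weight >= config$weight_floor, , drop = FALSE]
      long <- rbind(data.frame(gene = g2$gene_a, neighbour = g2$gene_b,
                               weight = g2$weight),
                    data.frame(gene = g2$gene_b, neighbour = g2$gene_a,
                               weight = g2$weight))
      long <- long[long$gene %in% model_mut$gene &
                     long$neighbour %in% colnames(expr), , drop = FALSE]
      long
    }
    if (nrow(nbhd) == 0)
      stop_xshadow("graph conditioning left no connected genes for any mutated gene",
                   "xshadow_graph_error")
  }
  tick("neighbourhoods")

  ## per-gene emission mixtures for every gene appearing as a neighbour
  nb_genes <- unique(nbhd$neighbour)
  mixtures <- vector("list", length(nb_genes))
  names(mixtures) <- nb_genes
  mix_ok <- logical(length(nb_genes))
  for (i in seq_along(nb_genes)) {
    mx <- tryCatch(
      suppressWarnings(fit_t_mixture(expr[, nb_genes[i]],
                                     max_iter = config$mix_max_iter,
                                     tol = config$mix_tol)),
      xshadow_degenerate_data_error = function(e) NULL)
    mixtures[[i]] <- mx
    mix_ok[i] <- !is.null(mx)
  }
  mixtures <- mixtures[mix_ok]
  nbhd <- nbhd[nbhd$neighbour %in% names(mixtures), , drop = FALSE]
  tick("emission_mixtures")

  ## submodels
  subs <- list()
  for (g in unique(nbhd$gene)) {
    pats <- sort(unique(model_mut$patient[model_mut$gene == g]))
    if (length(pats) == 0) next
    nb <- nbhd[nbhd$gene == g, , drop = FALSE]
    y <- expr[pats, nb$neighbour, drop = FALSE]
    colnames(y) <- nb$neighbour
    H <- if (mode == "cis" && config$force_H_down) rep("down", nrow(nb)) else NULL
    subs[[g]] <- build_submodel(g, y, nb$weight, mixtures[nb$neighbour], H = H)
  }
  if (length(subs) == 0)
    stop_xshadow("no mutated gene has both mutations and expression data",
                 "xshadow_empty_error")
  tick("submodels")

  ## EM on genes with enough mutations to pool
  em_subs <- Filter(function(s) nrow(s$y) >= config$min_mutations_em, subs)
  if (length(em_subs) > 0) {
    em <- em_fit(em_subs, init = init, max_iter = config$em_max_iter,
                 tol = config$em_tol)
    params <- em$params
    if (isTRUE(em$h_flipped)) {
      subs <- lapply(subs, function(s) {
        s$H <- ifelse(s$H == "up", "down", "up")
        s$Hm[] <- ifelse(s$Hm == "up", "down", "up")
        s
      })
    }
  } else {
    warning("no gene has enough mutations for EM; scoring with initial parameters")
    em <- NULL
    params <- init
  }
  tick("em")

  ## final inference for every submodel
  gene_rows <- vector("list", length(subs))
  mut_rows <- vector("list", length(subs))
  reg_rows <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    post <- infer_posteriors(s, params)
    M <- nrow(s$y); N <- ncol(s$y)
    gene_rows[[i]] <- data.frame(gene = s$gene, n_mutations = M,
                                 p_d = post$p_d, stringsAsFactors = FALSE)
    cls <- model_mut$mut_class[match(paste(s$gene, s$patients),
                                     paste(model_mut$gene, model_mut$patient))]
    mut_rows[[i]] <- data.frame(gene = s$gene, patient = s$patients,
                                mut_class = cls, p_f = post$p_f,
                                stringsAsFactors = FALSE)
    reg_rows[[i]] <- data.frame(
      gene = s$gene,
      patient = rep(s$patients, times = N),
      neighbour = rep(s$neighbours, each = M),
      h = rep(s$H, each = M),
      p_down = as.vector(post$p_g[, , 1]),
      p_neutral = as.vector(post$p_g[, , 2]),
      p_up = as.vector(post$p_g[, , 3]),
      stringsAsFactors = FALSE)
  }
  genes_df <- do.call(rbind, gene_rows)
  genes_df$impact_call <- genes_df$p_d >= config$p_d_threshold
  muts_df <- do.call(rbind, mut_rows)
  muts_df$impact_call <- muts_df$p_f >= config$p_f_threshold
  reg_df <- do.call(rbind, reg_rows)
  rownames(genes_df) <- rownames(muts_df) <- rownames(reg_df) <- NULL
  tick("inference")

  structure(list(call = cl, mode = mode, config = config,
                 seed = config$rng_seed,
                 params = params, em = em,
                 genes = genes_df, mutations = muts_df, regulation = reg_df,
                 directions = unique(reg_df[, c("gene", "neighbour", "h")]),
                 mixtures = mixtures,
                 expressed_calls = expressed_calls,
                 cohort = list(patients = al$patients,
                               n_patients = length(al$patients),
                               n_mutated_genes = length(subs)),
                 timings = unlist(timings)),
            class = "xshadow")
}

#' @export
print.xshadow <- function(x, ...) {
  cat(sprintf("Mutation-impact model fit (%s mode)\n", x$mode))
  cat(sprintf("  %d patients, %d mutated genes, %d mutations\n",
              x$cohort$n_patients, nrow(x$genes), nrow(x$mutations)))
  if (!is.null(x$em))
    cat(sprintf("  EM: %d iterations (%s)\n", x$em$n_iter,
                if (x$em$converged) "converged" else "iteration cap"))
  cat(sprintf("  genes with P(D) >= %.2f: %d;  mutations with P(F) >= %.2f: %d\n",
              x$config$p_d_threshold, sum(x$genes$impact_call),
              x$config$p_f_threshold, sum(x$mutations$impact_call)))
  invisible(x)
}

#' Summary of a fitted mutation-impact model
#'
#' @param object An `xshadow` fit.
#' @param ... Unused.
#' @return The fit, invisibly; prints fitted parameters and the top genes by
#'   gene-level posterior.
#' @export
summary.xshadow <- function(object, ...) {
  print(object)
  cat("\nFitted parameters:\n")
  print(object$params)
  top <- object$genes[order(-object$genes$p_d), ]
  cat("\nTop genes by P(D):\n")
  print(utils::head(top, 10), row.names = FALSE)
  invisible(object)
}

#' Fitted conditional probabilities as a named vector
#'
#' @param object An `xshadow` fit.
#' @param ... Unused.
#' @return Named numeric vector of the fitted parameters.
#' @export
coef.xshadow <- function(object, ...) {
  p <- object$params
  c(theta_D = p$theta_D, theta_F1_D1 = p$theta_F1_D1,
    theta_F1_D0 = p$theta_F1_D0,
    stats::setNames(p$theta_G_F0, paste0("theta_G_F0_", c("down", "neutral", "up"))),
    stats::setNames(p$theta_G_F1_up, paste0("theta_G_F1_up_", c("down", "neutral", "up"))),
    stats::setNames(p$theta_G_F1_down, paste0("theta_G_F1_down_", c("down", "neutral", "up"))))
}

#' Score a new cohort with an already fitted model
#'
#' Applies the trained conditional probabilities to new data (the
#' discovery/validation design): the new cohort gets its own emission
#' mixtures and direction estimates, but no EM re-fit.
#'
#' @param object An `xshadow` fit.
#' @param mutations,expression,graph,cnv,cnv_calls New cohort inputs, as in
#'   [xshadow()].
#' @param ... Unused.
#' @return An `xshadow` object for the new cohort, scored with the trained
#'   parameters.
#' @export
predict.xshadow <- function(object, mutations, expression, graph = NULL,
                            cnv = NULL, cnv_calls = NULL, ...) {
  cfg <- object$config
  cfg$em_max_iter <- 0L        # no re-learning: scoring only
  out <- xshadow(mutations, expression, graph = graph, cnv = cnv,
                 cnv_calls = cnv_calls, mode = object$mode, config = cfg,
                 init = object$params)
  out$call <- match.call()
  out
}

#' Plot posterior distributions of a fit
#'
#' Left: gene-level posteriors P(D) with the calling threshold; right:
#' mutation-level posteriors P(F), which separate into a bimodal pattern at 0
#' and 1 when mutations with and without expression impact coexist.
#'
#' @param x An `xshadow` fit.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.xshadow <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$genes$p_d, breaks = 20, main = "Gene posteriors",
                 xlab = "P(D)", col = "grey80", ...)
  graphics::abline(v = x$config$p_d_threshold, col = "firebrick", lty = 2)
  graphics::hist(x$mutations$p_f, breaks = 20, main = "Mutation posteriors",
                 xlab = "P(F)", col = "grey80", ...)
  graphics::abline(v = x$config$p_f_threshold, col = "firebrick", lty = 2)
  invisible(x)
}

#' Simulate cohorts from a fitted model
#'
#' Draws new synthetic cohorts from the generative model using the fitted
#' conditional probabilities (cohort dimensions follow `hyper`).
#'
#' @param object An `xshadow` fit.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param hyper [sim_hyperparams()] giving the cohort dimensions; its theta
#'   entries are overridden by the fitted parameters.
#' @param ... Unused.
#' @return A list of [simulate_xshadow_data()] outputs (length `nsim`).
#' @export
simulate.xshadow <- function(object, nsim = 1, seed = 1,
                             hyper = sim_hyperparams(), ...) {
  p <- object$params
  hyper$theta_F1_D1 <- p$theta_F1_D1
  hyper$theta_F1_D0 <- p$theta_F1_D0
  hyper$theta_G_dir <- p$theta_G_F1_up[3]
  hyper$theta_G_tail <- p$theta_G_F0[1]
  hyper$frac_D1 <- p$theta_D
  lapply(seq_len(nsim), function(i)
    simulate_xshadow_data(hyper, seed = derive_seed(seed, i)))
}
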