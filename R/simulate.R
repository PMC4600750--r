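#' Hyperparameters for the generative simulator
#'
#' The defaults are the study's benchmark conditions: 200 mutated genes (half
#' truly impacting expression), 30 mutated patients per gene in a cohort of
#' 200 patients, 20 connected genes per mutated gene, emission mixture
#' locations separated by `delta` within-component standard deviations, and
#' generative conditional probabilities matching a hard noise setting
#' (impactful mutations dysregulate each connected gene with probability 0.5
#' in its H direction; the null leaks 5% into each tail).  `delta = 1.5` is
#' the poorly discriminative emission setting; 3 and 0.75 give the highly and
#' barely discriminative settings of the benchmark grid.
#'
#' @param n_genes Number of mutated genes to simulate.
#' @param frac_D1 Fraction of genes with a true expression impact (D = 1).
#' @param M Mutated patients per gene.
#' @param N Connected genes per mutated gene.
#' @param n_patients Total cohort size (mutated patients are drawn from it).
#' @param delta Separation of adjacent emission components, in
#'   within-component SD units.
#' @param df Degrees of freedom of the emission t components.
#' @param theta_F1_D1,theta_F1_D0 Generative P(F = 1 | D).
#' @param theta_G_dir P(connected gene dysregulated in its H direction | F = 1).
#' @param theta_G_tail Per-tail P(non-neutral | F = 0) (also the opposite-tail
#'   leak under F = 1).
#' @param phenocopy Fraction of non-mutated patients whose expression mimics
#'   an impactful mutation (epigenetic phenocopies; default none).
#' @param mode `"trans"` (each gene has its own N connected genes) or
#'   `"cis"` (the gene is connected to itself only).
#' @return List of class `"sim_hyperparams"`.
#' @export
sim_hyperparams <- function(n_genes = 200, frac_D1 = 0.5, M = 30, N = 20,
                            n_patients = 200, delta = 1.5, df = 8,
                            theta_F1_D1 = 0.85, theta_F1_D0 = 0.10,
                            theta_G_dir = 0.5, theta_G_tail = 0.05,
                            phenocopy = 0, mode = c("trans", "cis")) {
  mode <- match.arg(mode)
  if (mode == "cis") N <- 1
  stopifnot(n_genes >= 1, M >= 1, N >= 1, n_patients >= M, delta >= 0,
            frac_D1 >= 0, frac_D1 <= 1, phenocopy >= 0, phenocopy <= 1)
  structure(list(n_genes = n_genes, frac_D1 = frac_D1, M = M, N = N,
                 n_patients = n_patients, delta = delta, df = df,
                 theta_F1_D1 = theta_F1_D1, theta_F1_D0 = theta_F1_D0,
                 theta_G_dir = theta_G_dir, theta_G_tail = theta_G_tail,
                 phenocopy = phenocopy, mode = mode),
            class = "sim_hyperparams")
}

# generative regulation-state tables implied by the hyperparameters
sim_theta_tables <- function(h) {
  list(F0 = c(h$theta_G_tail, 1 - 2 * h$theta_G_tail, h$theta_G_tail),
       up = c(h$theta_G_tail, 1 - h$theta_G_dir - h$theta_G_tail, h$theta_G_dir),
       down = c(h$theta_G_dir, 1 - h$theta_G_dir - h$theta_G_tail, h$theta_G_tail))
}

#' Simulate a cohort from the generative model
#'
#' Ancestral sampling from the model: per gene D, per mutation F | D, per
#' connected gene a uniform direction H, per (mutation, connected gene) a
#' regulation state G | F, H, and finally expression from a three-component
#' Student's-t mixture whose adjacent locations are `delta` within-component
#' SDs apart.  Patients without a mutation in the gene draw the connected
#' genes' expression from the null mixture marginal (plus optional
#' phenocopies).  Output is deterministic given `seed`.
#'
#' @param h A [sim_hyperparams()] object.
#' @param seed Integer seed.
#' @return List: `mutations` (mutation table), `expression` (patients x
#'   genes matrix), `graph` (influence-graph edge list, all weights 1) and
#'   `truth` (true D per gene, F per mutation, H per connected gene, G per
#'   gene as an M x N state matrix).
#' @export
simulate_xshadow_data <- function(h = sim_hyperparams(), seed = 1) {
  stopifnot(inherits(h, "sim_hyperparams"))
  set.seed(seed)
  sd_comp <- sqrt(h$df / (h$df - 2))          # within-component SD at scale 1
  mu <- c(-h$delta, 0, h$delta) * sd_comp
  th <- sim_theta_tables(h)

  patients <- sprintf("P%03d", seq_len(h$n_patients))
  genes <- sprintf("g%03d", seq_len(h$n_genes))
  D <- stats::rbinom(h$n_genes, 1, h$frac_D1)
  names(D) <- genes

  mut_rows <- vector("list", h$n_genes)
  truth_F <- vector("list", h$n_genes)
  truth_H <- vector("list", h$n_genes)
  truth_G <- vector("list", h$n_genes)
  expr_cols <- vector("list", h$n_genes)
  col_names <- vector("list", h$n_genes)

  draw_states <- function(n, probs) {
    sample.int(3, n, replace = TRUE, prob = probs)
  }

  for (i in seq_len(h$n_genes)) {
    g <- genes[i]
    mut_pat <- sort(sample(patients, h$M))
    f <- stats::rbinom(h$M, 1, if (D[i] == 1) h$theta_F1_D1 else h$theta_F1_D0)
    nb <- if (h$mode == "cis") g else sprintf("%s_t%02d", g, seq_len(h$N))
    H <- sample(c("down", "up"), h$N, replace = TRUE)

    G <- matrix(0L, h$n_patients, h$N)
    is_mut <- patients %in% mut_pat
    pheno <- !is_mut & stats::runif(h$n_patients) < h$phenocopy
    for (n in seq_len(h$N)) {
      G[!is_mut & !pheno, n] <- draw_states(sum(!is_mut & !pheno), th$F0)
      if (any(pheno)) G[pheno, n] <- draw_states(sum(pheno), th[[H[n]]])
    }
    mi <- match(mut_pat, patients)
    for (n in seq_len(h$N)) {
      f1 <- f == 1
      if (any(f1)) G[mi[f1], n] <- draw_states(sum(f1), th[[H[n]]])
      if (any(!f1)) G[mi[!f1], n] <- draw_states(sum(!f1), th$F0)
    }
    y <- matrix(stats::rt(h$n_patients * h$N, df = h$df) + mu[G],
                h$n_patients, h$N)

    mut_rows[[i]] <- data.frame(patient = mut_pat, gene = g,
                                mut_class = "missense",
                                stringsAsFactors = FALSE)
    truth_F[[i]] <- data.frame(gene = g, patient = mut_pat, f = f,
                               stringsAsFactors = FALSE)
    truth_H[[i]] <- data.frame(gene = g, neighbour = nb, h = H,
                               stringsAsFactors = FALSE)
    gm <- G[mi, , drop = FALSE]
    dimnames(gm) <- list(mut_pat, nb)
    truth_G[[i]] <- gm
    expr_cols[[i]] <- y
    col_names[[i]] <- nb
  }

  expression <- do.call(cbind, expr_cols)
  rownames(expression) <- patients
  colnames(expression) <- unlist(col_names)
  if (anyDuplicated(colnames(expression)))
    expression <- expression[, !duplicated(colnames(expression)), drop = FALSE]

  truth_H_df <- do.call(rbind, truth_H)
  graph <- data.frame(gene_a = truth_H_df$gene, gene_b = truth_H_df$neighbour,
                      weight = 1, stringsAsFactors = FALSE)
  names(truth_G) <- genes

  list(mutations = as_mutation_table(do.call(rbind, mut_rows)),
       expression = expression,
       graph = graph,
       truth = list(D = D, F = do.call(rbind, truth_F), H = truth_H_df,
                    G = truth_G),
       hyper = h, seed = seed)
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed from mid-ranks (equivalent to the
#' Mann-Whitney statistic); ties share their average rank.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) true labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_xshadow("AUROC undefined: need both classes in the truth labels",
                 "xshadow_domain_error")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC of inferred posteriors against simulation truth
#'
#' @param fit An `xshadow` fit on simulated data.
#' @param truth The `truth` element of [simulate_xshadow_data()] output.
#' @return Named vector `c(auc_D, auc_F)`.
#' @export
evaluate_auc <- function(fit, truth) {
  g <- fit$genes
  auc_d <- auroc(g$p_d, truth$D[g$gene])
  m <- fit$mutations
  key_fit <- paste(m$gene, m$patient)
  key_tr <- paste(truth$F$gene, truth$F$patient)
  f_true <- truth$F$f[match(key_fit, key_tr)]
  auc_f <- auroc(m$p_f, f_true)
  c(auc_D = auc_d, auc_F = auc_f)
}

#' Permute the inputs to build empirical null data
#'
#' Four schemes probe what drives the predictions while always leaving the
#' expression matrix untouched: `"sample"` permutes patient names within the
#' mutation table, `"gene"` permutes gene names within the mutation table
#' (both preserve per-gene mutation counts), `"network"` replaces every
#' mutated gene's connected-gene set by a random draw of equal size from the
#' expression gene universe, and `"all"` applies both the sample and network
#' shuffles.
#'
#' @param mut `mutation_table`.
#' @param graph Influence-graph edge list.
#' @param expr Expression matrix (supplies the gene universe for the network
#'   scheme; never modified).
#' @param scheme One of `"sample"`, `"gene"`, `"network"`, `"all"`.
#' @param seed Integer seed.
#' @return List `mut`, `graph` with the permuted inputs.
#' @export
permute_inputs <- function(mut, graph, expr, scheme = c("sample", "gene",
                                                        "network", "all"),
                           seed = 1) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  if (scheme %in% c("sample", "all")) {
    u <- unique(mut$patient)
    map <- stats::setNames(sample(u), u)
    mut$patient <- unname(map[mut$patient])
  }
  if (scheme == "gene") {
    u <- unique(mut$gene)
    map <- stats::setNames(sample(u), u)
    mut$gene <- unname(map[mut$gene])
  }
  if (scheme %in% c("network", "all")) {
    genes <- unique(mut$gene)
    universe <- colnames(expr)
    rows <- lapply(genes, function(g) {
      nb <- unique(c(graph$gene_b[graph$gene_a == g],
                     graph$gene_a[graph$gene_b == g]))
      k <- length(nb)
      if (k == 0) return(NULL)
      data.frame(gene_a = g,
                 gene_b = sample(setdiff(universe, g), k),
                 weight = 1, stringsAsFactors = FALSE)
    })
    graph <- do.call(rbind, rows)
  }
  list(mut = as_mutation_table(mut), graph = graph)
}

#' Permutation estimate of the false discovery rate
#'
#' The expected number of calls on permuted (null) inputs divided by the
#' number of calls on the real inputs, clipped to `[0, 1]`.
#'
#' @param real_calls Number of calls at the threshold on the real data.
#' @param permuted_calls Vector of call counts over the permutation runs.
#' @return Estimated FDR.
#' @export
estimate_permutation_fdr <- function(real_calls, permuted_calls) {
  stopifnot(real_calls >= 0, length(permuted_calls) >= 1)
  min(1, max(0, mean(permuted_calls) / max(real_calls, 1)))
}

#' Simulation benchmark of the full fit
#'
#' Simulates replicate cohorts from the generative model, runs the complete
#' analysis (emission fitting, direction estimation, EM, posterior
#' inference) on each, and scores recovery of the gene-level and
#' mutation-level impact indicators by AUROC.
#'
#' @param h [sim_hyperparams()] settings.
#' @param n_reps Number of independent replicates.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param config [xshadow_config()] overrides for the fits.  By default the
#'   influence-graph conditioning step is disabled: the simulator hands the
#'   true connected-gene sets (all weights 1), so the benchmark measures the
#'   model itself, not the real-data preprocessing.
#' @return Data frame with one row per replicate: `replicate`, `seed`,
#'   `auc_D`, `auc_F`.
#' @export
benchmark_simulation <- function(h = sim_hyperparams(), n_reps = 10, seed = 1,
                                 config = xshadow_config(condition_graph = FALSE)) {
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- derive_seed(seed, r)
    sim <- simulate_xshadow_data(h, seed = s)
    fit <- xshadow(sim$mutations, sim$expression, graph = sim$graph,
                   mode = h$mode, config = config)
    auc <- evaluate_auc(fit, sim$truth)
    data.frame(replicate = r, seed = s, auc_D = auc["auc_D"],
               auc_F = auc["auc_F"], row.names = NULL)
  })
  do.call(rbind, rows)
}
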