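#' Per-gene mutation-class counts
#'
#' Counts, per gene, the total number of mutation records, the
#' loss-of-function events (nonsense, stop-gain, frameshift indel, splice
#' site — the pattern characteristic of tumour suppressor genes) and the
#' hotspot events (missense mutations or in-frame indels whose codon recurs
#' at least twice in the gene across patients — characteristic of
#' oncogenes).  Records without a codon position never count as hotspot.
#'
#' @param mut A `mutation_table`.
#' @return Data frame `gene`, `n_total`, `n_loss`, `n_rec`.
#' @export
count_mutation_classes <- function(mut) {
  if (nrow(mut) == 0)
    stop_xshadow("mutation table is empty", "xshadow_empty_error")
  genes <- sort(unique(mut$gene))
  hot_cand <- mut$mut_class %in% c("missense", "inframe_indel") &
    !is.na(mut$position)
  key <- paste(mut$gene, mut$position, sep = "\r")
  rec_tab <- table(key[hot_cand])
  is_rec <- hot_cand & rec_tab[key] >= 2
  is_rec[is.na(is_rec)] <- FALSE
  df <- data.frame(
    gene = genes,
    n_total = as.integer(table(factor(mut$gene, levels = genes))),
    n_loss = as.integer(tapply(mut$mut_class %in% lof_classes,
                               factor(mut$gene, levels = genes), sum)),
    n_rec = as.integer(tapply(is_rec, factor(mut$gene, levels = genes), sum)),
    stringsAsFactors = FALSE)
  df$n_loss[is.na(df$n_loss)] <- 0L
  df$n_rec[is.na(df$n_rec)] <- 0L
  df
}

#' Fit a two-component binomial mixture to per-gene mutation counts
#'
#' The distribution of class-specific counts `n` out of totals `N` across
#' genes is modelled as a mixture of two binomials: a high-rate component
#' (driver-like genes, success rate `p1`) and a low-rate background
#' (`p2 < p1`).  This generalises the classic 20%-of-mutations rule: the
#' threshold is learned from the data and the posterior accounts for each
#' gene's total mutation burden.  Estimated by EM with a 0.5 pseudo-count
#' per component.
#'
#' @param n Vector of class-specific counts per gene.
#' @param N Vector of total mutation counts per gene.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   tolerance.
#' @param init List with starting `p` (length 2) and `w` (length 2).
#' @param pseudo Pseudo-count added to the expected counts.
#' @return Object of class `"binomial_mixture"`: `weight`, `p` (ordered
#'   `p1 > p2`), `loglik` (per-iteration trace), `converged`, `separated`
#'   (FALSE when the two rates collapsed).
#' @export
fit_binomial_mixture <- function(n, N, max_iter = 500, tol = 1e-8,
                                 init = list(p = c(0.3, 0.02), w = c(0.1, 0.9)),
                                 pseudo = 0.5) {
  keep <- !is.na(n) & !is.na(N) & N >= 1
  n <- n[keep]; N <- N[keep]
  if (any(n < 0) || any(n > N))
    stop_xshadow("counts must satisfy 0 <= n <= N", "xshadow_domain_error")
  if (length(n) < 50)
    stop_xshadow("need at least 50 genes with N >= 1", "xshadow_precondition_error")
  if (all(n == 0))
    stop_xshadow("all class counts are zero; mixture is degenerate",
                 "xshadow_degenerate_data_error")
  p <- init$p; w <- init$w / sum(init$w)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- log(w[1]) + stats::dbinom(n, N, p[1], log = TRUE)
    l2 <- log(w[2]) + stats::dbinom(n, N, p[2], log = TRUE)
    mx <- pmax(l1, l2)
    ll <- sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r1 <- 1 / (1 + exp(l2 - l1))
    r2 <- 1 - r1
    w <- c(sum(r1) + pseudo, sum(r2) + pseudo)
    w <- w / sum(w)
    p <- c((sum(r1 * n) + pseudo) / (sum(r1 * N) + 2 * pseudo),
           (sum(r2 * n) + pseudo) / (sum(r2 * N) + 2 * pseudo))
  }
  if (p[1] < p[2]) { p <- rev(p); w <- rev(w) }
  structure(list(weight = w, p = p, loglik = ll_trace, converged = converged,
                 separated = (p[1] - p[2]) > 0.01 && w[1] > 1e-4),
            class = "binomial_mixture")
}

#' @export
print.binomial_mixture <- function(x, ...) {
  cat(sprintf("Two-component binomial mixture: p1 = %.4f (w = %.3f), p2 = %.4f (w = %.3f)%s\n",
              x$p[1], x$weight[1], x$p[2], x$weight[2],
              if (!x$separated) "  [components not separated]" else ""))
  invisible(x)
}

#' Posterior membership in the high-rate binomial component
#'
#' `P(driver-like | n, N)` under a fitted [fit_binomial_mixture()]: the
#' posterior that the gene's counts come from the component with the higher
#' success rate.
#'
#' @param n,N Counts and totals (vectorised).
#' @param mix A `"binomial_mixture"`.
#' @return Posterior probabilities in `[0, 1]`; genes with `N = 0` get the
#'   prior weight of the high-rate component, with a warning.
#' @export
posterior_driver_class <- function(n, N, mix) {
  stopifnot(inherits(mix, "binomial_mixture"))
  if (any(n < 0 | n > N, na.rm = TRUE))
    stop_xshadow("counts must satisfy 0 <= n <= N", "xshadow_domain_error")
  out <- numeric(length(n))
  zero <- !is.na(N) & N == 0
  if (any(zero)) {
    warning("genes with N = 0 receive the prior high-rate weight")
    out[zero] <- mix$weight[1]
  }
  i <- !zero
  l1 <- log(mix$weight[1]) + stats::dbinom(n[i], N[i], mix$p[1], log = TRUE)
  l2 <- log(mix$weight[2]) + stats::dbinom(n[i], N[i], mix$p[2], log = TRUE)
  out[i] <- 1 / (1 + exp(l2 - l1))
  out
}

#' Annotate tumour-suppressor and oncogene mutation patterns
#'
#' Fits the loss-of-function and hotspot binomial mixtures independently on
#' the cohort's per-gene counts and reports, per gene, the posterior of
#' belonging to each high-rate component — P(TSG) from loss-of-function
#' counts, P(OCG) from hotspot counts — with threshold calls (default 0.2,
#' inclusive).
#'
#' @param mut A `mutation_table`.
#' @param threshold Posterior threshold for the boolean calls.
#' @return Data frame `gene`, `n_total`, `n_loss`, `n_rec`, `p_tsg`,
#'   `p_ocg`, `is_tsg`, `is_ocg`, with the two fitted mixtures attached as
#'   attributes `tsg_mixture` / `ocg_mixture`.
#' @export
annotate_drivers <- function(mut, threshold = 0.2) {
  cnt <- count_mutation_classes(mut)
  tsg_mix <- fit_binomial_mixture(cnt$n_loss, cnt$n_total)
  ocg_mix <- tryCatch(fit_binomial_mixture(cnt$n_rec, cnt$n_total),
                      xshadow_degenerate_data_error = function(e) NULL)
  cnt$p_tsg <- posterior_driver_class(cnt$n_loss, cnt$n_total, tsg_mix)
  cnt$p_ocg <- if (is.null(ocg_mix)) 0 else
    posterior_driver_class(cnt$n_rec, cnt$n_total, ocg_mix)
  cnt$is_tsg <- classify_drivers(cnt$p_tsg, threshold)
  cnt$is_ocg <- classify_drivers(cnt$p_ocg, threshold)
  attr(cnt, "tsg_mixture") <- tsg_mix
  attr(cnt, "ocg_mixture") <- ocg_mix
  cnt
}

#' Threshold posterior driver probabilities
#'
#' @param posterior Vector of posteriors in `[0, 1]`.
#' @param threshold Calling threshold (default 0.2); the comparison is
#'   inclusive (`>=`).
#' @return Logical vector.
#' @export
classify_drivers <- function(posterior, threshold = 0.2) {
  if (!is_prob(posterior[!is.na(posterior)]))
    stop_xshadow("posteriors must lie in [0, 1]", "xshadow_domain_error")
  posterior >= threshold
}
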