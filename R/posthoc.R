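# cache of Monte-Carlo null dip tables, keyed by (n, n_sim, seed)
.dip_null_cache <- new.env(parent = emptyenv())

#' Hartigan's dip statistic
#'
#' The maximum distance between the empirical CDF of `values` and the
#' closest unimodal CDF, computed via greatest-convex-minorant /
#' least-concave-majorant fits over candidate mode positions.  Large values
#' indicate departure from unimodality (e.g. a bimodal split of mutation
#' posteriors across patients).
#'
#' @param values Numeric vector (at least 4 observations).
#' @return The dip statistic, in `[1/(2n), 0.25]` for samples with distinct
#'   values.
#' @export
dip_stat <- function(values) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (n < 4)
    stop_xshadow("dip test needs at least 4 observations", "xshadow_sample_size_error")
  t <- unique(x)
  cnt <- as.integer(table(match(x, t)))
  .dip_stat_cpp(t, cnt, n)
}

#' Dip test of unimodality with Monte-Carlo p-value
#'
#' Compares the observed dip statistic to its null distribution under
#' uniform samples of the same size (uniformity is the canonical least
#' favourable unimodal null).  The null table is simulated once per sample
#' size with a fixed seed and cached, so repeated tests at one size are
#' cheap.  The p-value uses the add-one estimator
#' `(1 + #{null >= observed}) / (1 + n_sim)`.
#'
#' @param values Numeric vector (at least 4 observations).
#' @param n_sim Number of null simulations (at least 2000 recommended).
#' @param seed Seed for the null table (recorded in the output).
#' @return List: `dip`, `p_value`, `n`, `n_sim`, `seed`.
#' @export
dip_test <- function(values, n_sim = 2000, seed = 7) {
  d <- dip_stat(values)
  n <- sum(!is.na(values))
  key <- paste(n, n_sim, seed, sep = "_")
  if (is.null(.dip_null_cache[[key]])) {
    null_tab <- local({
      rng <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
      set.seed(seed)
      vapply(seq_len(n_sim), function(i) dip_stat(stats::runif(n)), 0)
    })
    .dip_null_cache[[key]] <- null_tab
  }
  null_tab <- .dip_null_cache[[key]]
  p <- (1 + sum(null_tab >= d)) / (1 + n_sim)
  list(dip = d, p_value = p, n = n, n_sim = n_sim, seed = seed)
}

#' Stratify mutated patients by their mutation-impact posterior
#'
#' Splits the patients carrying mutations in one gene into a high group
#' (P(F) at or above the threshold: mutations with expression impact) and a
#' low group, and tests the P(F) values for bimodality with the dip test.  A
#' bimodal pattern indicates that the same gene carries consequential
#' mutations in some patients and inert ones in others.
#'
#' @param pf Named vector of per-patient mutation posteriors in `[0, 1]`.
#' @param threshold Split point (default 0.5, inclusive for the high group).
#' @param n_sim,seed Passed to [dip_test()] (used when `length(pf) >= 4`).
#' @return List of class `"xshadow_strata"`: `high`, `low` (patient names or
#'   indices), `dip`, `p_value`.
#' @export
stratify_patients <- function(pf, threshold = 0.5, n_sim = 2000, seed = 7) {
  if (!is_prob(pf[!is.na(pf)]))
    stop_xshadow("posteriors must lie in [0, 1]", "xshadow_domain_error")
  nm <- if (is.null(names(pf))) seq_along(pf) else names(pf)
  hi <- pf >= threshold
  dt <- if (sum(!is.na(pf)) >= 4) dip_test(pf, n_sim = n_sim, seed = seed)
        else list(dip = NA_real_, p_value = NA_real_)
  structure(list(high = nm[which(hi)], low = nm[which(!hi)],
                 dip = dt$dip, p_value = dt$p_value, threshold = threshold),
            class = "xshadow_strata")
}

#' @export
print.xshadow_strata <- function(x, ...) {
  cat(sprintf("Patient strata at P(F) >= %.2f: %d high / %d low; dip = %s, p = %s\n",
              x$threshold, length(x$high), length(x$low),
              format(x$dip, digits = 3), format(x$p_value, digits = 3)))
  invisible(x)
}

#' Cross-tumour recurrence of connected-gene dysregulation
#'
#' Tests, per connected gene, whether its dysregulation co-occurs with
#' high-probability mutations more often than expected across tumour types.
#' Counts are the number of (mutated patient, tumour type) events where the
#' gene was dysregulated (P(G) at or above 0.5 in the tested direction)
#' while the patient's mutation had P(F) at or above 0.5; totals are the
#' corresponding numbers of trials.  The background rate is the pooled
#' maximum-likelihood estimate `sum(counts) / sum(totals)`, and each gene
#' gets an exact binomial upper-tail p-value with BH adjustment.  Up- and
#' down-regulation are analysed in separate calls.
#'
#' @param counts Matrix (connected genes x tumour types) of dysregulation
#'   co-occurrence counts, or a vector.
#' @param totals Matrix or vector of trial counts, recycled to match.
#' @return Data frame `neighbour`, `k`, `n`, `p_hat`, `p_value`, `q_value`,
#'   ordered as the input rows.
#' @export
recurrence_test <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (length(totals) == 1) totals <- matrix(totals, nrow(counts), ncol(counts))
  totals <- as.matrix(totals)
  if (is.null(dim(totals)) || !all(dim(totals) == dim(counts)))
    totals <- matrix(totals, nrow(counts), ncol(counts), byrow = TRUE)
  if (any(counts > totals))
    stop_xshadow("counts cannot exceed totals", "xshadow_domain_error")
  nm <- rownames(counts)
  if (is.null(nm)) nm <- paste0("gene", seq_len(nrow(counts)))
  k <- rowSums(counts)
  n <- rowSums(totals)
  keep <- n > 0
  if (!all(keep)) warning("rows with zero totals skipped")
  p_hat <- sum(counts[keep, , drop = FALSE]) / sum(totals[keep, , drop = FALSE])
  p <- rep(NA_real_, length(k))
  p[keep] <- stats::pbinom(k[keep] - 1, n[keep], p_hat, lower.tail = FALSE)
  data.frame(neighbour = nm, k = k, n = n, p_hat = p_hat, p_value = p,
             q_value = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag hypermutated tumours
#'
#' A tumour is flagged when its total mutation count strictly exceeds
#' `Q3 + multiplier * IQR` of the cohort's counts (linear-interpolation
#' quartiles).  The default multiplier of 4.5 is deliberately extreme: it
#' singles out ultramutated cases such as mismatch-repair-deficient or
#' POLE-mutant tumours whose abundant passenger mutations would otherwise
#' obscure per-mutation inference.
#'
#' @param mutation_counts Per-patient total mutation counts (at least 4
#'   patients).
#' @param multiplier IQR multiplier of the fence (default 4.5).
#' @return Logical vector, `TRUE` for hypermutators.
#' @export
flag_hypermutators <- function(mutation_counts, multiplier = 4.5) {
  x <- mutation_counts
  if (sum(!is.na(x)) < 4)
    stop_xshadow("need at least 4 patients", "xshadow_sample_size_error")
  fence <- tukey_fence(x, multiplier)
  x > fence["upper"]
}
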