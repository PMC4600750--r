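#' Exact posterior marginals for one mutated gene
#'
#' Sum-product belief propagation on the tree obtained by fixing the
#' regulation directions H.  Each leaf (mutation m, connected gene n) is
#' collapsed by summing the regulation state against its emission density;
#' per-mutation evidence is then aggregated into the gene-level indicator.
#' All message passing is carried out in log space, so thousands of connected
#' genes do not underflow.  The cost is linear in M x N and the marginals are
#' exact.
#'
#' @param sub Submodel (one mutated gene).
#' @param params An [xshadow_params()] object.
#' @param expected_counts If `TRUE`, additionally return the expected
#'   sufficient statistics used by the EM M-step.
#' @return A list of class `"xshadow_posteriors"`: `p_d` (posterior that the
#'   gene impacts expression), `p_f` (per-mutation posteriors, length M),
#'   `p_g` (M x N x 3 array of regulation-state posteriors) and `logZ`, the
#'   log marginal likelihood of the submodel.
#' @export
infer_posteriors <- function(sub, params, expected_counts = FALSE) {
  M <- nrow(sub$y); N <- ncol(sub$y)
  if (all(sub$miss)) {
    warning(sprintf("gene %s: no observed expression for any mutation; returning prior marginals",
                    sub$gene))
    p_f_prior <- params$theta_D * params$theta_F1_D1 +
      (1 - params$theta_D) * params$theta_F1_D0
    cpd1_up <- effective_G_cpd_matrix(params, sub$w, rep("up", N))
    cpd1_dn <- effective_G_cpd_matrix(params, sub$w, rep("down", N))
    up_leaf <- sub$Hm == "up"
    pg <- array(0, dim = c(M, N, 3))
    for (g in 1:3) {
      c1 <- ifelse(up_leaf, matrix(cpd1_up[g, ], M, N, byrow = TRUE),
                   matrix(cpd1_dn[g, ], M, N, byrow = TRUE))
      pg[, , g] <- p_f_prior * c1 + (1 - p_f_prior) * params$theta_G_F0[g]
    }
    return(structure(list(p_d = params$theta_D, p_f = rep(p_f_prior, M),
                          p_g = pg, logZ = 0), class = "xshadow_posteriors"))
  }

  lth0 <- log(params$theta_G_F0)
  cpd1_up <- effective_G_cpd_matrix(params, sub$w, rep("up", N))   # 3 x N
  cpd1_dn <- effective_G_cpd_matrix(params, sub$w, rep("down", N))
  up_leaf <- sub$Hm == "up"
  ld1 <- sub$ldens[, , 1, drop = FALSE]; dim(ld1) <- c(M, N)
  ld2 <- sub$ldens[, , 2, drop = FALSE]; dim(ld2) <- c(M, N)
  ld3 <- sub$ldens[, , 3, drop = FALSE]; dim(ld3) <- c(M, N)

  ## collapse each leaf: log sum_g P(G=g | F, H, w) p(y | G=g)
  lB0 <- logaddexp(logaddexp(ld1 + lth0[1], ld2 + lth0[2]), ld3 + lth0[3])
  lB1u <- logaddexp(
    logaddexp(sweep(ld1, 2, log(cpd1_up[1, ]), `+`),
              sweep(ld2, 2, log(cpd1_up[2, ]), `+`)),
    sweep(ld3, 2, log(cpd1_up[3, ]), `+`))
  lB1d <- logaddexp(
    logaddexp(sweep(ld1, 2, log(cpd1_dn[1, ]), `+`),
              sweep(ld2, 2, log(cpd1_dn[2, ]), `+`)),
    sweep(ld3, 2, log(cpd1_dn[3, ]), `+`))
  lB1 <- ifelse(up_leaf, lB1u, lB1d)
  dim(lB0) <- dim(lB1) <- c(M, N)

  ## per-mutation evidence under F=0 / F=1
  C0 <- rowSums(lB0); C1 <- rowSums(lB1)

  ## aggregate into D; lA[m, d+1] = log sum_f P(F=f | d) exp(C_f[m])
  lA0 <- logaddexp(log(1 - params$theta_F1_D0) + C0,
                   log(params$theta_F1_D0) + C1)
  lA1 <- logaddexp(log(1 - params$theta_F1_D1) + C0,
                   log(params$theta_F1_D1) + C1)
  S0 <- log(1 - params$theta_D) + sum(lA0)
  S1 <- log(params$theta_D) + sum(lA1)
  logZ <- logaddexp(S0, S1)
  p_d <- exp(S1 - logZ)

  ## cavity messages: log P(D=d, Y_{-m})
  B0 <- S0 - lA0
  B1 <- S1 - lA1

  ## joint posteriors P(F_m = f, D = d | Y)
  j00 <- B0 + log(1 - params$theta_F1_D0) + C0 - logZ
  j01 <- B0 + log(params$theta_F1_D0) + C1 - logZ
  j10 <- B1 + log(1 - params$theta_F1_D1) + C0 - logZ
  j11 <- B1 + log(params$theta_F1_D1) + C1 - logZ
  p_f <- exp(logaddexp(j01, j11))

  ## log P(F_m = f | Y) split for the leaf posteriors
  lU0 <- logaddexp(j00, j10)  # includes C0 - logZ
  lU1 <- logaddexp(j01, j11)

  ## leaf posteriors P(G_{m,n} = g, F_m = f | Y)
  pg <- array(0, dim = c(M, N, 3))
  if (expected_counts) {
    ec_G_F0 <- numeric(3)
    ec_G_F1_up <- numeric(3)
    ec_G_F1_down <- numeric(3)
  }
  obs <- !sub$miss
  for (g in 1:3) {
    ldg <- switch(g, ld1, ld2, ld3)
    pgf0 <- exp((lU0 - lB0) + ldg + lth0[g])
    lc1 <- ifelse(up_leaf, matrix(log(cpd1_up[g, ]), M, N, byrow = TRUE),
                  matrix(log(cpd1_dn[g, ]), M, N, byrow = TRUE))
    pgf1 <- exp((lU1 - lB1) + ldg + lc1)
    pg[, , g] <- pgf0 + pgf1
    if (expected_counts) {
      ## split the F=1 leaf counts between the dysregulated and null tables
      ## according to the edge-weight mixture responsibility
      r_up <- sub$w * params$theta_G_F1_up[g] / cpd1_up[g, ]
      r_dn <- sub$w * params$theta_G_F1_down[g] / cpd1_dn[g, ]
      r <- ifelse(up_leaf, matrix(r_up, M, N, byrow = TRUE),
                  matrix(r_dn, M, N, byrow = TRUE))
      ec_G_F0[g] <- sum(pgf0[obs]) + sum((pgf1 * (1 - r))[obs])
      contrib1 <- pgf1 * r
      ec_G_F1_up[g] <- sum(contrib1[obs & up_leaf])
      ec_G_F1_down[g] <- sum(contrib1[obs & !up_leaf])
    }
  }
  ## normalise away accumulated float error
  tot <- pg[, , 1] + pg[, , 2] + pg[, , 3]
  for (g in 1:3) pg[, , g] <- pg[, , g] / tot

  out <- list(p_d = p_d, p_f = unname(p_f), p_g = pg, logZ = logZ)
  if (expected_counts) {
    out$counts <- list(
      d1 = p_d,
      fd = matrix(c(sum(exp(j00)), sum(exp(j10)), sum(exp(j01)), sum(exp(j11))),
                  2, 2, dimnames = list(d = c("0", "1"), f = c("0", "1"))),
      g_f0 = ec_G_F0, g_f1_up = ec_G_F1_up, g_f1_down = ec_G_F1_down)
  }
  structure(out, class = "xshadow_posteriors")
}

#' Posterior marginals by exhaustive enumeration
#'
#' Brute-force reference for [infer_posteriors()]: sums the exponentiated
#' joint log-probability over every assignment of the latent variables with
#' log-sum-exp accumulation.  Only usable on tiny submodels; it exists to
#' cross-check the belief-propagation implementation.
#'
#' @inheritParams infer_posteriors
#' @return Same structure as [infer_posteriors()].
#' @export
enumerate_posteriors <- function(sub, params) {
  M <- nrow(sub$y); N <- ncol(sub$y)
  if (M * N > 12)
    stop_xshadow("enumeration guard: M * N must be <= 12", "xshadow_guard_error")

  n_leaf <- M * N
  A <- as.matrix(expand.grid(rep(list(1:3), n_leaf)))
  cpd1_up <- effective_G_cpd_matrix(params, sub$w, rep("up", N))
  cpd1_dn <- effective_G_cpd_matrix(params, sub$w, rep("down", N))
  leaf_m <- rep(seq_len(M), times = N)   # leaf j = (m, n) in column-major order
  leaf_n <- rep(seq_len(N), each = M)

  ## per-leaf state scores for f = 0 / 1
  S0 <- S1 <- matrix(0, n_leaf, 3)
  for (j in seq_len(n_leaf)) {
    m <- leaf_m[j]; n <- leaf_n[j]
    ld <- if (sub$miss[m, n]) c(0, 0, 0) else sub$ldens[m, n, ]
    cpd1 <- if (sub$Hm[m, n] == "up") cpd1_up[, n] else cpd1_dn[, n]
    S0[j, ] <- log(params$theta_G_F0) + ld
    S1[j, ] <- log(cpd1) + ld
  }

  f_grid <- as.matrix(expand.grid(rep(list(0:1), M)))
  n_assign <- 2 * nrow(f_grid) * nrow(A)
  if (n_assign > 5e7)
    stop_xshadow("enumeration guard: too many latent assignments",
                 "xshadow_guard_error")

  ## one log-probability vector per (d, f) combination, over all G assignments
  combos <- list()
  for (d in 0:1) {
    thf <- if (d == 1) params$theta_F1_D1 else params$theta_F1_D0
    lp_d <- log(if (d == 1) params$theta_D else 1 - params$theta_D)
    for (r in seq_len(nrow(f_grid))) {
      f <- f_grid[r, ]
      v <- rep(lp_d + sum(log(ifelse(f == 1, thf, 1 - thf))), nrow(A))
      for (j in seq_len(n_leaf)) {
        s <- if (f[leaf_m[j]] == 1) S1[j, ] else S0[j, ]
        v <- v + s[A[, j]]
      }
      combos[[length(combos) + 1]] <- list(d = d, f = f, v = v)
    }
  }

  all_v <- unlist(lapply(combos, `[[`, "v"))
  logZ <- logsumexp(all_v)
  p_d <- exp(logsumexp(unlist(lapply(combos, function(co)
    if (co$d == 1) co$v else numeric(0)))) - logZ)
  p_f <- vapply(seq_len(M), function(m) {
    exp(logsumexp(unlist(lapply(combos, function(co)
      if (co$f[m] == 1) co$v else numeric(0)))) - logZ)
  }, 0)
  pg <- array(0, dim = c(M, N, 3))
  for (j in seq_len(n_leaf)) {
    for (g in 1:3) {
      sel <- A[, j] == g
      pg[leaf_m[j], leaf_n[j], g] <-
        exp(logsumexp(unlist(lapply(combos, function(co) co$v[sel]))) - logZ)
    }
  }
  structure(list(p_d = p_d, p_f = p_f, p_g = pg, logZ = logZ),
            class = "xshadow_posteriors")
}

#' Learn model parameters by expectation-maximisation
#'
#' Pools expected sufficient statistics across all mutated-gene submodels
#' (the E-step is exact belief propagation per gene) and updates the
#' conditional probabilities as normalised expected-count ratios, with a
#' pseudo-count of 0.5 added to every count to keep parameters off the 0/1
#' boundary.  Identifiability constraints are re-imposed after each M-step by
#' label swaps.  One parameter set is shared by all genes in an analysis, so
#' statistical strength is borrowed across mutated genes.
#'
#' @param subs List of submodels (one per mutated gene).
#' @param init Starting [xshadow_params()].
#' @param max_iter,tol Iteration cap and relative log-likelihood convergence
#'   tolerance.
#' @param pseudo Pseudo-count added to every expected count in the M-step
#'   (equivalent to a Dirichlet(1 + pseudo) prior on each conditional
#'   probability table; `0` gives exact maximum-likelihood EM).
#' @return List of class `"xshadow_em"`: `params` (the fitted parameters),
#'   `loglik` (per-iteration total log marginal likelihood), `objective`
#'   (log marginal likelihood plus the log parameter prior — the quantity EM
#'   maximises, non-decreasing across iterations; equal to `loglik` when
#'   `pseudo = 0`), `n_iter`, `converged`, and `h_flipped` — `TRUE` when the
#'   identifiability correction relabelled all regulation directions (the
#'   caller must flip its H labels before scoring with the returned
#'   parameters).
#' @export
em_fit <- function(subs, init = xshadow_params(), max_iter = 100,
                   tol = 1e-5, pseudo = 0.5) {
  if (length(subs) == 0)
    stop_xshadow("no submodels to fit", "xshadow_domain_error")
  if (all(vapply(subs, function(s) all(s$miss), TRUE)))
    stop_xshadow("every submodel is empty of observed expression",
                 "xshadow_domain_error")
  log_prior <- function(p) {
    if (pseudo == 0) return(0)
    pseudo * (log(p$theta_D) + log(1 - p$theta_D) +
                log(p$theta_F1_D1) + log(1 - p$theta_F1_D1) +
                log(p$theta_F1_D0) + log(1 - p$theta_F1_D0) +
                sum(log(p$theta_G_F0)) + sum(log(p$theta_G_F1_up)) +
                sum(log(p$theta_G_F1_down)))
  }
  params <- init
  ll_trace <- obj_trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  h_flipped <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    ll <- 0
    c_d1 <- 0
    c_fd <- matrix(0, 2, 2)
    c_g_f0 <- c_g_f1_up <- c_g_f1_down <- numeric(3)
    for (sub in subs) {
      inf <- infer_posteriors(sub, params, expected_counts = TRUE)
      ll <- ll + inf$logZ
      c_d1 <- c_d1 + inf$counts$d1
      c_fd <- c_fd + inf$counts$fd
      c_g_f0 <- c_g_f0 + inf$counts$g_f0
      c_g_f1_up <- c_g_f1_up + inf$counts$g_f1_up
      c_g_f1_down <- c_g_f1_down + inf$counts$g_f1_down
    }
    ll_trace <- c(ll_trace, ll)
    obj <- ll + log_prior(params)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_old) && abs(obj - obj_old) <= tol * (abs(obj_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    obj_old <- obj

    n_g <- length(subs)
    theta_D <- (pseudo + c_d1) / (2 * pseudo + n_g)
    theta_F1_D0 <- (pseudo + c_fd[1, 2]) / (2 * pseudo + c_fd[1, 1] + c_fd[1, 2])
    theta_F1_D1 <- (pseudo + c_fd[2, 2]) / (2 * pseudo + c_fd[2, 1] + c_fd[2, 2])
    norm3 <- function(cc) (cc + pseudo) / sum(cc + pseudo)
    params <- structure(list(
      theta_D = theta_D, theta_F1_D1 = theta_F1_D1, theta_F1_D0 = theta_F1_D0,
      theta_G_F0 = norm3(c_g_f0),
      theta_G_F1_up = if (sum(c_g_f1_up) > 0) norm3(c_g_f1_up) else params$theta_G_F1_up,
      theta_G_F1_down = if (sum(c_g_f1_down) > 0) norm3(c_g_f1_down) else params$theta_G_F1_down),
      class = "xshadow_params")
    fix <- enforce_identifiability(params)
    params <- fix$params
    if (fix$flip_h) {
      ## relabel every direction together with the swapped tables: this is
      ## an exact relabeling of the model, so the likelihood is unchanged
      subs <- lapply(subs, function(s) {
        s$H <- ifelse(s$H == "up", "down", "up")
        s$Hm[] <- ifelse(s$Hm == "up", "down", "up")
        s
      })
      h_flipped <- !h_flipped
    }
  }
  structure(list(params = params, loglik = ll_trace, objective = obj_trace,
                 n_iter = it, converged = converged, h_flipped = h_flipped),
            class = "xshadow_em")
}

# re-impose the label conventions that give D and H their meaning; both
# corrections are exact relabelings (the D swap relabels D, the H swap must
# be accompanied by flipping every neighbour's direction label)
enforce_identifiability <- function(params) {
  if (params$theta_F1_D1 < params$theta_F1_D0) {
    tmp <- params$theta_F1_D1
    params$theta_F1_D1 <- params$theta_F1_D0
    params$theta_F1_D0 <- tmp
    params$theta_D <- 1 - params$theta_D
  }
  flip_h <- FALSE
  up_bad <- params$theta_G_F1_up[3] < params$theta_G_F0[3]
  down_bad <- params$theta_G_F1_down[1] < params$theta_G_F0[1]
  if (up_bad && down_bad &&
      params$theta_G_F1_down[3] >= params$theta_G_F0[3] &&
      params$theta_G_F1_up[1] >= params$theta_G_F0[1]) {
    tmp <- params$theta_G_F1_up
    params$theta_G_F1_up <- params$theta_G_F1_down
    params$theta_G_F1_down <- tmp
    flip_h <- TRUE
  }
  list(params = params, flip_h = flip_h)
}

#' @export
print.xshadow_em <- function(x, ...) {
  cat(sprintf("EM fit: %d iterations (%s), final log-likelihood %.3f\n",
              x$n_iter, if (x$converged) "converged" else "iteration cap",
              x$loglik[length(x$loglik)]))
  print(x$params)
  invisible(x)
}

#' @export
print.xshadow_posteriors <- function(x, ...) {
  cat(sprintf("Posteriors: P(D) = %.4f over %d mutation(s) x %d connected gene(s)\n",
              x$p_d, length(x$p_f), dim(x$p_g)[2]))
  invisible(x)
}
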