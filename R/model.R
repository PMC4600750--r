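#' Conditional-probability parameters of the mutation-impact model
#'
#' The model has five groups of conditional probabilities: the prior that a
#' recurrently mutated gene impacts expression (`theta_D`), the probability
#' that an individual mutation impacts expression given the gene-level
#' indicator (`theta_F1_D1`, `theta_F1_D0`), and the distributions of the
#' regulation state (down / neutral / up) of a connected gene given whether
#' the mutation is impactful and the gene's fixed regulation direction
#' (`theta_G_F0`, `theta_G_F1_up`, `theta_G_F1_down`).
#'
#' Two identifiability constraints give the latent indicators their intended
#' meaning: impactful genes must make impactful mutations more likely
#' (`theta_F1_D1 >= theta_F1_D0`), and impactful mutations must make the
#' H-direction regulation state more likely than under the null
#' (`theta_G_F1_up[3] >= theta_G_F0[3]`, mirrored for down-regulation).
#'
#' @param theta_D Prior probability that a mutated gene impacts expression.
#' @param theta_F1_D1,theta_F1_D0 P(mutation impactful | gene impacts / does
#'   not impact expression).
#' @param theta_G_F0 Length-3 simplex (down, neutral, up): regulation state
#'   distribution of a connected gene when the mutation has no impact.
#' @param theta_G_F1_up,theta_G_F1_down Length-3 simplexes for impactful
#'   mutations when the connected gene's direction is up (resp. down).
#' @return An object of class `"xshadow_params"`.
#' @export
xshadow_params <- function(theta_D = 0.5,
                           theta_F1_D1 = 0.8, theta_F1_D0 = 0.1,
                           theta_G_F0 = c(0.1, 0.8, 0.1),
                           theta_G_F1_up = c(0.05, 0.45, 0.5),
                           theta_G_F1_down = rev(theta_G_F1_up)) {
  p <- list(theta_D = theta_D, theta_F1_D1 = theta_F1_D1,
            theta_F1_D0 = theta_F1_D0,
            theta_G_F0 = theta_G_F0 / sum(theta_G_F0),
            theta_G_F1_up = theta_G_F1_up / sum(theta_G_F1_up),
            theta_G_F1_down = theta_G_F1_down / sum(theta_G_F1_down))
  validate_params(p)
  structure(p, class = "xshadow_params")
}

validate_params <- function(p) {
  scal <- c(p$theta_D, p$theta_F1_D1, p$theta_F1_D0)
  if (!all(scal > 0 & scal < 1))
    stop_xshadow("scalar parameters must lie strictly in (0, 1)",
                 "xshadow_domain_error")
  for (nm in c("theta_G_F0", "theta_G_F1_up", "theta_G_F1_down")) {
    v <- p[[nm]]
    if (length(v) != 3 || any(v <= 0) || abs(sum(v) - 1) > 1e-9)
      stop_xshadow(sprintf("'%s' must be a strictly positive 3-simplex", nm),
                   "xshadow_domain_error")
  }
  invisible(p)
}

#' @export
print.xshadow_params <- function(x, ...) {
  cat("Mutation-impact model parameters\n")
  cat(sprintf("  theta_D      = %.4f\n", x$theta_D))
  cat(sprintf("  theta_F1|D=1 = %.4f   theta_F1|D=0 = %.4f\n",
              x$theta_F1_D1, x$theta_F1_D0))
  tab <- rbind(`G|F=0` = x$theta_G_F0, `G|F=1,H=up` = x$theta_G_F1_up,
               `G|F=1,H=down` = x$theta_G_F1_down)
  colnames(tab) <- c("down", "neutral", "up")
  print(round(tab, 4))
  invisible(x)
}

#' Effective regulation-state tables for one connected gene
#'
#' The influence-graph weight `w` encodes prior confidence that the connected
#' gene really is regulated by the mutated gene.  It enters the model as a
#' convex mixture: with probability `w` an impactful mutation draws the
#' neighbour's state from the dysregulated table for direction `H`, otherwise
#' from the null table.  At `w = 1` the dysregulated table applies exactly;
#' at `w = 0` the neighbour is uninformative.
#'
#' @param params An [xshadow_params()] object.
#' @param w Edge weight in `[0, 1]`.
#' @param H Regulation direction, `"up"` or `"down"`.
#' @return List with components `F0` and `F1`, each a 3-simplex over
#'   (down, neutral, up).
#' @export
effective_G_cpd <- function(params, w, H = c("up", "down")) {
  H <- match.arg(H)
  if (!is.numeric(w) || length(w) != 1 || is.na(w) || w < 0 || w > 1)
    stop_xshadow("'w' must be a single value in [0, 1]", "xshadow_domain_error")
  th <- if (H == "up") params$theta_G_F1_up else params$theta_G_F1_down
  list(F0 = params$theta_G_F0,
       F1 = w * th + (1 - w) * params$theta_G_F0)
}

# matrix of F=1 regulation tables for all neighbours of a submodel: 3 x N
effective_G_cpd_matrix <- function(params, w, H) {
  thu <- params$theta_G_F1_up
  thd <- params$theta_G_F1_down
  th <- vapply(seq_along(w), function(n) {
    t1 <- if (H[n] == "up") thu else thd
    w[n] * t1 + (1 - w[n]) * params$theta_G_F0
  }, numeric(3))
  th
}

# Submodel of one mutated gene: M mutated patients x N connected genes, with
# precomputed per-component emission log-densities and mixture
# responsibilities for the observed expression values.
#
# When the directions are estimated from the data (H = NULL) and `loo` is
# TRUE, each leaf (m, n) is oriented by the direction estimated from the
# OTHER mutated patients (jackknife).  Plugging in a direction chosen from
# the same patient that is being scored would bias every leaf's likelihood
# ratio upwards — under a true null each neighbour's direction would be
# picked to match the scored patient's own noise.  The consensus direction
# over all patients is kept in `H` for reporting; `Hm` holds the per-leaf
# orientations actually used in inference.
build_submodel <- function(gene, y, w, mixtures, H = NULL, loo = TRUE) {
  y <- as.matrix(y)
  M <- nrow(y); N <- ncol(y)
  if (M < 1 || N < 1)
    stop_xshadow("a submodel needs at least one mutation and one connected gene",
                 "xshadow_domain_error")
  stopifnot(length(w) == N, length(mixtures) == N)
  miss <- !is.finite(y)
  ldens <- array(0, dim = c(M, N, 3))
  resp <- array(NA_real_, dim = c(M, N, 3))
  for (n in seq_len(N)) {
    obs <- !miss[, n]
    if (any(obs)) {
      ldens[obs, n, ] <- tmix_component_logdens(mixtures[[n]], y[obs, n])
      resp[obs, n, ] <- tmix_posterior(mixtures[[n]], y[obs, n])
    }
  }
  sub <- structure(list(gene = gene, patients = rownames(y),
                        neighbours = colnames(y), y = y, w = w,
                        miss = miss, ldens = ldens, resp = resp, H = H),
                   class = "xshadow_submodel")
  given_H <- !is.null(H)
  if (!given_H) sub$H <- estimate_H(sub)
  sub$Hm <- matrix(rep(sub$H, each = M), M, N)
  if (!given_H && loo && M > 1) {
    up <- resp[, , 3, drop = FALSE]; dim(up) <- c(M, N)
    dn <- resp[, , 1, drop = FALSE]; dim(dn) <- c(M, N)
    n_obs <- colSums(!miss)
    s_up <- colSums(up, na.rm = TRUE)
    s_dn <- colSums(dn, na.rm = TRUE)
    up0 <- up; up0[is.na(up0)] <- 0
    dn0 <- dn; dn0[is.na(dn0)] <- 0
    loo_up <- sweep(-up0, 2, s_up, `+`)
    loo_dn <- sweep(-dn0, 2, s_dn, `+`)
    hm <- ifelse(loo_up >= loo_dn, "up", "down")
    ## neighbours observed in fewer than two patients keep the consensus
    keep <- n_obs >= 2
    if (any(keep)) sub$Hm[, keep] <- hm[, keep]
  }
  sub
}

#' Estimate the regulation direction of each connected gene
#'
#' For each gene connected to the mutated gene, the direction variable H
#' (whether impactful mutations up- or down-regulate it) is estimated from
#' the mixture responsibilities of the observed expression values, averaged
#' over the mutated patients: the direction with the larger average
#' responsibility wins; exact ties are resolved to `"up"`.  Fixing H makes
#' the model a tree, which is what permits exact inference.
#'
#' @param sub A submodel built by the fitting pipeline.
#' @return Character vector of length N with values `"up"` / `"down"`.
#' @export
estimate_H <- function(sub) {
  up <- sub$resp[, , 3, drop = FALSE]; dim(up) <- dim(sub$y)
  down <- sub$resp[, , 1, drop = FALSE]; dim(down) <- dim(sub$y)
  up <- colMeans(up, na.rm = TRUE)
  down <- colMeans(down, na.rm = TRUE)
  up[is.nan(up)] <- 0; down[is.nan(down)] <- 0
  unname(ifelse(up >= down, "up", "down"))
}

#' Joint log-probability of a full latent assignment
#'
#' Evaluates the log of the model's joint distribution
#' `P(D) * prod_m P(F_m | D) * prod_{m,n} P(G_{m,n} | F_m, H_n) *
#' p(y_{m,n} | G_{m,n})` at a complete assignment of the latent variables.
#' Leaves with missing expression contribute their regulation-state prior but
#' no density term.
#'
#' @param sub Submodel.
#' @param params An [xshadow_params()] object.
#' @param d 0/1 gene-level indicator.
#' @param f 0/1 vector of per-mutation indicators, length M.
#' @param g_states Integer matrix M x N of regulation states (1 = down,
#'   2 = neutral, 3 = up).
#' @return The joint log-probability (a scalar).
#' @export
joint_log_prob <- function(sub, params, d, f, g_states) {
  M <- nrow(sub$y); N <- ncol(sub$y)
  g_states <- matrix(as.integer(g_states), M, N)
  if (!d %in% c(0, 1) || !all(f %in% c(0, 1)) || !all(g_states %in% 1:3))
    stop_xshadow("invalid latent state codes", "xshadow_domain_error")
  if (length(f) != M)
    stop_xshadow("'f' must have one entry per mutation", "xshadow_domain_error")
  thf <- if (d == 1) params$theta_F1_D1 else params$theta_F1_D0
  lp <- log(if (d == 1) params$theta_D else 1 - params$theta_D) +
    sum(log(ifelse(f == 1, thf, 1 - thf)))
  cpd1_up <- effective_G_cpd_matrix(params, sub$w, rep("up", N))
  cpd1_dn <- effective_G_cpd_matrix(params, sub$w, rep("down", N))
  for (m in seq_len(M)) {
    for (n in seq_len(N)) {
      g <- g_states[m, n]
      cpd1 <- if (sub$Hm[m, n] == "up") cpd1_up[g, n] else cpd1_dn[g, n]
      cpd <- if (f[m] == 1) cpd1 else params$theta_G_F0[g]
      lp <- lp + log(cpd)
      if (!sub$miss[m, n]) lp <- lp + sub$ldens[m, n, g]
    }
  }
  lp
}
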