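# Exact oracle for Hartigan's dip statistic on tiny samples, by linear
# programming over the band formulation: a unimodal CDF within sup-distance
# d of the ECDF exists iff its values v_k at the unique sample points fit
# the band [up_k - d, lo_k + d] (lo/up = ECDF left/right limits) with
# convexity left of the mode, concavity right of it, monotonicity, and the
# slope-coupling constraints across the modal gap (the mode may fall
# between sample points or exactly on one, where the CDF may jump).  Each
# mode configuration is one or two small LPs (boot::simplex); the dip is
# the minimal feasible d over all configurations.

dip_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  t <- unique(x)
  cnt <- as.integer(table(match(x, t)))
  J <- length(t)
  if (J == 1) return(0)
  up <- cumsum(cnt) / n
  lo <- c(0, up[-J])

  ## variable layout: v_1..v_J, d, (p for at-knot configs)
  ## rows carry a type: "le" goes into A1 x <= b1, "ge" into A2 x >= b2
  ## (boot::simplex requires non-negative right-hand sides)
  solve_lp <- function(extra_p, build) {
    nv <- J + 1 + as.integer(extra_p)
    rows <- build()
    typ <- vapply(rows, `[[`, "", 3)
    A1 <- do.call(rbind, lapply(rows[typ == "le"], `[[`, 1))
    b1 <- vapply(rows[typ == "le"], `[[`, 0, 2)
    A2 <- do.call(rbind, lapply(rows[typ == "ge"], `[[`, 1))
    b2 <- vapply(rows[typ == "ge"], `[[`, 0, 2)
    obj <- c(rep(0, J), 1, if (extra_p) 0)
    out <- tryCatch(
      boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    maxi = FALSE),
      error = function(e) NULL)
    if (is.null(out) || out$solved != 1) return(Inf)
    out$value
  }

  e <- function(i, nv) { z <- rep(0, nv); z[i] <- 1; z }
  band_rows <- function(nv, relaxed_at = 0) {
    rows <- list()
    for (k in seq_len(J)) {
      ## v_k - d <= lo_k   (or up_k at a jump knot)
      ub <- if (k == relaxed_at) up[k] else lo[k]
      rows[[length(rows) + 1]] <- list(e(k, nv) - e(J + 1, nv), ub, "le")
      ## v_k + d >= up_k
      rows[[length(rows) + 1]] <- list(e(k, nv) + e(J + 1, nv), up[k], "ge")
      ## v_k <= 1
      rows[[length(rows) + 1]] <- list(e(k, nv), 1, "le")
    }
    for (k in seq_len(J - 1))   # monotone
      rows[[length(rows) + 1]] <- list(e(k, nv) - e(k + 1, nv), 0, "le")
    rows
  }
  ## slope(k1 -> k2) <= slope(k2 -> k3) as a row (convexity of the triple)
  convex_row <- function(k1, k2, k3, nv) {
    h1 <- t[k2] - t[k1]; h2 <- t[k3] - t[k2]
    z <- rep(0, nv)
    z[k1] <- -h2; z[k2] <- h1 + h2; z[k3] <- -h1
    list(z, 0, "le")
  }
  concave_row <- function(k1, k2, k3, nv) {
    r <- convex_row(k1, k2, k3, nv)
    list(-r[[1]], 0, "le")
  }

  best <- Inf
  ## between-knot splits: prefix 1..i convex, suffix (i+1)..J concave
  for (i in 0:J) {
    variants <- list()
    base <- function(nv) {
      rows <- band_rows(nv)
      if (i >= 3) for (k in 1:(i - 2))
        rows[[length(rows) + 1]] <- convex_row(k, k + 1, k + 2, nv)
      if (i <= J - 3) for (k in (i + 1):(J - 2))
        rows[[length(rows) + 1]] <- concave_row(k, k + 1, k + 2, nv)
      rows
    }
    if (i >= 2 && i <= J - 1) {
      variants$A <- function(nv) c(base(nv), list(convex_row(i - 1, i, i + 1, nv)))
    }
    if (i >= 1 && i <= J - 2) {
      variants$B <- function(nv) c(base(nv), list(concave_row(i, i + 1, i + 2, nv)))
    }
    if (length(variants) == 0) variants$plain <- base
    for (bf in variants)
      best <- min(best, solve_lp(FALSE, function() bf(J + 1)))
  }
  ## at-knot modes: jump at t_j
  for (j in seq_len(J)) {
    nv <- J + 2   # extra pre-jump variable p at index J + 2
    rows <- band_rows(nv, relaxed_at = j)
    if (j >= 3) for (k in 1:(j - 2))
      rows[[length(rows) + 1]] <- convex_row(k, k + 1, k + 2, nv)
    if (j <= J - 2) for (k in j:(J - 2))
      rows[[length(rows) + 1]] <- concave_row(k, k + 1, k + 2, nv)
    if (j >= 2) {
      p <- J + 2
      ## v_{j-1} <= p ; p <= v_j ; p - d <= lo_j
      rows[[length(rows) + 1]] <- list(e(j - 1, nv) - e(p, nv), 0, "le")
      rows[[length(rows) + 1]] <- list(e(p, nv) - e(j, nv), 0, "le")
      rows[[length(rows) + 1]] <- list(e(p, nv) - e(J + 1, nv), lo[j], "le")
      if (j >= 3) {
        ## p >= v_{j-1} + slope(t_{j-2} -> t_{j-1}) * (t_j - t_{j-1})
        h0 <- t[j - 1] - t[j - 2]; h1 <- t[j] - t[j - 1]
        z <- rep(0, nv)
        z[j - 1] <- h0 + h1; z[j - 2] <- -h1; z[p] <- -h0
        rows[[length(rows) + 1]] <- list(z, 0, "le")
      }
    }
    best <- min(best, solve_lp(TRUE, function() rows))
  }
  best
}
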