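# Chance-constrained stochastic DEA, output oriented, variable returns to
# scale. For DMU o at risk level alpha the model is
#
#   max theta  over (lambda >= 0, sum lambda = 1)
#   s.t.  sum_j lambda_j xbar_ij
#           - qn(alpha) * sqrt( sum_{j!=o} lambda_j^2 sI_ij^2
#                               + (lambda_o - 1)^2 sI_io^2 )  <=  xbar_io
#         sum_j lambda_j ybar_rj
#           + qn(alpha) * sqrt( sum_{j!=o} lambda_j^2 sO_rj^2
#                               + (lambda_o - theta)^2 sO_ro^2 ) >= theta ybar_ro
#
# where qn is the standard normal quantile. The stochastic efficiency of DMU o
# is 1/theta. qn(alpha) = 0 (alpha = 0.5) or all-zero SDs reduce the model to
# the deterministic output-oriented BCC linear program, solved exactly.
# Otherwise the program is solved by a multistart augmented-Lagrangian local
# solver with analytic gradients; for alpha < 0.5 the feasible region is
# convex, so the local solution from the always-feasible point lambda = e_o
# is global. Every returned solution is re-certified against the exact
# constraints before being emitted. (lambda = e_o, theta = 1) is feasible for
# every alpha, hence theta* >= 1 and efficiency lies in (0, 1].

#' The default risk-level grid
#'
#' @return numeric vector `c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.8, 0.9, 0.95)`.
#' @export
default_alpha_grid <- function() c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.8, 0.9, 0.95)

#' Standard normal quantile
#'
#' The inverse standard normal distribution function evaluated at `alpha`.
#'
#' @param alpha probability strictly between 0 and 1.
#' @return the real z with `pnorm(z) == alpha`.
#' @export
normal_quantile <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop_hazedea("alpha must lie strictly between 0 and 1", "config")
  }
  stats::qnorm(alpha)
}

resolve_dmu <- function(panel, o) {
  if (is.character(o)) {
    i <- match(o, panel$dmu_ids)
    if (is.na(i)) stop_hazedea(sprintf("unknown DMU: %s", o), "config")
    return(i)
  }
  o <- as.integer(o)
  if (o < 1L || o > length(panel$dmu_ids)) stop_hazedea("DMU index out of range", "config")
  o
}

# Internal: scale panel data so constraints are O(1) for DMU o. Radial DEA
# constraints are invariant to per-column positive rescaling, and the sqrt
# variance terms rescale with their column.
scaled_data <- function(panel, o) {
  X <- panel$input_mean; SX <- panel$input_sd
  Y <- panel$output_mean; SY <- panel$output_sd
  cx <- ifelse(X[o, ] > 0, X[o, ], pmax(colMeans(X), 1e-8))
  cy <- Y[o, ]
  if (any(cy <= 0)) {
    stop_hazedea("evaluated DMU has a non-positive output mean", "degenerate")
  }
  list(X = sweep(X, 2, cx, "/"), A = sweep(SX, 2, cx, "/")^2,
       Y = sweep(Y, 2, cy, "/"), B = sweep(SY, 2, cy, "/")^2,
       Xo = X[o, ] / cx, Yo = rep(1, length(cy)), o = o,
       n = nrow(X), m = ncol(X), s = ncol(Y))
}

# Exact input-constraint values (scaled): c_i(lambda) <= 0 means feasible.
input_cons <- function(d, z, lam) {
  u <- lam; u[d$o] <- lam[d$o] - 1
  q <- colSums(u^2 * d$A)
  drop(crossprod(lam, d$X)) - z * sqrt(q) - d$Xo
}

# Largest theta satisfying the output chance constraints for fixed lambda,
# by the exact root of the defining quadratic per output (see vignette).
# Returns NA if no theta is feasible, `cap` if unbounded above.
theta_given_lambda <- function(d, z, lam, cap = 1e6) {
  v2 <- lam^2; v2[d$o] <- NA  # placeholder; handled per output below
  th <- rep(NA_real_, d$s)
  for (r in seq_len(d$s)) {
    A <- sum(lam * d$Y[, r])
    ybar <- d$Yo[r]
    b <- d$B[d$o, r]
    B <- sum(lam[-d$o]^2 * d$B[-d$o, r])
    lo <- lam[d$o]
    if (z == 0 || (b == 0 && B == 0)) { th[r] <- A / ybar; next }
    z2 <- z^2
    c2 <- ybar^2 - z2 * b
    c1 <- -2 * A * ybar + 2 * z2 * b * lo
    c0 <- A^2 - z2 * B - z2 * b * lo^2
    disc <- max(c1^2 - 4 * c2 * c0, 0)
    if (z > 0) {
      if (c2 <= 0) { th[r] <- cap; next }
      r2 <- (-c1 + sqrt(disc)) / (2 * c2)
      th[r] <- max(A / ybar, r2)
    } else {
      if (c2 > 0) {
        th[r] <- (-c1 - sqrt(disc)) / (2 * c2)     # smaller root, <= A/ybar
      } else if (c2 < 0) {
        r1 <- (-c1 + sqrt(disc)) / (2 * c2)        # note c2 < 0: this is smaller
        r2 <- (-c1 - sqrt(disc)) / (2 * c2)
        lohi <- sort(c(r1, r2))
        if (lohi[2] <= A / ybar) th[r] <- lohi[2] else return(NA_real_)
      } else {
        # degenerate linear case: fall back to a numeric scan below A/ybar
        f <- function(t) t * ybar - A + abs(z) * sqrt(B + (lo - t)^2 * b)
        g <- seq(A / ybar, max(A / ybar - 5, 1e-6), length.out = 200)
        ok <- g[vapply(g, f, 0) <= 0]
        if (!length(ok)) return(NA_real_)
        th[r] <- ok[1]
      }
    }
  }
  min(pmin(th, cap))
}

# Exact constraint violation of a candidate (scaled units, i.e. relative to
# the evaluated DMU's own levels). Output constraint: d_r <= 0 feasible.
candidate_violation <- function(d, z, lam, theta) {
  ci <- input_cons(d, z, lam)
  v <- lam; v[d$o] <- lam[d$o] - theta
  w <- colSums(v^2 * d$B)
  dr <- theta * d$Yo - drop(crossprod(lam, d$Y)) - z * sqrt(w)
  max(c(ci, dr, abs(sum(lam) - 1)))
}

# Augmented-Lagrangian local solve from one start. Data already scaled.
al_solve <- function(d, z, lam0, th0, cap = 1e6,
                     inner_maxit = 80, outer = 6, eps = 1e-18) {
  n <- d$n
  Xo <- d$Xo; Yo <- d$Yo
  yc <- numeric(d$m); yd <- numeric(d$s); ye <- 0
  rho <- 100
  par <- c(lam0, th0)
  lower <- c(rep(0, n), 1e-6)
  upper <- c(rep(Inf, n), cap)
  pieces <- function(par) {
    lam <- par[seq_len(n)]; th <- par[n + 1L]
    u <- lam; u[d$o] <- lam[d$o] - 1
    q <- colSums(u^2 * d$A); si <- sqrt(q + eps)
    ci <- drop(crossprod(lam, d$X)) - z * si - Xo
    v <- lam; v[d$o] <- lam[d$o] - th
    w <- colSums(v^2 * d$B); ti <- sqrt(w + eps)
    dr <- th * Yo - drop(crossprod(lam, d$Y)) - z * ti
    list(lam = lam, th = th, u = u, si = si, ci = ci,
         v = v, ti = ti, dr = dr, e = sum(lam) - 1)
  }
  fn <- function(par) {
    p <- pieces(par)
    mc <- pmax(0, yc + rho * p$ci); md <- pmax(0, yd + rho * p$dr)
    -p$th + ye * p$e + rho / 2 * p$e^2 +
      (sum(mc^2) - sum(yc^2)) / (2 * rho) +
      (sum(md^2) - sum(yd^2)) / (2 * rho)
  }
  gr <- function(par) {
    p <- pieces(par)
    mc <- pmax(0, yc + rho * p$ci); md <- pmax(0, yd + rho * p$dr)
    gl <- rep(ye + rho * p$e, n)
    if (any(mc > 0)) {
      gl <- gl + drop(d$X %*% mc) - z * p$u * drop(d$A %*% (mc / p$si))
    }
    gth <- -1
    if (any(md > 0)) {
      gl <- gl - drop(d$Y %*% md) - z * p$v * drop(d$B %*% (md / p$ti))
      gth <- gth + sum(md * (Yo + z * p$v[d$o] * d$B[d$o, ] / p$ti))
    }
    c(gl, gth)
  }
  viol_prev <- Inf
  for (k in seq_len(outer)) {
    res <- try(stats::optim(par, fn, gr, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = inner_maxit)), silent = TRUE)
    if (inherits(res, "try-error")) break
    par <- res$par
    p <- pieces(par)
    viol <- max(c(p$ci, p$dr, abs(p$e), 0))
    yc <- pmax(0, yc + rho * p$ci)
    yd <- pmax(0, yd + rho * p$dr)
    ye <- ye + rho * p$e
    if (viol < 1e-10) break
    if (viol > 0.25 * viol_prev) rho <- min(rho * 10, 1e9)
    viol_prev <- viol
  }
  list(lambda = par[seq_len(n)], theta = par[n + 1L])
}

# Project a raw lambda onto the simplex face (clip + renormalize), check the
# exact input constraints, and recompute the exact best theta. Returns NULL
# when the polished point is input-infeasible beyond tolerance.
polish_candidate <- function(d, z, lam, cap = 1e6, tol = 1e-9) {
  lam <- pmax(lam, 0)
  if (!is.finite(sum(lam)) || sum(lam) <= 0) return(NULL)
  # solver output can carry infeasible dust in near-zero coordinates; try the
  # point as-is, then with progressively clipped small entries
  for (clip in c(0, 1e-8, 1e-6, 1e-4)) {
    l2 <- lam
    l2[l2 < clip * max(l2)] <- 0
    l2 <- l2 / sum(l2)
    ci <- input_cons(d, z, l2)
    if (max(ci) > tol) next
    th <- theta_given_lambda(d, z, l2, cap = cap)
    if (is.na(th) || th < 1e-6) next
    return(list(lambda = l2, theta = th, violation = max(max(ci), 0)))
  }
  NULL
}

new_ccdea_result <- function(panel, o, alpha, theta, lambda, status,
                             n_starts_used, violation) {
  structure(list(dmu = panel$dmu_ids[o], o = o, alpha = alpha,
                 theta = theta, efficiency = 1 / theta,
                 lambda = stats::setNames(lambda, panel$dmu_ids),
                 status = status, n_starts_used = n_starts_used,
                 violation = violation),
            class = "ccdea_result")
}

#' @export
print.ccdea_result <- function(x, ...) {
  cat(sprintf("<ccdea_result> DMU %s  alpha=%s  theta=%.6f  efficiency=%.6f  [%s]\n",
              x$dmu, format(x$alpha), x$theta, x$efficiency, x$status))
  invisible(x)
}

#' Deterministic output-oriented BCC efficiency
#'
#' Solves the variable-returns-to-scale linear program
#' `max theta` s.t. `sum lambda x <= x_o`, `sum lambda y >= theta y_o`,
#' `sum lambda = 1`, `lambda >= 0` on the panel means (all SDs ignored).
#' This is the zero-noise / alpha = 0.5 reduction of the stochastic model.
#'
#' @param panel an [indicator_panel()].
#' @param o DMU index or id to evaluate.
#' @return a `ccdea_result` (with `alpha = NA`).
#' @export
solve_bcc_output <- function(panel, o) {
  o <- resolve_dmu(panel, o)
  d <- scaled_data(panel, o)
  n <- d$n; m <- d$m; s <- d$s
  # variables: (theta, lambda_1..lambda_n)
  a <- c(1, rep(0, n))
  A1 <- cbind(0, t(d$X))                 # m x (n+1): sum lambda x <= x_o
  b1 <- d$Xo
  A2 <- cbind(-d$Yo, t(d$Y))             # s x (n+1): -theta y_o + sum lambda y >= 0
  b2 <- rep(0, s)
  A3 <- matrix(c(0, rep(1, n)), 1)
  b3 <- 1
  run_lp <- function(b1p) {
    boot::simplex(a = a, A1 = A1, b1 = b1p, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = TRUE,
                  n.iter = 100 * (n + m + s))
  }
  # degenerate DEA polytopes occasionally break the tableau pivoting; retry
  # with a deterministic, escalating right-hand-side perturbation, then
  # recompute theta exactly from the returned lambda
  sol <- try(run_lp(b1), silent = TRUE)
  k <- 0L
  while ((inherits(sol, "try-error") || sol$solved != 1) && k < 6L) {
    k <- k + 1L
    pert <- with_local_seed(sub_seed(1234L, 17L * o + k),
                            1 + 10^(-9 + k) * stats::runif(m))
    sol <- try(run_lp(b1 * pert), silent = TRUE)
  }
  if (inherits(sol, "try-error") || sol$solved == -1) {
    stop_hazedea("BCC LP failed (should not happen: lambda = e_o is feasible)",
                 "solver")
  }
  lam <- sol$soln[-1]
  theta <- sol$soln[1]
  # clean the basic solution and recompute theta exactly from lambda: the
  # polished value is the certified one (a perturbed retry can inflate the
  # raw LP objective by the perturbation size)
  pc <- polish_candidate(d, 0, lam, tol = 1e-7)
  if (!is.null(pc)) {
    lam <- pc$lambda; theta <- pc$theta
  }
  # the self-reference point theta = 1 is exact; prefer it over a solution
  # that only reaches 1 up to LP round-off and feasibility dust
  if (theta <= 1 + 1e-7) {
    e_o <- numeric(n); e_o[o] <- 1
    pe <- polish_candidate(d, 0, e_o, tol = 1e-9)
    if (!is.null(pe) && pe$theta >= theta - 1e-7) {
      lam <- pe$lambda; theta <- pe$theta
    }
  }
  viol <- candidate_violation(d, 0, lam, theta)
  new_ccdea_result(panel, o, NA_real_, theta, lam, "optimal", 1L, max(viol, 0))
}

#' Solve the chance-constrained stochastic DEA program
#'
#' Maximizes the output-expansion factor theta for DMU `o` at risk level
#' `alpha`, with the per-DMU variance terms of the chance constraints taken
#' exactly as modelled (independence across DMUs; the evaluated DMU's own
#' terms carry `(lambda_o - 1)^2` on inputs and `(lambda_o - theta)^2` on the
#' outputs). The stochastic efficiency is `1/theta`.
#'
#' `alpha = 0.5` (zero quantile) and all-zero SDs reduce exactly to
#' [solve_bcc_output()] and are solved as that LP. `alpha < 0.5` gives a
#' convex feasible region: the augmented-Lagrangian solve from the
#' always-feasible point `lambda = e_o` is globally valid. `alpha > 0.5` is
#' nonconvex and solved by multistart (e_o, the BCC solution, any supplied
#' warm starts, plus `n_random_starts` random simplex points drawn from a
#' seed derived deterministically from `seed`, `o` and `alpha`); the best
#' certified-feasible candidate is returned with status `"multistart-best"`.
#' Ties in theta (within 1e-9) break toward the smallest `||lambda||_2`.
#'
#' @param panel an [indicator_panel()].
#' @param o DMU index or id.
#' @param alpha risk level strictly between 0 and 1.
#' @param n_random_starts random multistart points for the nonconvex case.
#' @param seed integer; all randomness derives from it.
#' @param warm_starts optional list of lambda vectors used as extra starts
#'   (e.g. the solution at a neighbouring alpha, or the pre-deletion
#'   solution in an influence scan).
#' @param cap upper bound on theta for solver stability.
#' @return a `ccdea_result`: theta, efficiency = 1/theta, lambda, alpha,
#'   solver status, number of starts used, and the certified maximum
#'   constraint violation (relative to the evaluated DMU's own levels).
#' @export
solve_ccdea <- function(panel, o, alpha, n_random_starts = 6L, seed = 1L,
                        warm_starts = NULL, cap = 1e6) {
  o <- resolve_dmu(panel, o)
  z <- normal_quantile(alpha)
  no_noise <- max(panel$input_sd) == 0 && max(panel$output_sd) == 0
  if (z == 0 || no_noise) {
    res <- solve_bcc_output(panel, o)
    res$alpha <- alpha
    return(res)
  }
  d <- scaled_data(panel, o)
  n <- d$n
  e_o <- numeric(n); e_o[o] <- 1

  starts <- list(e_o)
  bcc <- try(solve_bcc_output(panel, o), silent = TRUE)
  if (!inherits(bcc, "try-error")) starts <- c(starts, list(unname(bcc$lambda)))
  if (z > 0) {
    rnd <- with_local_seed(sub_seed(seed, o * 131L + as.integer(round(1e4 * alpha))), {
      lapply(seq_len(n_random_starts), function(i) {
        w <- stats::rexp(n); w / sum(w)
      })
    })
    starts <- c(starts, rnd)
  }
  if (!is.null(warm_starts)) starts <- c(warm_starts, starts)

  cands <- list()
  # warm/deterministic starts are themselves candidates after exact polish:
  for (st in starts) {
    pc <- polish_candidate(d, z, st, cap = cap)
    if (!is.null(pc)) cands[[length(cands) + 1L]] <- pc
  }
  n_used <- 0L
  for (st in starts) {
    th0 <- {
      pc <- polish_candidate(d, z, st, cap = cap)
      if (!is.null(pc)) pc$theta else 1
    }
    fit <- al_solve(d, z, st, th0, cap = cap)
    n_used <- n_used + 1L
    pc <- polish_candidate(d, z, fit$lambda, cap = cap)
    if (!is.null(pc)) cands[[length(cands) + 1L]] <- pc
  }
  # lambda = e_o with theta = theta*(e_o) is always feasible; make sure it is
  # present even if every numerical start failed to certify.
  pc <- polish_candidate(d, z, e_o, cap = cap)
  if (!is.null(pc)) cands[[length(cands) + 1L]] <- pc
  if (!length(cands)) {
    stop_hazedea("no feasible candidate found (the self-reference point should always certify)",
                 "solver")
  }
  thetas <- vapply(cands, `[[`, 0, "theta")
  best <- max(thetas)
  tied <- which(thetas >= best - 1e-9)
  norms <- vapply(cands[tied], function(cn) sum(cn$lambda^2), 0)
  pick <- cands[[tied[which.min(norms)]]]
  viol <- candidate_violation(d, z, pick$lambda, pick$theta)
  status <- if (z < 0) "optimal" else "multistart-best"
  new_ccdea_result(panel, o, alpha, pick$theta, pick$lambda, status,
                   n_used, max(viol, 0))
}

#' Stochastic efficiency across a grid of risk levels
#'
#' Solves [solve_ccdea()] for one DMU at each alpha in ascending order,
#' warm-starting each level with the previous level's solution. Because the
#' feasible sets are nested as the normal quantile grows, the warm start
#' guarantees a numerically non-decreasing theta profile (equivalently:
#' efficiency never increases with the risk level). Per-alpha
#' solver errors are recorded in the `status` column without aborting the
#' sweep.
#'
#' @param panel an [indicator_panel()].
#' @param o DMU index or id.
#' @param alphas risk levels (default [default_alpha_grid()]).
#' @param ... passed to [solve_ccdea()].
#' @return a `data.frame` with columns `dmu`, `alpha`, `theta`, `efficiency`,
#'   `status`, `violation`; the per-alpha lambda vectors are attached as the
#'   `"lambdas"` attribute (a named list).
#' @export
efficiency_profile <- function(panel, o, alphas = default_alpha_grid(), ...) {
  o <- resolve_dmu(panel, o)
  alphas <- sort(alphas)
  rows <- list(); lams <- list()
  warm <- NULL
  for (a in alphas) {
    res <- try(solve_ccdea(panel, o, a, warm_starts = warm, ...), silent = TRUE)
    if (inherits(res, "try-error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        dmu = panel$dmu_ids[o], alpha = a, theta = NA_real_,
        efficiency = NA_real_, status = "error", violation = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    warm <- list(unname(res$lambda))
    lams[[as.character(a)]] <- res$lambda
    rows[[length(rows) + 1L]] <- data.frame(
      dmu = res$dmu, alpha = a, theta = res$theta, efficiency = res$efficiency,
      status = res$status, violation = res$violation, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "lambdas") <- lams
  out
}

#' Brute-force grid oracle for the stochastic DEA program
#'
#' Independent check of [solve_ccdea()] on small instances: enumerates
#' lambda on the unit simplex with the given step, keeps the points that
#' satisfy the exact input chance constraints, and maximizes theta at each
#' kept point by 1-D bisection on the output chance constraint. Intended for
#' n <= 4 DMUs (the grid grows combinatorially).
#'
#' @param panel an [indicator_panel()].
#' @param o DMU index or id.
#' @param alpha risk level.
#' @param step simplex grid step (default 0.01).
#' @param cap upper bound on theta.
#' @return list with `theta` (grid optimum) and `lambda` (arg max).
#' @export
ccdea_grid_oracle <- function(panel, o, alpha, step = 0.01, cap = 1e6) {
  o <- resolve_dmu(panel, o)
  z <- normal_quantile(alpha)
  d <- scaled_data(panel, o)
  n <- d$n
  if (n > 4L) stop_hazedea("grid oracle supports at most 4 DMUs", "config")
  k <- round(1 / step)
  # integer compositions of k into n parts
  G <- if (n == 1L) matrix(k, 1, 1) else {
    grid <- do.call(expand.grid, rep(list(0:k), n - 1L))
    grid <- grid[rowSums(grid) <= k, , drop = FALSE]
    as.matrix(cbind(grid, k - rowSums(grid)))
  }
  L <- G / k
  # exact input feasibility, vectorized over grid rows
  U2 <- L^2; U2[, o] <- (L[, o] - 1)^2
  lhs <- L %*% d$X - z * sqrt(U2 %*% d$A)
  feas <- rowSums(sweep(lhs, 2, d$Xo + 1e-9, ">")) == 0
  if (!any(feas)) stop_hazedea("no grid point satisfies the input constraints", "solver")
  L <- L[feas, , drop = FALSE]
  g <- nrow(L)
  L2 <- L^2
  # bisection for the largest feasible theta, vectorized across grid points
  out_ok <- function(th) {
    # th: vector of length g; TRUE where all output constraints hold
    ok <- rep(TRUE, g)
    for (r in seq_len(d$s)) {
      A <- drop(L %*% d$Y[, r])
      B <- drop(L2 %*% d$B[, r]) - L2[, o] * d$B[o, r]
      w <- B + (L[, o] - th)^2 * d$B[o, r]
      ok <- ok & (th * d$Yo[r] - A - z * sqrt(w) <= 1e-12)
    }
    ok
  }
  lo <- rep(NA_real_, g)
  for (r in seq_len(d$s)) {
    A <- drop(L %*% d$Y[, r])
    lo_r <- A / d$Yo[r]
    lo <- if (r == 1) lo_r else pmin(lo, lo_r)
  }
  if (z < 0) {
    # below 0.5 the buffer tightens; start from a point known feasible
    lo[!out_ok(lo)] <- NA
  }
  hi <- pmax(lo, 1) * 2 + 1
  for (i in 1:60) {
    still <- !is.na(lo) & out_ok(hi) & hi < cap
    if (!any(still)) break
    lo[still] <- hi[still]
    hi[still] <- hi[still] * 2
  }
  hi <- pmin(hi, cap)
  keep <- !is.na(lo)
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    ok <- out_ok(mid) & keep
    lo[ok] <- mid[ok]
    hi[!ok & keep] <- mid[!ok & keep]
  }
  if (!any(keep)) stop_hazedea("no output-feasible grid point", "solver")
  best <- which.max(ifelse(keep, lo, -Inf))
  list(theta = lo[best], lambda = stats::setNames(L[best, ], panel$dmu_ids))
}
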