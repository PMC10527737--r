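# Shared fixtures and independent oracles, all built in code.

toy_cd <- function() {
  d <- tibble::tibble(
    z = c(1, 2, 3, 4, 5, 6),
    delta = c(1, 0, 1, 1, 0, 1),
    x1 = c(0.9, 2.1, 2.9, 4.2, 5.1, 5.8),
    x2 = c(0.3, -0.2, 0.1, 0.4, -0.5, 0.2),
    t1 = c(0.05, 0.25, 0.4, 0.6, 0.75, 0.95))
  censored_data(d, parametric = c("x1", "x2"), nonparametric = "t1")
}

sim_fixture <- function(n, cl, seed, q = 2) {
  simulate_plam(n = n, cl = cl, q = q, seed = seed)
}

# Exhaustive O(n^2) nearest-neighbour imputation oracle: literal
# distance-sort-then-average, no shortcuts shared with the implementation.
knn_oracle <- function(z, delta, x_ref, k) {
  out <- z
  for (i in seq_along(z)) {
    if (delta[i] == 1) next
    cand <- data.frame(j = seq_along(z), d = abs(x_ref - x_ref[i]),
                       z = z, delta = delta)
    cand <- cand[order(cand$d, cand$j), ]
    cand <- cand[cand$delta == 1, ]
    out[i] <- mean(cand$z[seq_len(k)])
  }
  out
}

# Independent partially linear solve for a single smoother: the joint
# (p + n)-dimensional linear system of the two stationarity equations
#   X'W(z - f - X beta) = 0  and  f = S (z - X beta),
# solved literally, no hat-matrix algebra.
block_solve_oracle <- function(S, X, z, w = NULL) {
  n <- length(z)
  p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  A <- rbind(cbind(crossprod(X, w * X), t(X * w)),
             cbind(S %*% X, diag(n)))
  b <- c(crossprod(X, w * z), drop(S %*% z))
  sol <- solve(A, b)
  list(beta = sol[seq_len(p)], f = sol[p + seq_len(n)])
}

# Kaplan-Meier survival of the censoring (or lifetime) variable via the
# survival package, for tie-free inputs.
survfit_oracle <- function(z, delta, kind = "censoring", at) {
  testthat::skip_if_not_installed("survival")
  ev <- if (kind == "censoring") 1 - delta else delta
  sf <- survival::survfit(survival::Surv(z, ev) ~ 1)
  vapply(at, function(u) {
    keep <- sf$time <= u
    if (!any(keep)) 1 else min(sf$surv[keep][sum(keep)])
  }, numeric(1))
}

expect_equal_tol <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected)), tol)
}
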