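test_that("product-limit estimate of the censoring distribution matches direct evaluation", {
  # no censored points: empty product, curve identically 1
  c0 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(nrow(c0), 0)
  expect_equal(km_survival(c0, c(0.5, 1, 2, 10)), rep(1, 4))

  # one censored point at the middle order statistic (n = 3)
  c1 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_survival(c1, c(1, 1.9)), c(1, 1))
  expect_equal(km_survival(c1, c(2, 2.5, 3, 10)), rep(1 / 2, 4))

  # all censored: successive factors (n-i)/(n-i+1)
  c2 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_survival(c2, c(1, 1.5)), c(2 / 3, 2 / 3))
  expect_equal(km_survival(c2, c(2, 2.5)), c(1 / 3, 1 / 3))
  expect_equal(km_survival(c2, c(3, 99)), c(0, 0))
  expect_true(attr(c2, "degenerate"))
})

test_that("product-limit curves agree with the survival package on tie-free data", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 40
    z <- sort(rexp(n)) + seq_len(n) * 1e-6   # guarantee distinct values
    delta <- rbinom(n, 1, 0.7)
    if (!any(delta == 1)) delta[1] <- 1
    if (!any(delta == 0)) delta[2] <- 0
    at <- c(min(z) - 1, sample(z, 10), max(z) + 1)
    for (kind in c("censoring", "lifetime")) {
      ours <- km_survival(km_curve(z, delta, kind), at)
      expect_equal(ours, survfit_oracle(z, delta, kind, at), tolerance = 1e-10)
    }
  }
})

test_that("product-limit survival values are nonincreasing step functions in [0, 1]", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    z <- round(rexp(n), sample(c(1, 2, 8), 1))   # induce occasional ties
    delta <- rbinom(n, 1, runif(1, 0.3, 0.95))
    cv <- km_curve(z, delta, sample(c("censoring", "lifetime"), 1))
    s <- km_survival(cv, sort(c(z, runif(10, 0, max(z) + 1))))
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(km_survival(cv, min(z) - 1), 1)
  }
})

test_that("synthetic transformation rescales uncensored points and zeroes censored ones", {
  # worked n = 3 case: z3 scaled by 1/(1 - G(3)) = 2
  expect_equal(st_transform(c(1, 2, 3), c(1, 0, 1)), c(1, 0, 6))
  # fully uncensored: identity
  z <- c(2.5, 1, 4, 3)
  expect_equal(st_transform(z, rep(1, 4)), z)
  # censored points map exactly to zero regardless of magnitude
  set.seed(2)
  z <- rexp(30)
  delta <- rbinom(30, 1, 0.6)
  expect_true(all(st_transform(z, delta)[delta == 0] == 0))
})

test_that("synthetic transformation is empirically unbiased for the mean lifetime", {
  # y ~ Exp, censoring c ~ Exp with known distribution G supplied to the
  # transform (as a fine step curve): mean(z^G) should track mean(y) within
  # Monte-Carlo error. Unbiasedness is a property of the transform with the
  # true G; the plug-in product-limit estimate adds only finite-sample bias.
  set.seed(99)
  reps <- 2000
  n <- 40
  rate_c <- 0.35
  grid <- seq(0, 60, length.out = 5000)
  G_true <- structure(tibble::tibble(time = grid, surv = exp(-rate_c * grid)),
                      class = c("km_curve", class(tibble::tibble())),
                      kind = "censoring", n = length(grid))
  diffs <- replicate(reps, {
    y <- rexp(n, rate = 1)
    cc <- rexp(n, rate = rate_c)
    z <- pmin(y, cc)
    delta <- as.numeric(y <= cc)
    mean(st_transform(z, delta, curve = G_true)) - mean(y)
  })
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * mc_se)
})

test_that("Kaplan-Meier weights equal the product-limit jumps and respect their invariants", {
  expect_equal(km_weights(c(1, 2, 3), c(1, 0, 1)), c(1 / 3, 0, 2 / 3))
  # no censoring: uniform 1/n for any n
  for (n in c(3, 7, 20)) {
    expect_equal(km_weights(sort(rnorm(n)), rep(1, n)), rep(1 / n, n))
  }
  # order dependence is enforced
  expect_error(km_weights(c(2, 1, 3), c(1, 1, 1)), "sorted")

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    z <- sort(rexp(n))
    delta <- rbinom(n, 1, runif(1, 0.4, 1))
    if (!any(delta == 1)) delta[1] <- 1
    w <- km_weights(z, delta)
    expect_true(all(w[delta == 0] == 0))
    expect_true(all(w >= 0))
    expect_lte(sum(w), 1 + 1e-12)
    if (delta[n] == 1) expect_equal(sum(w), 1)
    # weights are the jumps of the lifetime product-limit estimate
    Fhat <- 1 - km_survival(km_curve(z, delta, "lifetime"), z)
    expect_equal(w, diff(c(0, Fhat)), tolerance = 1e-12)
  }
})

test_that("reference predictor maximises |correlation| with z over uncensored rows", {
  cd <- toy_cd()
  expect_equal(select_reference_predictor(cd), "x1")  # x1 tracks z, x2 is noise
  d1 <- tibble::tibble(z = 1:6, delta = rep(1, 6), x1 = c(6, 5, 4, 3, 2, 1))
  expect_equal(select_reference_predictor(d1, parametric = "x1"), "x1")
  # negative correlation counts through its absolute value
  set.seed(5)
  d2 <- tibble::tibble(z = 1:20 + rnorm(20, 0, 0.1), delta = rep(1, 20),
                       x1 = -(1:20) + rnorm(20, 0, 0.5), x2 = rnorm(20))
  expect_equal(select_reference_predictor(d2, parametric = c("x1", "x2")), "x1")
  # all-degenerate parametric block is an error
  d3 <- tibble::tibble(z = 1:5, delta = rep(1, 5), x1 = rep(2, 5))
  expect_error(select_reference_predictor(d3, parametric = "x1"),
               "zero variance")
})

test_that("kNN imputation matches the exhaustive distance-sort oracle", {
  # worked toy: censored row's two nearest uncensored neighbours average
  z <- c(3, 4, 0.5, 8, 9)
  delta <- c(1, 1, 0, 1, 1)
  x <- c(0, 1, 2, 10, 11)
  imp <- knn_impute(z, delta, x, k = 2)
  expect_equal(imp[3], (4 + 3) / 2)
  expect_equal(imp[delta == 1], z[delta == 1])  # uncensored pass through
  # no censored rows: identity
  expect_equal(knn_impute(z, rep(1, 5), x, k = 2), z)
  # random fixtures against the O(n^2) oracle
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(8:40, 1)
    z <- rexp(n)
    delta <- rbinom(n, 1, 0.7)
    if (sum(delta) < 3) delta[1:3] <- 1
    x <- rnorm(n)
    k <- sample(2:min(6, sum(delta)), 1)
    expect_equal(knn_impute(z, delta, x, k), knn_oracle(z, delta, x, k))
  }
  expect_error(knn_impute(z, delta, x, k = sum(delta) + 1), "uncensored")
})

test_that("neighbour count selection minimises in-sample MSE with ties to the smaller k", {
  d <- sim_fixture(40, 0.25, seed = 17)
  # singleton feasible range
  expect_equal(select_knn_k(d, parametric = c("x1", "x2"),
                            nonparametric = c("t1", "t2"), k_range = 3), 3)
  # constructed fixture: a censored row sits exactly between two uncensored
  # duplicates of the truth, so k = 2 imputes exactly and larger k degrades
  dd <- tibble::tibble(
    z = c(5, 5, 1, 9, 9.5, 1.2, 5.1, 8.8),
    delta = c(1, 1, 0, 1, 1, 1, 1, 1),
    x1 = c(0.99, 1.01, 1, 3, 3.1, -2, 1.05, 2.9),
    t1 = seq(0.1, 0.8, length.out = 8))
  k_best <- select_knn_k(dd, parametric = "x1", nonparametric = "t1",
                         k_range = c(2, 6), ref = "x1")
  expect_equal(k_best, 2)
  expect_error(select_knn_k(dd, parametric = "x1", nonparametric = "t1",
                            k_range = 50:60), "feasible")
})

test_that("with no censoring every solution reduces to the complete-data fit", {
  d <- sim_fixture(50, 0, seed = 23)
  expect_true(all(d$delta == 1))
  adj <- censor_adjust(d, "st", parametric = c("x1", "x2"),
                       nonparametric = c("t1", "t2"))
  expect_equal(adj$z_st, d$z)
  adj <- censor_adjust(d, "kmw", parametric = c("x1", "x2"),
                       nonparametric = c("t1", "t2"))
  expect_equal(adj$w_kmw, rep(1 / 50, 50))
  adj <- censor_adjust(d, "knni", parametric = c("x1", "x2"),
                       nonparametric = c("t1", "t2"), k = 3)
  expect_equal(adj$z_knn, d$z)
  # downstream: the three fits coincide with each other
  ctl <- plam_control(tol = 1e-8, max_iter = 300)
  fits <- lapply(c("st", "kmw", "knni"), function(m)
    plam(d, parametric = c("x1", "x2"), nonparametric = c("t1", "t2"),
         method = m, k = 3, control = ctl))
  expect_equal(fits[[1]]$beta, fits[[2]]$beta, tolerance = 1e-6)
  expect_equal(fits[[2]]$beta, fits[[3]]$beta, tolerance = 1e-6)
  expect_equal(fits[[1]]$fitted, fits[[2]]$fitted, tolerance = 1e-6)
})
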