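test_that("Wald ratio and its delta-method SE follow the definitions", {
  h <- make_h(beta_exp = 0.1, beta_out = 0, se_out = 0.01)
  expect_equal(wald_ratio(h)$theta, 0)

  h <- make_h(beta_exp = 0.1, beta_out = 0.05, se_out = 0.01)
  wr <- wald_ratio(h)
  expect_equal(wr$theta, 0.5)
  expect_equal(wr$se, 0.1)

  # joint sign flip leaves the ratio and SE unchanged
  h2 <- make_h(beta_exp = -0.1, beta_out = -0.05, se_out = 0.01)
  expect_equal(wald_ratio(h2)$theta, 0.5)
  expect_equal(wald_ratio(h2)$se, 0.1)

  expect_error(wald_ratio(make_h(0, 0.1)), "zero")
})

test_that("IVW equals the closed-form inverse-variance mean and Q", {
  h <- make_h(beta_exp = c(0.1, 0.2, 0.15),
              beta_out = c(0.03, 0.05, 0.02),
              se_out = c(0.01, 0.015, 0.02))
  wr <- wald_ratio(h)
  o <- oracle_ivw(wr$theta, wr$se)
  res <- mr_ivw(h, model = "fixed")
  expect_equal(res$estimate$beta, o$beta, tolerance = 1e-12)
  expect_equal(res$estimate$se, o$se, tolerance = 1e-12)
  expect_equal(res$heterogeneity$q, o$q, tolerance = 1e-12)
  expect_equal(res$heterogeneity$df, 2)

  # randomized inputs against the oracle
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    h <- make_h(beta_exp = runif(k, 0.05, 0.3) * sample(c(-1, 1), k, TRUE),
                beta_out = rnorm(k, 0, 0.05),
                se_out = runif(k, 0.005, 0.05))
    wr <- wald_ratio(h)
    o <- oracle_ivw(wr$theta, wr$se)
    expect_equal(mr_ivw(h, model = "fixed")$estimate$beta, o$beta,
                 tolerance = 1e-12)
  }
})

test_that("IVW cross-checks against a fixed-effect meta-analysis fit", {
  h <- make_h(beta_exp = c(0.08, 0.12, -0.09, 0.2),
              beta_out = c(0.02, 0.04, -0.01, 0.05),
              se_out = c(0.01, 0.02, 0.012, 0.03))
  wr <- wald_ratio(h)
  fit <- metafor::rma(yi = wr$theta, sei = wr$se, method = "FE")
  res <- mr_ivw(h, model = "fixed")
  expect_equal(res$estimate$beta, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(res$estimate$se, fit$se, tolerance = 1e-10)
  expect_equal(res$heterogeneity$q, fit$QE, tolerance = 1e-10)
})

test_that("IVW model selection and degeneracies behave as documented", {
  # all ratios equal: Q = 0, fixed model kept under auto
  h <- make_h(beta_exp = c(0.1, 0.2, 0.4), beta_out = c(0.05, 0.1, 0.2),
              se_out = 0.01)
  res <- mr_ivw(h, model = "auto")
  expect_equal(res$heterogeneity$q, 0)
  expect_equal(res$estimate$model, "fixed")
  expect_equal(res$estimate$beta, 0.5)

  # single instrument degenerates to the Wald ratio
  h1 <- make_h(0.1, 0.05, se_out = 0.02)
  res1 <- mr_ivw(h1, model = "auto")
  expect_equal(res1$estimate$method, "wald")
  expect_equal(res1$estimate$beta, 0.5)
  expect_equal(res1$estimate$se, 0.2)
  expect_true(is.na(res1$heterogeneity$q))

  # heterogeneous ratios trigger the MRE model; SE never shrinks
  set.seed(5)
  h2 <- make_h(beta_exp = rep(0.1, 6),
               beta_out = c(0.01, 0.09, -0.05, 0.12, 0.02, -0.08),
               se_out = 0.005)
  auto <- mr_ivw(h2, model = "auto")
  expect_true(auto$heterogeneity$p < 0.05)
  expect_equal(auto$estimate$model, "mre")
  fixed <- mr_ivw(h2, model = "fixed")
  expect_true(auto$estimate$se >= fixed$estimate$se)
  expect_equal(auto$estimate$se,
               fixed$estimate$se *
                 sqrt(auto$heterogeneity$q / auto$heterogeneity$df))
})

test_that("IVW is invariant under joint sign flips of instrument subsets", {
  set.seed(9)
  h <- make_h(beta_exp = runif(6, 0.05, 0.3), beta_out = rnorm(6, 0, 0.03),
              se_out = runif(6, 0.005, 0.03))
  flip <- c(1, 3, 4)
  h2 <- h
  h2$beta_exp[flip] <- -h2$beta_exp[flip]
  h2$beta_out[flip] <- -h2$beta_out[flip]
  expect_equal(mr_ivw(h2)$estimate$beta, mr_ivw(h)$estimate$beta,
               tolerance = 1e-14)
})

test_that("Egger recovers exact linear and affine data", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- make_h(beta_exp = bx, beta_out = 0.3 * bx, se_out = 0.01)
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)

  h2 <- make_h(beta_exp = bx, beta_out = 0.1 + 0.3 * bx, se_out = 0.01)
  eg2 <- mr_egger(h2)
  expect_equal(eg2$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg2$intercept, 0.1, tolerance = 1e-10)

  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.01, 0.02))), "at least 3")
})

test_that("Egger coefficients equal an independent normal-equations solve", {
  set.seed(13)
  for (rep in 1:10) {
    k <- 6
    h <- make_h(beta_exp = runif(k, 0.05, 0.3),
                beta_out = rnorm(k, 0.02, 0.03),
                se_out = runif(k, 0.005, 0.04))
    eg <- mr_egger(h)
    cf <- oracle_wls(h$beta_exp, h$beta_out, 1 / h$se_out^2)
    expect_equal(eg$intercept, cf[1], tolerance = 1e-10)
    expect_equal(eg$slope$beta, cf[2], tolerance = 1e-10)
  }
})

test_that("Egger re-orients instruments to positive exposure effects", {
  set.seed(14)
  h <- make_h(beta_exp = runif(5, 0.05, 0.3),
              beta_out = rnorm(5, 0, 0.05), se_out = 0.02)
  h2 <- h
  h2$beta_exp[2] <- -h2$beta_exp[2]
  h2$beta_out[2] <- -h2$beta_out[2]
  expect_equal(mr_egger(h2)$slope$beta, mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(h2)$intercept, mr_egger(h)$intercept,
               tolerance = 1e-12)
})

test_that("with no pleiotropy and exact data all estimators agree", {
  bx <- c(0.06, 0.1, 0.18, 0.25)
  h <- make_h(beta_exp = bx, beta_out = 0.4 * bx, se_out = 0.01)
  wr <- wald_ratio(h)
  expect_equal(wr$theta, rep(0.4, 4))
  expect_equal(mr_ivw(h)$estimate$beta, 0.4, tolerance = 1e-12)
  expect_equal(mr_egger(h)$slope$beta, 0.4, tolerance = 1e-10)
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.4,
               tolerance = 1e-12)
})

test_that("weighted median interpolates the 50% weight point", {
  # equal weights, ratios {1, 2, 9}: midpoint rule gives the middle ratio
  h <- make_h(beta_exp = c(0.1, 0.1, 0.1), beta_out = c(0.1, 0.2, 0.9),
              se_out = 0.01)
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 2)

  # constant ratios: estimate equals the constant regardless of weights
  h2 <- make_h(beta_exp = c(0.1, 0.2, 0.3), beta_out = c(0.05, 0.1, 0.15),
               se_out = c(0.01, 0.03, 0.02))
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$beta, 0.5)

  # randomized sets against the brute-force oracle
  set.seed(17)
  for (rep in 1:25) {
    k <- sample(3:10, 1)
    h <- make_h(beta_exp = runif(k, 0.05, 0.3),
                beta_out = rnorm(k, 0, 0.05),
                se_out = runif(k, 0.005, 0.04))
    wr <- wald_ratio(h)
    expect_equal(mr_weighted_median(h, n_boot = 50, seed = rep)$beta,
                 oracle_weighted_median(wr$theta, 1 / wr$se^2),
                 tolerance = 1e-12)
  }
})

test_that("a dominant instrument pins the weighted median near its ratio", {
  set.seed(19)
  for (rep in 1:10) {
    h <- make_h(beta_exp = c(0.5, runif(4, 0.05, 0.1)),
                beta_out = c(0.25, rnorm(4, 0, 0.05)),
                se_out = c(0.002, rep(0.05, 4)))
    wr <- wald_ratio(h)
    w <- 1 / wr$se^2
    expect_true(w[1] / sum(w) > 0.5)
    est <- mr_weighted_median(h, n_boot = 50, seed = rep)$beta
    # within the interpolation neighborhood: between the dominant ratio
    # and its nearest ordered neighbor
    ord <- order(wr$theta)
    pos <- which(ord == 1)
    nb <- wr$theta[ord][pmax(1, pos - 1):pmin(5, pos + 1)]
    expect_true(est >= min(nb) && est <= max(nb))
  }
})

test_that("weighted median with equal SEs matches the simple median", {
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(c(3, 5, 7, 9), 1)
    be <- rep(0.1, k)
    bo <- rnorm(k, 0, 0.03)
    h <- make_h(beta_exp = be, beta_out = bo, se_out = 0.01)
    wr <- wald_ratio(h)
    expect_equal(mr_weighted_median(h, n_boot = 50, seed = rep)$beta,
                 median(wr$theta), tolerance = 1e-12)
  }
})

test_that("estimate tables satisfy the OR/CI contract", {
  set.seed(29)
  h <- make_h(beta_exp = runif(5, 0.05, 0.3), beta_out = rnorm(5, 0, 0.05),
              se_out = runif(5, 0.01, 0.03))
  ests <- rbind(mr_ivw(h)$estimate, mr_egger(h)$slope,
                mr_weighted_median(h, n_boot = 100, seed = 1))
  expect_equal(ests$or, exp(ests$beta))
  expect_equal(ests$ci_low, exp(ests$beta - 1.96 * ests$se))
  expect_equal(ests$ci_high, exp(ests$beta + 1.96 * ests$se))
  expect_true(all(ests$ci_low < ests$ci_high))
  expect_true(all(ests$ci_low <= ests$or & ests$or <= ests$ci_high))
  expect_true(all(ests$p > 0 & ests$p <= 1))
})

test_that("bootstrap SE is reproducible under a fixed seed", {
  h <- make_h(beta_exp = c(0.1, 0.15, 0.2, 0.08),
              beta_out = c(0.03, 0.04, 0.07, 0.01), se_out = 0.02)
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(a, b)
  expect_error(mr_weighted_median(h, n_boot = 200), "seed")
})
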