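test_that("the geometric toy fit matches the profile-search oracle", {
  counts <- c(100, 60, 36)
  d <- removal_data(data.frame(primary = 1:3, secondary = 1, count = counts))
  fit <- fit_removal(d, grm_spec(), n_restarts = 3, seed = 1)
  oracle <- oracle_grm_mle(counts)
  expect_true(fit$converged)
  expect_equal(fit$natural[["p"]], oracle$p, tolerance = 1e-3)
  expect_equal(fit$N_hat, oracle$N, tolerance = 1e-3)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  # the classical closed-form values are recovered up to the effect of the
  # continuous-n0 relaxation on these exactly geometric counts
  expect_equal(fit$natural[["p"]], 0.4, tolerance = 0.03)
  expect_equal(fit$N_hat, 250, tolerance = 0.02)
})

test_that("the likelihood at a fixed vector matches the fit's objective", {
  scn <- removal_scenario("constant", 2, K = 10)
  dat <- simulate_removal(scn, seed = 21)
  spec <- rmer_spec(attr(dat, "design"), "stationary", "random")
  truth <- pack_parameters(spec, phi12 = 0.4, p = 0.3,
                           n0 = 500 - total_removed(dat))
  fit <- fit_removal(dat, spec, starts = list(truth))
  expect_gte(fit$loglik, removal_loglik(dat, spec, truth) - 1e-8)
})

test_that("abundance estimates never fall below the number removed", {
  set.seed(8)
  for (rep in 1:5) {
    scn <- removal_scenario("constant", sample(1:2, 1), K = 10)
    dat <- simulate_removal(scn, seed = 300 + rep)
    fit <- fit_removal(dat, rmer_spec(attr(dat, "design"), "stationary", "random"),
                       n_restarts = 2, seed = rep)
    expect_gte(fit$N_hat[[1]], total_removed(dat))
    expect_gte(fit$natural[["n0"]], 0)
  }
})

test_that("nested models never beat their supermodel's likelihood", {
  scn <- removal_scenario("constant", 2, K = 20)
  dat <- simulate_removal(scn, seed = 77)
  design <- attr(dat, "design")
  small <- fit_removal(dat, rmer_spec(design, "stationary", "random"),
                       n_restarts = 3, seed = 1)
  big <- fit_removal(dat, rmer_spec(design, "free", "none"),
                     n_restarts = 5, seed = 1)
  expect_gte(big$loglik, small$loglik - 1e-4)
})

test_that("AIC ranking orders models and zeroes the best delta", {
  scn <- removal_scenario("constant", 2, K = 20)
  dat <- simulate_removal(scn, seed = 55)
  design <- attr(dat, "design")
  single <- rank_models(dat, rmer_spec(design, "stationary", "random"),
                        n_restarts = 2, seed = 1)
  expect_equal(single$delta_AIC, 0)
  tab <- rank_models(
    dat,
    list(rmer_spec(design, "stationary", "random"),
         rmer_spec(design, "free", "none"),
         grm_spec()),
    n_restarts = 3, seed = 1
  )
  expect_equal(tab$AIC, sort(tab$AIC))
  expect_equal(tab$delta_AIC[1], 0)
  expect_equal(tab$AIC, -2 * tab$loglik + 2 * tab$h)
  expect_setequal(tab$model, c("R-SRC", "R-NNC", "G-C"))
})

test_that("Hessian standard errors track the empirical spread", {
  scn <- removal_scenario("constant", 2, K = 20)
  spec <- rmer_spec(scn$design, "stationary", "random")
  seeds <- 1:80
  ests <- ses <- matrix(NA_real_, length(seeds), 2,
                        dimnames = list(NULL, c("phi12", "p")))
  for (i in seq_along(seeds)) {
    dat <- simulate_removal(scn, seed = 4000 + seeds[i])
    fit <- fit_removal(dat, spec, n_restarts = 2, seed = i, compute_se = TRUE)
    if (!fit$converged || is.null(fit$se)) next
    ests[i, ] <- fit$se$estimate[match(c("phi12", "p"), fit$se$term)]
    ses[i, ] <- fit$se$std.error[match(c("phi12", "p"), fit$se$term)]
  }
  ok <- stats::complete.cases(ests)
  expect_gt(mean(ok), 0.9)
  for (j in 1:2) {
    expect_equal(mean(ses[ok, j]), sd(ests[ok, j]), tolerance = 0.25)
  }
})

test_that("boundary optima suppress Hessian standard errors", {
  # all removals at the very first occasion push p-hat to 1
  d <- removal_data(data.frame(primary = rep(1:2, each = 2),
                               secondary = rep(1:2, 2),
                               count = c(60, 0, 0, 0)))
  fit <- fit_removal(d, grm_spec(), n_restarts = 4, seed = 2, compute_se = TRUE)
  expect_true(length(fit$boundary) > 0)
  expect_null(fit$se)
  expect_match(fit$se_reason, "boundary")
})

test_that("bootstrap edge cases behave", {
  d <- removal_data(data.frame(primary = 1:3, secondary = 1,
                               count = c(100, 60, 36)))
  fit <- fit_removal(d, grm_spec(), n_restarts = 2, seed = 1)
  empty <- bootstrap_removal(fit, B = 0)
  expect_equal(nrow(empty$replicates), 0)
  expect_equal(empty$n_failed, 0)

  # all removals in one cell: resampling cannot move them, so the
  # replicate estimates collapse to a point mass
  d1 <- removal_data(data.frame(primary = 1:3, secondary = 1,
                                count = c(80, 0, 0)))
  fit1 <- fit_removal(d1, grm_spec(), n_restarts = 2, seed = 1)
  bt <- bootstrap_removal(fit1, B = 20, seed = 3)
  expect_lt(max(apply(bt$replicates, 2, sd)), 1e-6)
})

test_that("bootstrap standard errors are coherent with the Hessian", {
  scn <- removal_scenario("constant", 2, K = 20)
  dat <- simulate_removal(scn, seed = 62)
  spec <- rmer_spec(attr(dat, "design"), "stationary", "random")
  fit <- fit_removal(dat, spec, n_restarts = 2, seed = 1, compute_se = TRUE)
  bt <- bootstrap_removal(fit, B = 60, seed = 4)
  expect_equal(bt$B, 60)
  expect_true(all(bt$ci$lower <= bt$ci$upper))
  if (!is.null(fit$se)) {
    se_h <- fit$se$std.error[fit$se$term == "p"]
    expect_equal(bt$se[["p"]], se_h, tolerance = 0.5)
  }
})

test_that("covariate relabelling is exactly compensated by the coefficients", {
  scn <- removal_scenario("constant", 2, K = 20)
  dat <- simulate_removal(scn, seed = 91)
  design <- attr(dat, "design")
  z <- as.numeric(scale(sin(1:20)))
  spec <- rmer_spec(design, "stationary", "random", p = "covariate")
  f1 <- fit_removal(dat, spec, covariate = z, n_restarts = 3, seed = 1)
  a <- 2.5
  b <- -1
  # alpha' = alpha - beta b / a, beta' = beta / a keeps every p identical
  start2 <- f1$theta_hat
  start2[["alpha"]] <- f1$natural[["alpha"]] - f1$natural[["beta"]] * b / a
  start2[["beta"]] <- f1$natural[["beta"]] / a
  f2 <- fit_removal(dat, spec, covariate = a * z + b, starts = list(start2))
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f2$natural[["beta"]], f1$natural[["beta"]] / a, tolerance = 1e-4)
  expect_equal(f2$natural[["alpha"]],
               f1$natural[["alpha"]] - f1$natural[["beta"]] * b / a,
               tolerance = 1e-4)
})

test_that("tidy and glance expose the fit in broom style", {
  d <- removal_data(data.frame(primary = 1:3, secondary = 1,
                               count = c(100, 60, 36)))
  fit <- fit_removal(d, grm_spec(), n_restarts = 2, seed = 1, compute_se = TRUE)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true(all(c("p", "n0", "N_1") %in% td$term))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$AIC, -2 * gl$logLik + 2 * gl$h)
  expect_s3_class(autoplot(fit), "ggplot")
})
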