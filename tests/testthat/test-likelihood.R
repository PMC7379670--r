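test_that("cell probabilities reduce to geometric depletion with one state", {
  s <- rmer_spec(removal_design(1, 3), pi = "free", phi = "random")
  th <- pack_parameters(s, pi = 1, phi12 = 0.5, p = 0.3, n0 = 1)
  cp <- cell_probabilities(expand_parameters(th, s))
  expect_equal(cp$prob, c(0.3, 0.21, 0.147), tolerance = 1e-12)
  expect_equal(unname(never_removed(cp)), 0.343, tolerance = 1e-12)
})

test_that("a permanently unavailable population is never removed", {
  s <- rmer_spec(removal_design(4, 2), pi = "free", phi = "none")
  th <- pack_parameters(s, pi = 0, phi12 = 0.5, phi21 = 0, p = 0.7, n0 = 10)
  cp <- cell_probabilities(expand_parameters(th, s))
  expect_equal(cp$prob, rep(0, 8))
  expect_equal(unname(never_removed(cp)), 1)
})

test_that("cell probabilities match the brute-force path-enumeration oracle", {
  cases <- list(
    list(design = removal_design(2, 2), pi = 0.5,
         phi12 = 0.8, phi21 = 0.2, p = rep(0.3, 4)),
    list(design = removal_design(3, c(2, 1, 3)), pi = 0.35,
         phi12 = c(0.7, 0.15), phi21 = c(0.4, 0.9),
         p = c(0.2, 0.5, 0.35, 0.6, 0.1, 0.45)),
    list(design = removal_design(4, 2), pi = 0.9,
         phi12 = c(0.2, 0.5, 0.8), phi21 = c(0.3, 0.6, 0.1),
         p = seq(0.1, 0.8, length.out = 8))
  )
  for (cs in cases) {
    s <- rmer_spec(cs$design, pi = "free", phi = "none",
                   phi_time = "time_varying", p = "time_varying")
    th <- pack_parameters(s, pi = cs$pi, phi12 = cs$phi12, phi21 = cs$phi21,
                          p = cs$p, n0 = 5)
    cp <- cell_probabilities(expand_parameters(th, s))
    oracle <- oracle_cell_probs(cs$pi, cs$phi12, cs$phi21, cs$p, cs$design)
    expect_equal(cp$prob, oracle$L, tolerance = 1e-12)
    expect_equal(unname(never_removed(cp)), oracle$L0, tolerance = 1e-12)
  }
})

test_that("cells always sum to one", {
  set.seed(42)
  for (rep in 1:20) {
    Tn <- sample(1:5, 1)
    k <- sample(1:3, Tn, replace = TRUE)
    s <- rmer_spec(removal_design(Tn, k), pi = "free", phi = "none",
                   phi_time = if (Tn > 1) "time_varying" else "constant",
                   p = "time_varying")
    theta <- rnorm(n_free_parameters(s), sd = 2)
    cp <- cell_probabilities(expand_parameters(theta, s))
    expect_equal(sum(cp$prob) + sum(never_removed(cp)), 1, tolerance = 1e-10)
  }
})

test_that("state relabelling symmetry leaves the cells unchanged", {
  # renaming the latent states (1 <-> 2) while swapping pi -> 1 - pi,
  # phi12 <-> phi21 and moving detection to the other state is the same
  # model, so every cell probability must be identical
  design <- removal_design(3, 2)
  s <- rmer_spec(design, pi = "free", phi = "none", phi_time = "time_varying",
                 p = "time_varying")
  set.seed(7)
  pi0 <- 0.3
  phi12 <- runif(2)
  phi21 <- runif(2)
  p <- runif(6)
  relabelled <- oracle_cell_probs(1 - pi0, phi21, phi12, p, design,
                                  observable = 2L)
  th1 <- pack_parameters(s, pi = pi0, phi12 = phi12, phi21 = phi21, p = p, n0 = 4)
  cp1 <- cell_probabilities(expand_parameters(th1, s))
  expect_equal(cp1$prob, relabelled$L, tolerance = 1e-12)
  expect_equal(unname(never_removed(cp1)), relabelled$L0, tolerance = 1e-12)
})

test_that("log-likelihood matches hand multinomial arithmetic", {
  # two occasions in one primary period, counts (3, 1), p = 0.5, pi = 1,
  # n0 = 0: cells are 0.5, 0.25 and the likelihood is
  # 4!/(3! 1! 0!) * 0.5^3 * 0.25^1
  d <- removal_data(data.frame(primary = 1, secondary = 1:2, count = c(3, 1)))
  s <- rmer_spec(removal_design(1, 2), pi = "free", phi = "random")
  th <- pack_parameters(s, pi = 1, phi12 = 0.5, p = 0.5, n0 = 1e-12)
  expect_equal(
    removal_loglik(d, s, th),
    log(factorial(4) / (factorial(3) * factorial(1)) * 0.5^3 * 0.25),
    tolerance = 1e-6
  )
})

test_that("per-cell log terms re-sum to the direct multinomial product", {
  set.seed(5)
  for (rep in 1:5) {
    scn <- removal_scenario("constant", sample(1:2, 1), K = 10)
    dat <- simulate_removal(scn, seed = 100 + rep)
    s <- rmer_spec(attr(dat, "design"), pi = "free", phi = "none")
    th <- pack_parameters(s, pi = runif(1, .2, .8), phi12 = runif(1, .2, .8),
                          phi21 = runif(1, .2, .8), p = runif(1, .2, .6),
                          n0 = runif(1, 10, 80))
    params <- expand_parameters(th, s)
    cp <- cell_probabilities(params)
    n <- dat$count[order(dat$occasion)]
    n0 <- params[[1]]$n0
    N <- n0 + sum(n)
    direct <- lgamma(N + 1) - lgamma(n0 + 1) - sum(lfactorial(n)) +
      n0 * log(never_removed(cp)) + sum(n * log(cp$prob))
    expect_equal(removal_loglik(dat, s, th), unname(direct), tolerance = 1e-10)
  }
})

test_that("a removal at a zero-probability occasion gives -Inf", {
  d <- removal_data(data.frame(primary = 1, secondary = 1:2, count = c(3, 1)))
  s <- rmer_spec(removal_design(1, 2), pi = "free", phi = "random")
  # pi = 0 makes every removal impossible
  th <- pack_parameters(s, pi = 0, phi12 = 0.5, p = 0.5, n0 = 10)
  expect_identical(removal_loglik(d, s, th), -Inf)
})

test_that("the integrated likelihood is the sum over populations", {
  design <- removal_design(5, 2)
  scn <- removal_scenario("integrated", 1, K = 10)
  dat <- simulate_removal(scn, seed = 31)
  spec2 <- rmer_spec(design, pi = "stationary", phi = "random",
                     phi_time = "time_varying", additive = TRUE,
                     n_populations = 2)
  phit <- c(0.6, 0.3, 0.7, 0.5)
  gamma2 <- -0.4
  th <- pack_parameters(spec2, phi12 = phit, gamma = gamma2, p = 0.35,
                        n0 = c(40, 25))
  joint <- removal_loglik(dat, spec2, th)

  # manual product: evaluate each population under its own single-pop spec
  spec1 <- rmer_spec(design, pi = "stationary", phi = "random",
                     phi_time = "time_varying")
  split_pop <- function(w, n0) {
    sub <- as.data.frame(dat[dat$population == w,
                             c("primary", "secondary", "count")])
    d1 <- removal_data(sub, design = design)
    phi_w <- if (w == 1) phit else plogis(qlogis(phit) + gamma2)
    removal_loglik(d1, spec1,
                   pack_parameters(spec1, phi12 = phi_w, p = 0.35, n0 = n0))
  }
  expect_equal(joint, split_pop(1, 40) + split_pop(2, 25), tolerance = 1e-10)

  # zero offset forces equal transitions across populations
  th0 <- pack_parameters(spec2, phi12 = phit, gamma = 0, p = 0.35,
                         n0 = c(40, 25))
  spec_shared <- rmer_spec(design, pi = "stationary", phi = "random",
                           phi_time = "time_varying", n_populations = 2)
  th_shared <- pack_parameters(spec_shared, phi12 = phit, p = 0.35,
                               n0 = c(40, 25))
  expect_equal(removal_loglik(dat, spec2, th0),
               removal_loglik(dat, spec_shared, th_shared), tolerance = 1e-10)
})

test_that("missing occasions force p = 0 and zero cells", {
  design <- removal_design(3, 2,
                           missing = data.frame(primary = 2, secondary = 1))
  s <- rmer_spec(design, pi = "free", phi = "random")
  th <- pack_parameters(s, pi = 0.8, phi12 = 0.3, p = 0.4, n0 = 10)
  params <- expand_parameters(th, s)
  expect_equal(params[[1]]$p[3], 0)
  cp <- cell_probabilities(params)
  expect_equal(cp$prob[cp$primary == 2 & cp$secondary == 1], 0)
  expect_equal(sum(cp$prob) + sum(never_removed(cp)), 1, tolerance = 1e-10)
})
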