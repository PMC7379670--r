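test_that("parameter expansion honours each constraint", {
  d <- removal_design(10, 2)

  # random emigration: phi21 = 1 - phi12 (scenario-1 style truths)
  sR <- rmer_spec(d, pi = "free", phi = "random")
  pr <- expand_parameters(
    pack_parameters(sR, pi = 0.2, phi12 = 0.8, p = 0.3, n0 = 50), sR
  )
  expect_equal(pr[[1]]$phi21, rep(0.2, 9), tolerance = 1e-12)

  # even flow: phi21 = phi12
  sE <- rmer_spec(d, pi = "free", phi = "even", phi_time = "time_varying")
  phis <- seq(0.3, 0.5, length.out = 9)
  pe <- expand_parameters(
    pack_parameters(sE, pi = 0.4, phi12 = phis, p = 0.3, n0 = 50), sE
  )
  expect_equal(pe[[1]]$phi21, pe[[1]]$phi12)
  expect_equal(pe[[1]]$phi12, phis, tolerance = 1e-10)

  # stationary pi: mean of phi21/(phi12+phi21); cross-check against the
  # eigen-decomposition stationary vector of the transition matrix
  sS <- rmer_spec(d, pi = "stationary", phi = "none")
  ps <- expand_parameters(
    pack_parameters(sS, phi12 = 0.4, phi21 = 0.6, p = 0.3, n0 = 50), sS
  )
  expect_equal(ps[[1]]$pi, 0.6, tolerance = 1e-12)
  P <- matrix(c(1 - 0.4, 0.4, 0.6, 1 - 0.6), 2, 2, byrow = TRUE)
  ev <- eigen(t(P))
  statv <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  expect_equal(ps[[1]]$pi, (statv / sum(statv))[1], tolerance = 1e-10)

  # last-two-equal: final transition copies the penultimate one
  s2 <- rmer_spec(d, pi = "free", phi = "random", phi_time = "time_varying",
                  last_two_equal = TRUE)
  phis8 <- seq(0.2, 0.9, length.out = 8)
  p2 <- expand_parameters(
    pack_parameters(s2, pi = 0.5, phi12 = phis8, p = 0.3, n0 = 50), s2
  )
  expect_length(p2[[1]]$phi12, 9)
  expect_equal(p2[[1]]$phi12[9], p2[[1]]$phi12[8])

  # general transition-sum constraint: phi21 = v - phi12
  sV <- rmer_spec(d, pi = "free", phi = "general")
  pv <- expand_parameters(
    pack_parameters(sV, pi = 0.5, phi12 = 0.5, v = 1.2, p = 0.3, n0 = 50), sV
  )
  expect_equal(pv[[1]]$phi21, rep(0.7, 9), tolerance = 1e-10)

  # covariate capture link: p = logistic(alpha + beta z)
  sZ <- rmer_spec(d, pi = "free", phi = "random", p = "covariate")
  z <- sin(1:20)
  pz <- expand_parameters(
    pack_parameters(sZ, pi = 0.5, phi12 = 0.5, alpha = -1, beta = 0.7, n0 = 50),
    sZ, covariate = z
  )
  expect_equal(pz[[1]]$p, plogis(-1 + 0.7 * z))

  # additive group offset on the logit of phi12
  sI <- rmer_spec(d, pi = "stationary", phi = "random",
                  phi_time = "time_varying", additive = TRUE, n_populations = 2)
  phit <- seq(0.3, 0.8, length.out = 9)
  pi_ <- expand_parameters(
    pack_parameters(sI, phi12 = phit, gamma = -0.5, p = 0.3, n0 = c(30, 20)), sI
  )
  expect_equal(pi_[[2]]$phi12, plogis(qlogis(phit) - 0.5), tolerance = 1e-10)
  expect_equal(pi_[[1]]$phi12, phit, tolerance = 1e-10)
})

test_that("expansion maps any finite free vector to valid probabilities", {
  d <- removal_design(5, 2)
  specs <- list(
    rmer_spec(d, "free", "none", "time_varying", p = "time_varying"),
    rmer_spec(d, "stationary", "random", "time_varying"),
    rmer_spec(d, "free", "even", p = "covariate"),
    rmer_spec(d, "stationary", "random", "time_varying",
              additive = TRUE, n_populations = 2)
  )
  set.seed(99)
  for (spec in specs) {
    for (rep in 1:5) {
      theta <- rnorm(n_free_parameters(spec), sd = 3)
      params <- expand_parameters(theta, spec, covariate = sin(1:10))
      for (pw in params) {
        probs <- c(pw$pi, pw$phi12, pw$phi21, pw$p)
        expect_true(all(probs >= 0 & probs <= 1))
        expect_gte(pw$n0, 0)
      }
    }
  }
})

test_that("parameter counts match the published conventions", {
  d10 <- removal_design(10, 2) # K = 20
  # fully time-dependent model has K + 2T free parameters
  full <- rmer_spec(d10, "free", "none", "time_varying", p = "time_varying")
  expect_identical(n_free_parameters(full, include_abundance = TRUE),
                   20L + 2L * 10L)
  # abundance convention: the two counts differ by one n0 per population
  for (W in 1:3) {
    sp <- rmer_spec(d10, "free", "none", n_populations = W)
    expect_identical(
      n_free_parameters(sp, TRUE) - n_free_parameters(sp, FALSE), W
    )
  }
  # top integrated model: T = 47, shared covariate p, additive offset
  d47 <- removal_design(47, 2)
  top <- rmer_spec(d47, "stationary", "random", "time_varying",
                   p = "covariate", additive = TRUE, n_populations = 2)
  expect_identical(n_free_parameters(top, TRUE), 51L)
  # single population, everything constant, excluding abundance
  d1 <- removal_design(10, 1)
  expect_identical(
    n_free_parameters(rmer_spec(d1, "free", "none"), FALSE), 4L
  )
})

test_that("printed h values of the constant-transition table reproduce", {
  rows <- list(
    list(code = "NNC", h = 4L), list(code = "NNZ", h = 5L),
    list(code = "SNC", h = 3L), list(code = "NRC", h = 3L),
    list(code = "NEC", h = 3L), list(code = "SNZ", h = 4L),
    list(code = "NRZ", h = 4L), list(code = "NEZ", h = 4L),
    list(code = "SRC", h = 2L), list(code = "SEC", h = 2L),
    list(code = "SRZ", h = 3L), list(code = "SEZ", h = 3L)
  )
  for (row in rows) {
    # the h column is shared by the robust and single-secondary variants
    expect_identical(
      n_free_parameters(spec_from_code(row$code), FALSE), row$h
    )
    expect_identical(
      n_free_parameters(spec_from_code(paste0("R-", row$code)), FALSE), row$h
    )
  }
})

test_that("model codes are generated and parsed consistently", {
  d2 <- removal_design(5, 2)
  d1 <- removal_design(10, 1)
  expect_identical(
    model_code(rmer_spec(d2, "stationary", "random", "time_varying")), "R-SRtC"
  )
  expect_identical(model_code(rmer_spec(d1, "free", "none")), "NNC")
  expect_identical(
    model_code(rmer_spec(d2, "stationary", "random", "time_varying",
                         p = "covariate", additive = TRUE, n_populations = 2)),
    "IR-S1,2RatZ"
  )
  expect_identical(model_code(grm_spec("constant")), "G-C")
  expect_identical(model_code(grm_spec("covariate")), "G-Z")

  # round trip through the parser for a lattice of codes
  codes <- c("R-SRC", "R-NNC", "R-SEtZ", "R-NR2tC", "NNC", "SRC",
             "IR-S1,2RatC", "IR-NRtC", "R-SVtC")
  for (code in codes) {
    sp <- spec_from_code(code)
    expect_identical(model_code(sp), code)
  }
})

test_that("invalid specifications are rejected", {
  d <- removal_design(5, 2)
  expect_error(rmer_spec(d, last_two_equal = TRUE), "time-varying")
  expect_error(rmer_spec(d, additive = TRUE), "n_populations")
  expect_error(rmer_spec(removal_design(1, 3), pi = "stationary"), "primary")
  expect_error(parse_model_code("R-XQC", d), "parse")
  # v outside (0, 2) cannot be produced by the link, and an invalid
  # phi21 = v - phi12 errors out
  sV <- rmer_spec(d, pi = "free", phi = "general")
  expect_error(
    expand_parameters(
      pack_parameters(sV, pi = 0.5, phi12 = 0.9, v = 1.95, p = 0.3, n0 = 5), sV
    ),
    "phi21"
  )
})
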