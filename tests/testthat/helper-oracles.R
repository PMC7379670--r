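# Independent oracles used across the test files. These deliberately avoid
# the package's forward-recursion likelihood code paths.

# Brute-force individual-level enumeration of the removal cell
# probabilities: sum over all 2^T hidden state paths of the path probability
# times the conditional capture pattern probability. States: 1 = on-site.
oracle_cell_probs <- function(pi, phi12, phi21, p, design, observable = 1L) {
  Tn <- design$n_primary
  k <- design$k
  K <- design$K
  occ_index <- function(i, j) sum(k[seq_len(i - 1)]) + j
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  L <- numeric(K)
  L0 <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    w <- if (s[1] == 1) pi else 1 - pi
    if (Tn > 1) {
      for (i in 1:(Tn - 1)) {
        w <- w * switch(
          paste0(s[i], s[i + 1]),
          "11" = 1 - phi12[i], "12" = phi12[i],
          "21" = phi21[i], "22" = 1 - phi21[i]
        )
      }
    }
    # capture process conditional on the path
    surv <- 1 # probability of not yet having been removed
    for (i in seq_len(Tn)) {
      if (s[i] == observable) {
        for (j in seq_len(k[i])) {
          m <- occ_index(i, j)
          L[m] <- L[m] + w * surv * p[m]
          surv <- surv * (1 - p[m])
        }
      }
    }
    L0 <- L0 + w * surv
  }
  list(L = L, L0 = L0)
}

# 2-D profile/grid maximum-likelihood oracle for the constant-p geometric
# removal model with continuous n0 (log-Gamma multinomial coefficient).
oracle_grm_mle <- function(counts) {
  K <- length(counts)
  D <- sum(counts)
  ll <- function(p, n0) {
    q <- cumprod(1 - rep(p, K))
    L <- p * c(1, q[-K])
    L0 <- q[K]
    N <- n0 + D
    lgamma(N + 1) - lgamma(n0 + 1) - sum(lfactorial(counts)) +
      n0 * log(L0) + sum(counts * log(L))
  }
  prof <- function(n0) optimize(function(p) ll(p, n0), c(0.01, 0.99), maximum = TRUE)
  n0_grid <- seq(max(D * 0.05, 1), D * 2, length.out = 400)
  vals <- vapply(n0_grid, function(n0) prof(n0)$objective, numeric(1))
  n0_opt <- optimize(function(n0) prof(n0)$objective,
                     range(n0_grid[order(vals, decreasing = TRUE)[1:5]]),
                     maximum = TRUE)
  list(p = prof(n0_opt$maximum)$maximum, n0 = n0_opt$maximum,
       N = n0_opt$maximum + D, loglik = n0_opt$objective)
}

# spec shorthand used in the redundancy tests
spec_from_code <- function(code, K = 10, n_populations = NULL) {
  robust <- grepl("^R-|^IR-", code)
  design <- if (robust) removal_design(K / 2, 2) else removal_design(K, 1)
  parse_model_code(code, design, n_populations = n_populations)
}
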