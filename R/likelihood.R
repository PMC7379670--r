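# Forward pass over the two-state hidden chain for one population.
# a = row vector of joint probabilities (never removed so far, current
# state); within a primary the closure assumption means no transition
# between secondaries; between primaries the Markov transition applies.
# Returns the per-occasion removal probabilities L (length K) and the
# never-removed probability L0.
cell_probs_one <- function(pi, phi12, phi21, p, design) {
  Tn <- design$n_primary
  k <- design$k
  a1 <- pi
  a2 <- 1 - pi
  L <- numeric(design$K)
  m <- 0L
  for (i in seq_len(Tn)) {
    for (j in seq_len(k[i])) {
      m <- m + 1L
      pij <- p[m]
      L[m] <- a1 * pij
      a1 <- a1 * (1 - pij)
    }
    if (i < Tn) {
      new1 <- a1 * (1 - phi12[i]) + a2 * phi21[i]
      new2 <- a1 * phi12[i] + a2 * (1 - phi21[i])
      a1 <- new1
      a2 <- new2
    }
  }
  list(L = L, L0 = a1 + a2)
}

#' Multinomial cell probabilities of a removal model
#'
#' Computes, for each population, the probability \eqn{L_{i,j}} that a given
#' individual is removed at secondary occasion `j` of primary period `i`,
#' and the probability \eqn{L_0} of never being removed, under the two-state
#' hidden Markov removal process: individuals start on-site with probability
#' \eqn{\pi}, are captured (and permanently removed) at each secondary
#' occasion with probability \eqn{p_{i,j}} while on-site, and move between
#' the on-site and off-site states between primary periods according to the
#' transition probabilities \eqn{\phi^{12}_i, \phi^{21}_i}. The cells always
#' satisfy \eqn{L_0 + \sum_{i,j} L_{i,j} = 1}.
#'
#' @param params An `rmer_params` object (see [expand_parameters()]).
#' @param design Optional [removal_design()]; defaults to the design stored
#'   in `params`' specification.
#' @return A tibble with columns `population`, `primary`, `secondary`,
#'   `occasion`, `prob`, plus an attribute `L0`: the named per-population
#'   never-removed probabilities, retrievable with `never_removed()`.
#' @examples
#' spec <- rmer_spec(removal_design(2, 2), pi = "free", phi = "none")
#' theta <- pack_parameters(spec, pi = 0.5, phi12 = 0.8, phi21 = 0.2,
#'                          p = 0.3, n0 = 10)
#' cp <- cell_probabilities(expand_parameters(theta, spec))
#' sum(cp$prob) + never_removed(cp)
#' @export
cell_probabilities <- function(params, design = NULL) {
  stopifnot(inherits(params, "rmer_params"))
  spec <- attr(params, "spec")
  if (is.null(design)) design <- spec$design
  occ <- design_occasions(design)
  out <- purrr::map_dfr(seq_along(params), function(w) {
    pw <- params[[w]]
    cp <- cell_probs_one(pw$pi, pw$phi12, pw$phi21, pw$p, design)
    dplyr::mutate(occ, population = w, prob = cp$L, .before = 1)
  })
  L0 <- vapply(params, function(pw) {
    cell_probs_one(pw$pi, pw$phi12, pw$phi21, pw$p, design)$L0
  }, numeric(1))
  names(L0) <- seq_along(params)
  out <- dplyr::select(out, "population", "primary", "secondary", "occasion", "prob")
  attr(out, "L0") <- L0
  out
}

#' @rdname cell_probabilities
#' @param x The tibble returned by `cell_probabilities()`.
#' @export
never_removed <- function(x) attr(x, "L0")

# log multinomial likelihood contribution for one population:
# counts n (length K), cells L, never-removed L0, continuous n0 relaxation.
loglik_one <- function(n, L, L0, n0) {
  if (n0 < 0 || !is.finite(n0)) return(-Inf)
  obs <- n > 0
  if (any(L[obs] <= 0)) return(-Inf) # removal recorded at an impossible occasion
  N <- n0 + sum(n)
  l0_term <- if (n0 > 0) {
    if (L0 <= 0) return(-Inf) else n0 * log(L0)
  } else 0
  lgamma(N + 1) - lgamma(n0 + 1) - sum(lfactorial(n[obs])) +
    l0_term + sum(n[obs] * log(L[obs]))
}

#' Log-likelihood of a removal model
#'
#' Evaluates the product-multinomial log-likelihood of removal counts under
#' an RMER/MER/IRMER specification, at a free-parameter vector on the
#' unconstrained scale. For each population with counts \eqn{n_{i,j}},
#' number never removed \eqn{n_0} and total \eqn{N = n_0 + D},
#' \deqn{\ell = \log\Gamma(N+1) - \log\Gamma(n_0+1) - \sum \log(n_{i,j}!) +
#'   n_0 \log L_0 + \sum n_{i,j} \log L_{i,j},}
#' with \eqn{n_0} treated as a continuous parameter through the
#' gamma-function relaxation of the multinomial coefficient. The
#' multinomial constant is included, so values are comparable across models
#' fitted to the same data. Populations are independent, so the integrated
#' log-likelihood is the sum over populations. A positive count at an
#' occasion whose removal probability is zero yields `-Inf`.
#'
#' @param data A [removal_data()] object (possibly multi-population).
#' @param spec An [rmer_spec()] with the same design and number of
#'   populations as `data`.
#' @param theta Free-parameter vector on the unconstrained scale, including
#'   the `n0` block (see [pack_parameters()]).
#' @param covariate Optional covariate column name in `data` (or a numeric
#'   vector of length `K`) for the covariate capture model.
#' @return The log-likelihood (a scalar; `-Inf` for impossible data).
#' @export
removal_loglik <- function(data, spec, theta, covariate = NULL) {
  stopifnot(inherits(data, "removal_data"))
  design <- attr(data, "design")
  z <- covariate_vector(data, covariate)
  params <- expand_parameters(theta, spec, covariate = z)
  counts <- counts_matrix(data)
  if (length(counts) != spec$n_populations) {
    abort(sprintf(
      "Data has %d population(s) but the spec declares %d.",
      length(counts), spec$n_populations
    ))
  }
  ll <- 0
  for (w in seq_along(counts)) {
    pw <- params[[w]]
    cp <- cell_probs_one(pw$pi, pw$phi12, pw$phi21, pw$p, design)
    ll <- ll + loglik_one(counts[[w]], cp$L, cp$L0, pw$n0)
  }
  ll
}

# Resolve a covariate argument (column name or numeric vector) into a
# per-occasion numeric vector of length K (values shared across populations).
covariate_vector <- function(data, covariate) {
  if (is.null(covariate)) return(NULL)
  if (is.numeric(covariate)) return(covariate)
  stopifnot(is.character(covariate), length(covariate) == 1L)
  if (!covariate %in% names(data)) {
    abort(sprintf("Covariate column '%s' not found in the data.", covariate))
  }
  sub <- data[data$population == data$population[[1]], ]
  sub[[covariate]][order(sub$occasion)]
}
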