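# Deterministic standardized covariate sequence used when ranking
# covariate-capture ("Z") models: the rank of the Jacobian depends on the
# covariate varying over occasions, so a fixed non-constant sequence is
# used wherever no real covariate is supplied.
#' Synthetic covariate sequence for redundancy diagnostics
#'
#' @param K Number of occasions.
#' @return A standardized (mean 0, sd 1), non-constant numeric vector of
#'   length `K`, deterministic in `K`.
#' @export
redundancy_covariate <- function(K) {
  z <- sin(seq_len(K)) + 0.5 * cos(2 * seq_len(K))
  as.numeric(scale(z))
}

# random interior natural-scale draws for the free parameters of a spec
random_interior_points <- function(template, n_points, seed) {
  set.seed(seed)
  lapply(seq_len(n_points), function(i) {
    vapply(seq_len(nrow(template)), function(r) {
      switch(template$par[r],
        pi = , phi12 = , phi21 = , p = runif(1, 0.15, 0.85),
        v = runif(1, 0.4, 1.6),
        gamma = runif(1, -1, 1),
        alpha = runif(1, -1, 1),
        beta = runif(1, 0.3, 1),
        n0 = runif(1, 20, 200),
        runif(1, 0.15, 0.85)
      )
    }, numeric(1))
  })
}

#' Exhaustive summary of a removal model
#'
#' Returns the exhaustive-summary map \eqn{\kappa(\theta)}: the vector of
#' all cell probabilities \eqn{(L_{1,1}, \ldots, L_{T,k_T}, L_0)} per
#' population (stacked for integrated models), as a function of the
#' natural-scale free parameters excluding `n0`. The structure of the model
#' is fully determined by \eqn{\kappa}, so the rank of its Jacobian
#' \eqn{D = \partial\kappa/\partial\theta} decides which parameters are
#' estimable.
#'
#' @param spec An [rmer_spec()].
#' @param covariate Optional length-`K` covariate vector for "Z" models;
#'   defaults to [redundancy_covariate()].
#' @return A function mapping a natural-scale free vector (length
#'   `n_free_parameters(spec, include_abundance = FALSE)`) to a numeric
#'   vector of length `(K + 1) * n_populations`.
#' @export
exhaustive_summary <- function(spec, covariate = NULL) {
  stopifnot(inherits(spec, "rmer_spec"))
  design <- spec$design
  if (spec$p == "covariate" && is.null(covariate)) {
    covariate <- redundancy_covariate(design$K)
  }
  function(theta_natural) {
    params <- expand_natural(theta_natural, spec, covariate = covariate,
                             include_abundance = FALSE)
    unlist(lapply(params, function(pw) {
      cp <- cell_probs_one(pw$pi, pw$phi12, pw$phi21, pw$p, design)
      c(cp$L, cp$L0)
    }), use.names = FALSE)
  }
}

#' Numeric parameter-redundancy diagnostic
#'
#' Estimates the deficiency of a model numerically: the Jacobian of the
#' exhaustive summary with respect to the natural-scale free parameters
#' (excluding `n0`) is computed by central finite differences at several
#' random interior points, its numeric rank is taken from the singular
#' values with a relative threshold, and the deficiency is
#' `d = h - max(rank)`. A deficiency of zero means full rank (all
#' parameters theoretically estimable); `d > 0` means the model is
#' parameter redundant and only `r` combinations of parameters are
#' estimable. This is a numerical surrogate for symbolic rank computation;
#' near-redundancy (a full-rank model with a nearly singular information
#' matrix) is diagnosed separately by [near_redundancy()].
#'
#' @param spec An [rmer_spec()].
#' @param n_points Number of random interior evaluation points.
#' @param seed Seed for the evaluation points.
#' @param covariate Optional covariate vector for "Z" models.
#' @param sv_tol Relative singular-value threshold: singular values above
#'   `sv_tol * max(sv)` count towards the rank.
#' @param step Optional finite-difference step width passed to the Jacobian.
#' @return An object of class `redundancy_report`: list with `h`, `rank`,
#'   `deficiency`, `status` (`"FR"` full rank / `"PR"` parameter
#'   redundant), per-point ranks, the singular values at the last point,
#'   and `null_directions` (orthonormal basis of the numeric null space at
#'   the last point when `d > 0`).
#' @examples
#' check_redundancy(rmer_spec(removal_design(5, 2), pi = "free", phi = "none"))
#' @export
check_redundancy <- function(spec, n_points = 5, seed = 1, covariate = NULL,
                             sv_tol = 1e-8, step = NULL) {
  template <- theta_template(spec, include_abundance = FALSE)
  h <- nrow(template)
  kappa <- exhaustive_summary(spec, covariate = covariate)
  pts <- random_interior_points(template, n_points, seed)
  jac <- function(x) {
    if (is.null(step)) pracma::jacobian(kappa, x)
    else pracma::jacobian(kappa, x, heps = step)
  }
  ranks <- integer(n_points)
  sv_last <- NULL
  J_last <- NULL
  for (i in seq_len(n_points)) {
    J <- jac(pts[[i]])
    sv <- svd(J, nu = 0, nv = 0)$d
    ranks[i] <- sum(sv > sv_tol * max(sv))
    sv_last <- sv
    J_last <- J
  }
  r <- max(ranks)
  d <- h - r
  null_dirs <- NULL
  if (d > 0) {
    V <- svd(J_last)$v
    null_dirs <- V[, (r + 1):h, drop = FALSE]
    rownames(null_dirs) <- template$name
  }
  structure(
    list(
      model = model_code(spec), h = h, rank = r, deficiency = d,
      status = if (d > 0) "PR" else "FR",
      ranks = ranks, singular_values = sv_last,
      null_directions = null_dirs, n_points = n_points, spec = spec
    ),
    class = "redundancy_report"
  )
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf("<redundancy_report> %s: h = %d, rank = %d, d = %d (%s)\n",
              x$model, x$h, x$rank, x$deficiency, x$status))
  invisible(x)
}

#' @export
tidy.redundancy_report <- function(x, ...) {
  tibble::tibble(model = x$model, h = x$h, rank = x$rank,
                 deficiency = x$deficiency, status = x$status)
}

#' Near-redundancy diagnostic
#'
#' A full-rank model can still be practically unidentifiable when it lies
#' close to a nested parameter-redundant model: the expected information
#' matrix is then nearly singular and estimates are unstable however large
#' the sample. This diagnostic builds the expected multinomial information
#' \eqn{I(\theta) = N \, J^\top \mathrm{diag}(1/\kappa) \, J} (with `J` the
#' Jacobian of the exhaustive summary at the supplied truth) and flags near
#' redundancy when the smallest-to-largest eigenvalue ratio falls below
#' `threshold`. For a parameter-redundant model the smallest eigenvalue is
#' numerically zero. Near-redundancy is inherently scenario-dependent: the
#' flag refers to the supplied parameter values, not to the model as such.
#'
#' @param spec An [rmer_spec()] with deficiency 0 (a `d > 0` model is
#'   trivially singular).
#' @param truth Named natural-scale values of the free parameters (excluding
#'   `n0`), e.g. `c(phi12 = 0.8, p = 0.3)` for an "R-SRC" model.
#' @param N Population size scaling the information.
#' @param covariate Optional covariate vector for "Z" models.
#' @param threshold Eigenvalue-ratio threshold below which the model is
#'   flagged near redundant.
#' @return A list with `min_eigenvalue`, `max_eigenvalue`, `ratio`,
#'   `near_redundant` (logical) and `eigenvalues`.
#' @export
near_redundancy <- function(spec, truth, N = 500, covariate = NULL,
                            threshold = 1e-6) {
  template <- theta_template(spec, include_abundance = FALSE)
  if (!is.null(names(truth))) {
    missing_nm <- setdiff(template$name, names(truth))
    if (length(missing_nm)) {
      abort(paste0("`truth` is missing: ", paste(missing_nm, collapse = ", ")))
    }
    truth <- truth[template$name]
  } else {
    stopifnot(length(truth) == nrow(template))
  }
  kappa <- exhaustive_summary(spec, covariate = covariate)
  x <- as.numeric(truth)
  k_val <- kappa(x)
  keep <- k_val > 0
  if (!all(keep)) {
    warn(sprintf("%d zero-probability cell(s) excluded from the information.",
                 sum(!keep)))
  }
  J <- pracma::jacobian(kappa, x)[keep, , drop = FALSE]
  info <- N * t(J) %*% (J / k_val[keep])
  ev <- eigen((info + t(info)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ratio <- min(ev) / max(ev)
  list(
    model = model_code(spec),
    min_eigenvalue = min(ev), max_eigenvalue = max(ev),
    ratio = ratio, near_redundant = ratio < threshold,
    eigenvalues = ev
  )
}

#' Check the estimable parameter combinations of a redundant model
#'
#' For a parameter-redundant model only certain combinations of the
#' parameters are estimable: any two parameter sets agreeing on those
#' combinations produce identical cell probabilities. For the
#' single-secondary (MER) models the known combinations are
#' * `"NNC"`: \eqn{\pi p}, \eqn{\phi^{21} p},
#'   \eqn{(\phi^{12}-1)p - \phi^{12} - \phi^{21}};
#' * `"NRC"`: \eqn{\pi p}, \eqn{(\phi^{12}-1)p};
#' * `"SRC"`: \eqn{(\phi^{12}-1)p}.
#'
#' The check draws random parameter sets, constructs a second set matched
#' exactly on the combinations (closed form for the three model codes
#' above; a numerical solve for user-supplied combination functions), and
#' compares the exhaustive summaries. As a negative control, an
#' insufficient combination set must fail the invariance.
#'
#' @param spec A parameter-redundant single-secondary [rmer_spec()], model
#'   code "NNC", "NRC" or "SRC" (used to pick the closed-form matching when
#'   `combos` is `NULL`).
#' @param combos Optional list of functions, each taking the named
#'   natural-scale free-parameter vector and returning one combination
#'   value; triggers the numerical matching route.
#' @param n_pairs Number of random matched pairs.
#' @param seed Seed.
#' @param tol Tolerance on the maximum absolute difference of the
#'   exhaustive summaries.
#' @return A list with `invariant` (logical: all pairs matched within
#'   `tol`), `max_diff`, `n_pairs`, `model`.
#' @export
check_estimable_combinations <- function(spec, combos = NULL, n_pairs = 100,
                                         seed = 1, tol = 1e-8) {
  stopifnot(inherits(spec, "rmer_spec"))
  code <- model_code(spec)
  template <- theta_template(spec, include_abundance = FALSE)
  kappa <- exhaustive_summary(spec)
  set.seed(seed)
  draw <- function() {
    x <- vapply(seq_len(nrow(template)), function(r) runif(1, 0.2, 0.8), numeric(1))
    names(x) <- template$name
    x
  }
  max_diff <- 0
  made <- 0L
  guard <- 0L
  while (made < n_pairs && guard < n_pairs * 200L) {
    guard <- guard + 1L
    th1 <- draw()
    th2 <- if (is.null(combos)) {
      matched_pair_closed_form(th1, code)
    } else {
      matched_pair_numeric(th1, combos, template)
    }
    if (is.null(th2)) next
    d <- max(abs(kappa(as.numeric(th1[template$name])) -
                   kappa(as.numeric(th2[template$name]))))
    max_diff <- max(max_diff, d)
    made <- made + 1L
  }
  if (made < n_pairs) {
    warn(sprintf("Only %d of %d valid matched pairs were constructed.", made, n_pairs))
  }
  list(invariant = max_diff <= tol, max_diff = max_diff,
       n_pairs = made, model = code)
}

# closed-form construction of a second parameter set matched on the known
# estimable combinations; returns NULL when the perturbed set leaves (0,1)
matched_pair_closed_form <- function(th, code) {
  p2 <- th[["p"]] * runif(1, 0.7, 1.4)
  if (p2 <= 0 || p2 >= 1 || abs(p2 - th[["p"]]) < 1e-4) return(NULL)
  ok <- function(x) all(x > 0 & x < 1)
  if (code == "NNC") {
    # invariants: pi*p, phi21*p, (phi12 - 1)p - phi12 - phi21
    pi2 <- th[["pi"]] * th[["p"]] / p2
    phi21_2 <- th[["phi21"]] * th[["p"]] / p2
    c3 <- (th[["phi12"]] - 1) * th[["p"]] - th[["phi12"]] - th[["phi21"]]
    phi12_2 <- (c3 + p2 + phi21_2) / (p2 - 1)
    out <- c(pi = pi2, phi12 = phi12_2, phi21 = phi21_2, p = p2)
  } else if (code == "NRC") {
    pi2 <- th[["pi"]] * th[["p"]] / p2
    phi12_2 <- 1 + (th[["phi12"]] - 1) * th[["p"]] / p2
    out <- c(pi = pi2, phi12 = phi12_2, p = p2)
  } else if (code == "SRC") {
    phi12_2 <- 1 + (th[["phi12"]] - 1) * th[["p"]] / p2
    out <- c(phi12 = phi12_2, p = p2)
  } else {
    abort(sprintf("No closed-form estimable combinations known for '%s'.", code))
  }
  if (!ok(out)) return(NULL)
  out
}

# numerical matching: solve combos(th2) = combos(th1) from a random start
matched_pair_numeric <- function(th1, combos, template) {
  target <- vapply(combos, function(f) f(th1), numeric(1))
  obj <- function(u) {
    x <- plogis(u)
    names(x) <- template$name
    sum((vapply(combos, function(f) f(x), numeric(1)) - target)^2)
  }
  start <- qlogis(pmin(pmax(th1 + runif(length(th1), -0.2, 0.2), 0.05), 0.95))
  sol <- tryCatch(optim(start, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-16)),
                  error = function(e) NULL)
  if (is.null(sol) || sol$value > 1e-18) return(NULL)
  th2 <- plogis(sol$par)
  names(th2) <- template$name
  if (max(abs(th2 - th1)) < 1e-3) return(NULL) # same point, uninformative
  th2
}
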