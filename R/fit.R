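BOUNDARY_TOL <- 1e-4

# spec-agnostic log-likelihood dispatch
loglik_for <- function(data, spec, theta, covariate = NULL) {
  if (inherits(spec, "grm_spec")) {
    grm_loglik(data, spec, theta, covariate = covariate)
  } else {
    removal_loglik(data, spec, theta, covariate = covariate)
  }
}

# Fast negative log-likelihood closure: the parameter template, counts and
# occasion layout are resolved once, not at every optimiser evaluation.
make_nll <- function(data, spec, z) {
  template <- theta_template(spec, include_abundance = TRUE)
  design <- attr(data, "design")
  counts <- counts_matrix(data)
  miss <- design_occasions(design)$missing
  K <- design$K
  if (inherits(spec, "grm_spec")) {
    W <- spec$n_populations
    if (length(counts) != W) abort("Population count mismatch between data and spec.")
    fn <- function(theta) {
      natural <- theta_to_natural(theta, template)
      ll <- 0
      for (w in seq_len(W)) {
        p <- if (spec$p == "covariate") {
          plogis(natural[["alpha"]] + natural[["beta"]] * z)
        } else if (spec$shared_p || W == 1L) {
          rep(natural[["p"]], K)
        } else {
          rep(natural[[paste0("p_", w)]], K)
        }
        p[miss] <- 0
        cp <- grm_cells(p)
        n0_nm <- if (W == 1L) "n0" else paste0("n0_", w)
        ll <- ll + loglik_one(counts[[w]], cp$L, cp$L0, natural[[n0_nm]])
      }
      ll
    }
  } else {
    if (length(counts) != spec$n_populations) {
      abort("Population count mismatch between data and spec.")
    }
    fn <- function(theta) {
      natural <- theta_to_natural(theta, template)
      attr(natural, "template") <- template
      params <- expand_core(natural, spec, covariate = z)
      ll <- 0
      for (w in seq_along(counts)) {
        pw <- params[[w]]
        cp <- cell_probs_one(pw$pi, pw$phi12, pw$phi21, pw$p, design)
        ll <- ll + loglik_one(counts[[w]], cp$L, cp$L0, pw$n0)
      }
      ll
    }
  }
  function(theta) {
    ll <- tryCatch(fn(theta), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
}

# method-of-moments-flavoured starting values on the unconstrained scale
default_start <- function(data, spec, template) {
  D_pop <- total_removed(data, by_population = TRUE)
  # depletion ratio within the first primary period with >= 2 sampled counts
  first <- data[data$population == 1 & data$effort == 1, ]
  p0 <- 0.3
  for (i in sort(unique(first$primary))) {
    n <- first$count[first$primary == i][1:2]
    if (length(n) == 2 && !anyNA(n) && n[1] > 0) {
      p0 <- min(max(1 - n[2] / n[1], 0.05), 0.9)
      break
    }
  }
  vapply(seq_len(nrow(template)), function(r) {
    par <- template$par[r]
    link <- template$link[r]
    val <- switch(par,
      pi = 0.5, phi12 = 0.5, phi21 = 0.5, v = 1,
      gamma = 0,
      p = p0, alpha = qlogis(p0), beta = 0,
      n0 = max(D_pop[template$population[r]] / 2, 1),
      0.5
    )
    natural_to_link(val, link)
  }, numeric(1))
}

#' Fit a removal model by maximum likelihood
#'
#' Maximises the product-multinomial log-likelihood of an RMER/MER/IRMER
#' specification (or the geometric baseline, [grm_spec()]) over the free
#' parameters on unconstrained scales (logit for probabilities, log for
#' `n0`), by quasi-Newton search from a method-of-moments start plus random
#' restarts. The best local optimum over restarts is returned; the result
#' is deterministic given the data, the starts and `seed`.
#'
#' @param data A [removal_data()] object with `D >= 1` removals.
#' @param spec An [rmer_spec()] or [grm_spec()].
#' @param covariate Optional covariate column name (or length-`K` vector)
#'   for covariate capture models.
#' @param starts Optional list of starting vectors (unconstrained scale);
#'   these replace the generated random restarts.
#' @param n_restarts Total number of starts when `starts` is `NULL` (the
#'   first is the method-of-moments start, the rest random perturbations).
#' @param seed Seed controlling the random restarts.
#' @param compute_se Compute Hessian-based standard errors at an interior
#'   optimum (skipped automatically at boundary estimates)?
#' @return An object of class `rmer_fit` with elements `theta_hat`
#'   (unconstrained MLEs), `natural` (free parameters on their natural
#'   scales), `params` (the expanded parameter set, see
#'   [expand_parameters()]), `N_hat` (`n0_hat + D` per population),
#'   `loglik`, `h` (parameter count including abundance), `AIC`, `se`
#'   (tibble or `NULL` with `se_reason`), `boundary` (names of parameters at
#'   a boundary), `converged`, and bookkeeping fields. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`, `logLik()`.
#' @examples
#' d <- removal_data(data.frame(primary = 1:3, secondary = 1,
#'                              count = c(100, 60, 36)))
#' fit <- fit_removal(d, grm_spec(), n_restarts = 3, seed = 1)
#' glance(fit)
#' @export
fit_removal <- function(data, spec, covariate = NULL, starts = NULL,
                        n_restarts = 10, seed = NULL, compute_se = FALSE) {
  stopifnot(inherits(data, "removal_data"))
  D <- total_removed(data)
  if (D < 1) abort("Cannot fit a removal model to data with no removals.")
  template <- theta_template(spec, include_abundance = TRUE)
  z <- covariate_vector(data, covariate)
  nll <- make_nll(data, spec, z)
  base <- default_start(data, spec, template)
  if (is.null(starts)) {
    if (!is.null(seed)) set.seed(seed)
    starts <- c(list(base), lapply(seq_len(max(n_restarts - 1L, 0L)), function(i) {
      base + rnorm(length(base), sd = 1)
    }))
  }
  runs <- lapply(starts, function(s) {
    out <- tryCatch(
      optim(s, nll, method = "BFGS", control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(out)) {
      out <- tryCatch(
        optim(s, nll, method = "Nelder-Mead", control = list(maxit = 5000)),
        error = function(e) NULL
      )
    }
    out
  })
  runs <- Filter(function(o) !is.null(o) && is.finite(o$value), runs)
  if (!length(runs)) {
    return(structure(
      list(spec = spec, data = data, converged = FALSE, loglik = -Inf,
           theta_hat = NULL, se = NULL, se_reason = "no successful restart"),
      class = "rmer_fit"
    ))
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  # polish: re-run quasi-Newton from the best optimum until no improvement
  for (i in 1:3) {
    pol <- tryCatch(
      optim(best$par, nll, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(pol) || pol$value > best$value - 1e-10) break
    best <- pol
  }
  theta_hat <- setNames(best$par, template$name)
  natural <- theta_to_natural(theta_hat, template)
  loglik <- -best$value
  converged <- best$convergence == 0 && best$value < 1e9

  # boundary detection on the natural scale
  boundary <- character()
  for (r in seq_len(nrow(template))) {
    val <- natural[[r]]
    at <- switch(template$link[r],
      logit = val < BOUNDARY_TOL || val > 1 - BOUNDARY_TOL,
      logit2 = val < BOUNDARY_TOL || val > 2 - BOUNDARY_TOL,
      log = val < BOUNDARY_TOL,
      FALSE
    )
    if (isTRUE(at)) boundary <- c(boundary, template$name[r])
  }

  params <- if (inherits(spec, "rmer_spec")) {
    expand_parameters(theta_hat, spec, covariate = z)
  } else NULL
  # expanded-scale boundary scan: a constrained or offset parameter can push
  # an expanded probability onto {0, 1} even when every free parameter is
  # interior on its own scale (e.g. a diverging group offset)
  if (!is.null(params)) {
    miss <- design_occasions(attr(data, "design"))$missing
    for (w in seq_along(params)) {
      pw <- params[[w]]
      probs <- c(
        pi = pw$pi,
        setNames(pw$phi12, paste0("phi12_", seq_along(pw$phi12))),
        setNames(pw$phi21, paste0("phi21_", seq_along(pw$phi21))),
        setNames(pw$p[!miss], paste0("p_", which(!miss)))
      )
      bad <- names(probs)[probs < BOUNDARY_TOL | probs > 1 - BOUNDARY_TOL]
      if (length(bad)) {
        tag <- if (length(params) > 1L) paste0(bad, "[pop", w, "]") else bad
        boundary <- union(boundary, tag)
      }
    }
  }
  D_pop <- total_removed(data, by_population = TRUE)
  n0_hat <- natural[template$par == "n0"]
  N_hat <- unname(n0_hat + D_pop)
  h <- nrow(template)
  fit <- structure(
    list(
      spec = spec, data = data, covariate = covariate, template = template,
      theta_hat = theta_hat, natural = natural, params = params,
      D = D, N_hat = N_hat, loglik = loglik, h = h,
      AIC = -2 * loglik + 2 * h,
      boundary = boundary, converged = converged,
      se = NULL, se_reason = "not computed",
      n_starts = length(starts), optim = best
    ),
    class = "rmer_fit"
  )
  if (compute_se) fit <- add_hessian_se(fit)
  fit
}

#' Hessian-based standard errors for a fitted removal model
#'
#' Inverts the observed information (numerical Hessian of the negative
#' log-likelihood at the optimum, on the unconstrained scale) and transforms
#' to the natural scale by the delta method. Standard errors are reported as
#' absent -- with the reason -- when any estimate sits on a boundary of the
#' parameter space or the information matrix is singular; in those cases the
#' nonparametric bootstrap ([bootstrap_removal()]) is the appropriate
#' uncertainty measure.
#'
#' @param fit An `rmer_fit` from [fit_removal()].
#' @return The fit with `se` (tibble `term`, `estimate`, `std.error`, on the
#'   natural scale, plus a `N_<w>` row per population) or `se = NULL` and a
#'   `se_reason`.
#' @export
add_hessian_se <- function(fit) {
  stopifnot(inherits(fit, "rmer_fit"))
  if (length(fit$boundary)) {
    fit["se"] <- list(NULL)
    fit$se_reason <- paste0(
      "boundary estimate(s): ", paste(fit$boundary, collapse = ", "),
      "; use bootstrap_removal()"
    )
    return(fit)
  }
  z <- covariate_vector(fit$data, fit$covariate)
  nll <- function(theta) {
    ll <- loglik_for(fit$data, fit$spec, theta, covariate = z)
    if (!is.finite(ll)) 1e10 else -ll
  }
  H <- pracma::hessian(nll, fit$theta_hat)
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (anyNA(ev) || min(ev) <= 1e-12 * max(abs(ev))) {
    fit["se"] <- list(NULL)
    fit$se_reason <- "observed information singular or not positive definite"
    return(fit)
  }
  V <- solve(H)
  template <- fit$template
  # delta method: d(natural)/d(link) is diagonal
  grad <- vapply(seq_len(nrow(template)), function(r) {
    x <- fit$theta_hat[[r]]
    switch(template$link[r],
      logit = plogis(x) * (1 - plogis(x)),
      logit2 = 2 * plogis(x) * (1 - plogis(x)),
      log = exp(x),
      identity = 1
    )
  }, numeric(1))
  se_nat <- sqrt(pmax(diag(V), 0)) * abs(grad)
  out <- tibble::tibble(term = template$name,
                        estimate = unname(fit$natural),
                        std.error = se_nat)
  # N_hat = n0_hat + D shares n0's SE
  n0_rows <- which(template$par == "n0")
  out <- dplyr::bind_rows(out, tibble::tibble(
    term = paste0("N_", seq_along(n0_rows)),
    estimate = fit$N_hat,
    std.error = se_nat[n0_rows]
  ))
  fit$se <- out
  fit$se_reason <- NULL
  fit
}

#' Nonparametric bootstrap for a fitted removal model
#'
#' Resamples the `D` observed removal records over the occasion cells (a
#' multinomial redraw of the observed counts with `D` held fixed, per
#' population), refits the model to each resample, and summarises the
#' replicate estimates by their empirical standard deviations and percentile
#' confidence intervals. An alternative parametric scheme
#' (`scheme = "parametric"`) redraws full data sets of size `N_hat` from the
#' fitted model instead.
#'
#' @param fit A converged `rmer_fit`.
#' @param B Number of resamples (`B = 0` returns empty replicates).
#' @param seed Master seed.
#' @param scheme `"records"` (default) or `"parametric"`.
#' @param level Confidence level for the percentile intervals.
#' @param n_restarts Optimiser restarts per refit (started at the original
#'   MLE).
#' @return An object of class `rmer_bootstrap`: list with `replicates` (one
#'   row of natural-scale estimates per converged resample), `se`, `ci`
#'   (percentile bounds), `n_failed` and `level`.
#' @export
bootstrap_removal <- function(fit, B = 500, seed = 1,
                              scheme = c("records", "parametric"),
                              level = 0.95, n_restarts = 2) {
  stopifnot(inherits(fit, "rmer_fit"))
  if (!fit$converged) abort("Bootstrap needs a converged original fit.")
  scheme <- match.arg(scheme)
  design <- attr(fit$data, "design")
  occ <- design_occasions(design)
  counts <- counts_matrix(fit$data)
  seeds <- if (B > 0) replicate_seeds(seed, B) else integer()
  est_names <- c(names(fit$natural), paste0("N_", seq_along(fit$N_hat)))

  resample_data <- function(b) {
    set.seed(seeds[b])
    if (scheme == "records") {
      rows <- purrr::map_dfr(seq_along(counts), function(w) {
        n <- counts[[w]]
        Dw <- sum(n)
        new <- if (Dw > 0) rmultinom(1, Dw, n / Dw)[, 1] else n
        dplyr::mutate(occ, population = w, count = as.integer(new), .before = 1)
      })
      removal_data(rows[c("population", "primary", "secondary", "count")],
                   design = design)
    } else {
      pops <- lapply(seq_along(counts), function(w) {
        pw <- fit$params[[w]]
        list(N = round(fit$N_hat[w]), pi = pw$pi, phi12 = pw$phi12,
             phi21 = pw$phi21, p = pw$p)
      })
      simulate_removal(list(design = design, populations = pops))
    }
  }

  reps <- purrr::map(seq_len(B), function(b) {
    dat <- resample_data(b)
    refit <- tryCatch(
      fit_removal(dat, fit$spec, covariate = fit$covariate,
                  starts = c(list(fit$theta_hat),
                             lapply(seq_len(max(n_restarts - 1, 0)), function(i) {
                               fit$theta_hat + rnorm(length(fit$theta_hat), sd = 0.3)
                             }))),
      error = function(e) NULL
    )
    if (is.null(refit) || !refit$converged) return(NULL)
    vals <- c(refit$natural, setNames(refit$N_hat, paste0("N_", seq_along(refit$N_hat))))
    tibble::as_tibble(as.list(vals))
  })
  n_failed <- sum(vapply(reps, is.null, logical(1)))
  replicates <- dplyr::bind_rows(reps)
  if (nrow(replicates)) {
    a <- (1 - level) / 2
    se <- dplyr::summarise(replicates, dplyr::across(dplyr::everything(), sd))
    ci <- purrr::map_dfr(names(replicates), function(nm) {
      q <- quantile(replicates[[nm]], c(a, 1 - a), names = FALSE)
      tibble::tibble(term = nm, lower = q[1], upper = q[2])
    })
  } else {
    se <- tibble::tibble()
    ci <- tibble::tibble(term = character(), lower = numeric(), upper = numeric())
  }
  structure(
    list(replicates = replicates, se = se, ci = ci, n_failed = n_failed,
         B = B, level = level, scheme = scheme),
    class = "rmer_bootstrap"
  )
}

#' @export
print.rmer_bootstrap <- function(x, ...) {
  cat(sprintf("<rmer_bootstrap> %d resamples (%s scheme), %d failed\n",
              x$B, x$scheme, x$n_failed))
  if (nrow(x$ci)) print(x$ci)
  invisible(x)
}

#' Rank candidate models by AIC
#'
#' Fits each specification to the same data and tabulates them by AIC with
#' differences to the best model.
#'
#' @param data A [removal_data()] object.
#' @param specs A list of [rmer_spec()]/[grm_spec()] objects (optionally
#'   named; unnamed entries are labelled by their model code).
#' @param covariate Optional covariate column name, passed to every fit.
#' @param ... Further arguments to [fit_removal()].
#' @return A tibble with columns `model`, `h`, `loglik`, `AIC`,
#'   `delta_AIC`, `converged`, sorted by AIC, plus the fits in attribute
#'   `fits`.
#' @export
rank_models <- function(data, specs, covariate = NULL, ...) {
  if (inherits(specs, "rmer_spec") || inherits(specs, "grm_spec")) specs <- list(specs)
  fits <- lapply(specs, function(s) {
    fit_removal(data, s, covariate = if (s$p == "covariate") covariate else NULL, ...)
  })
  out <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble::tibble(
      model = names(specs)[i] %||% model_code(f$spec),
      h = f$h, loglik = f$loglik, AIC = f$AIC, converged = f$converged
    )
  })
  if (is.null(names(specs)) || any(!nzchar(out$model))) {
    out$model <- vapply(fits, function(f) model_code(f$spec), character(1))
  }
  out <- dplyr::arrange(out, .data$AIC)
  out$delta_AIC <- out$AIC - min(out$AIC)
  attr(out, "fits") <- fits
  out
}
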