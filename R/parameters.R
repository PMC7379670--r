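# Link functions between the unconstrained optimisation scale and the
# natural scale: logit for probabilities, logit of v/2 for the general
# transition-sum parameter v in (0,2), log for n0, identity for regression
# coefficients and group offsets.
link_to_natural <- function(x, link) {
  switch(link,
    logit = plogis(x),
    logit2 = 2 * plogis(x),
    log = exp(x),
    identity = x,
    abort(sprintf("Unknown link '%s'.", link))
  )
}

natural_to_link <- function(x, link) {
  switch(link,
    logit = qlogis(x),
    logit2 = qlogis(x / 2),
    log = log(x),
    identity = x,
    abort(sprintf("Unknown link '%s'.", link))
  )
}

theta_from_natural <- function(values, template) {
  stopifnot(length(values) == nrow(template))
  vapply(seq_along(values), function(i) {
    natural_to_link(values[[i]], template$link[[i]])
  }, numeric(1))
}

theta_to_natural <- function(theta, template) {
  stopifnot(length(theta) == nrow(template))
  out <- vapply(seq_along(theta), function(i) {
    link_to_natural(theta[[i]], template$link[[i]])
  }, numeric(1))
  names(out) <- template$name
  out
}

#' Build a free-parameter vector from natural-scale values
#'
#' Assembles the ordered free-parameter vector of a model, on the
#' unconstrained scale used by the optimiser (logit for probabilities, log
#' for the number never removed `n0`, identity for regression coefficients),
#' from values given on their natural scales.
#'
#' @param spec An [rmer_spec()] or [grm_spec()].
#' @param ... Named natural-scale values. Scalars are recycled over the time
#'   index of a parameter: `pi`, `phi12`, `phi21` (vectors of length
#'   `T - 1`, or `T - 2` under the last-two-equal constraint), `v`, `gamma`
#'   (vector for populations `2..W`), `p` (scalar, or `alpha`/`beta` for the
#'   covariate model, or length-K vector for fully time-varying `p`), and
#'   `n0` (one value per population).
#' @param include_abundance Whether the vector includes `n0`.
#' @return A named numeric vector on the unconstrained scale, in the model's
#'   canonical parameter order.
#' @examples
#' spec <- rmer_spec(removal_design(10, 2), pi = "stationary", phi = "random")
#' pack_parameters(spec, phi12 = 0.8, p = 0.3, n0 = 100)
#' @export
pack_parameters <- function(spec, ..., include_abundance = TRUE) {
  template <- theta_template(spec, include_abundance = include_abundance)
  vals <- list(...)
  universe <- c("pi", "phi12", "phi21", "v", "gamma", "p", "alpha", "beta", "n0")
  unknown <- setdiff(names(vals), universe)
  if (length(unknown)) {
    abort(paste0("Unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  natural <- numeric(nrow(template))
  for (r in seq_len(nrow(template))) {
    par <- template$par[r]
    if (is.null(vals[[par]])) {
      abort(sprintf("Missing value for parameter '%s'.", par))
    }
    v <- vals[[par]]
    idx <- 1L
    if (par %in% c("phi12", "phi21", "p") && !is.na(template$index[r]) && length(v) > 1L) {
      idx <- template$index[r]
    } else if (par %in% c("pi", "n0") && length(v) > 1L) {
      idx <- template$population[r]
    } else if (par == "gamma" && length(v) > 1L) {
      idx <- template$population[r] - 1L
    }
    if (idx > length(v)) abort(sprintf("Too few values supplied for '%s'.", par))
    natural[r] <- v[[idx]]
  }
  out <- theta_from_natural(natural, template)
  names(out) <- template$name
  out
}

# Core expansion from a *named natural-scale* free vector to the full
# parameter set. Returns a list of populations, each with elements
# pi, phi12, phi21 (length T-1), p (length K, 0 at missing occasions), n0.
expand_core <- function(natural, spec, covariate = NULL) {
  template <- attr(natural, "template")
  design <- spec$design
  Tn <- design$n_primary
  nt <- max(Tn - 1L, 0L)
  K <- design$K
  W <- spec$n_populations
  get <- function(nm) unname(natural[[nm]])
  get_series <- function(par) {
    nm <- template$name[template$par == par & !is.na(template$index)]
    if (!length(nm)) nm <- template$name[template$par == par]
    unname(natural[nm])
  }

  # baseline phi12 over the T-1 transitions
  if (nt > 0L) {
    if (spec$phi_time == "constant") {
      phi12_base <- rep(get("phi12"), nt)
    } else {
      v <- get_series("phi12")
      if (spec$last_two_equal) v <- c(v, v[length(v)])
      phi12_base <- v
    }
    if (spec$phi == "none") {
      if (spec$phi_time == "constant") {
        phi21_base <- rep(get("phi21"), nt)
      } else {
        v <- get_series("phi21")
        if (spec$last_two_equal) v <- c(v, v[length(v)])
        phi21_base <- v
      }
    }
  } else {
    phi12_base <- numeric(0)
  }

  # capture probability over the K occasions (shared across populations)
  occ <- design_occasions(design)
  if (spec$p == "constant") {
    p_vec <- rep(get("p"), K)
  } else if (spec$p == "covariate") {
    if (is.null(covariate)) {
      abort("The covariate capture model needs a `covariate` vector (one value per occasion).")
    }
    if (length(covariate) != K) {
      abort(sprintf("`covariate` must have length K = %d, got %d.", K, length(covariate)))
    }
    p_vec <- plogis(get("alpha") + get("beta") * covariate)
  } else {
    p_vec <- numeric(K)
    free_occ <- occ$occasion[!occ$missing]
    p_vec[free_occ] <- unname(natural[paste0("p_", free_occ)])
  }
  p_vec[occ$missing] <- 0

  pops <- vector("list", W)
  for (w in seq_len(W)) {
    if (nt > 0L) {
      phi12 <- phi12_base
      if (spec$additive && w > 1L) {
        phi12 <- plogis(qlogis(phi12_base) + get(paste0("gamma_", w)))
      }
      phi21 <- switch(spec$phi,
        none = phi21_base,
        random = 1 - phi12,
        even = phi12,
        general = {
          out <- get("v") - phi12
          if (any(out < 0 | out > 1)) {
            abort("Constraint v - phi12 gives phi21 outside [0, 1].")
          }
          out
        }
      )
    } else {
      phi12 <- phi21 <- numeric(0)
    }
    if (spec$pi[w] == "stationary") {
      pi_w <- mean(phi21 / (phi12 + phi21))
    } else {
      pi_w <- get(if (W == 1L) "pi" else paste0("pi_", w))
    }
    n0_nm <- if (W == 1L) "n0" else paste0("n0_", w)
    n0_w <- if (n0_nm %in% names(natural)) unname(natural[[n0_nm]]) else NA_real_
    pops[[w]] <- list(pi = pi_w, phi12 = phi12, phi21 = phi21, p = p_vec, n0 = n0_w)
  }
  structure(pops, class = "rmer_params", spec = spec)
}

#' Expand a free-parameter vector to the full parameter set
#'
#' Maps the free parameters of a model (on the unconstrained scale, see
#' [pack_parameters()]) to the full natural-scale parameter set per
#' population: the initial availability \eqn{\pi}, the transition
#' probabilities \eqn{\phi^{12}_i}, \eqn{\phi^{21}_i} for the `T - 1`
#' between-primary transitions, the capture probabilities \eqn{p_{i,j}} for
#' all `K` occasions (zero at occasions without sampling effort), and the
#' number never removed `n0`. All active constraints (stationary \eqn{\pi},
#' random/even/general transition flow, equal last two transitions,
#' covariate-logit capture, additive group offsets) are applied here; the
#' expansion is deterministic given the specification and any finite free
#' vector maps to valid probabilities.
#'
#' @param theta Numeric free-parameter vector on the unconstrained scale
#'   (ordered as in [pack_parameters()]), with or without the trailing `n0`
#'   block.
#' @param spec An [rmer_spec()].
#' @param covariate Optional per-occasion covariate vector (length `K`),
#'   required for the covariate capture model.
#' @return An object of class `rmer_params`: a list with one element per
#'   population, each a list `pi`, `phi12`, `phi21`, `p`, `n0`.
#' @examples
#' spec <- rmer_spec(removal_design(10, 2), pi = "free", phi = "random")
#' theta <- pack_parameters(spec, pi = 0.2, phi12 = 0.8, p = 0.3, n0 = 50)
#' expand_parameters(theta, spec)
#' @export
expand_parameters <- function(theta, spec, covariate = NULL) {
  tpl_full <- theta_template(spec, include_abundance = TRUE)
  tpl_red <- theta_template(spec, include_abundance = FALSE)
  template <- if (length(theta) == nrow(tpl_full)) {
    tpl_full
  } else if (length(theta) == nrow(tpl_red)) {
    tpl_red
  } else {
    abort(sprintf(
      "`theta` has length %d; expected %d (with n0) or %d (without).",
      length(theta), nrow(tpl_full), nrow(tpl_red)
    ))
  }
  natural <- theta_to_natural(theta, template)
  attr(natural, "template") <- template
  expand_core(natural, spec, covariate = covariate)
}

# Natural-scale expansion used by the redundancy diagnostics, where
# derivatives are taken with respect to the natural parameters directly.
expand_natural <- function(natural_values, spec, covariate = NULL,
                           include_abundance = FALSE) {
  template <- theta_template(spec, include_abundance = include_abundance)
  stopifnot(length(natural_values) == nrow(template))
  natural <- as.numeric(natural_values)
  names(natural) <- template$name
  attr(natural, "template") <- template
  expand_core(natural, spec, covariate = covariate)
}

#' @export
print.rmer_params <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<rmer_params> %d population(s)\n", length(x)))
  for (w in seq_along(x)) {
    pw <- x[[w]]
    cat(sprintf(
      "  pop %d: pi = %.4g; mean phi12 = %.4g; mean phi21 = %.4g; mean p = %.4g; n0 = %.4g\n",
      w, pw$pi, mean(pw$phi12), mean(pw$phi21), mean(pw$p[pw$p > 0]), pw$n0
    ))
  }
  invisible(x)
}

#' @export
tidy.rmer_params <- function(x, ...) {
  purrr::map_dfr(seq_along(x), function(w) {
    pw <- x[[w]]
    dplyr::bind_rows(
      tibble::tibble(population = w, term = "pi", index = NA_integer_, value = pw$pi),
      tibble::tibble(
        population = w, term = "phi12",
        index = seq_along(pw$phi12), value = pw$phi12
      ),
      tibble::tibble(
        population = w, term = "phi21",
        index = seq_along(pw$phi21), value = pw$phi21
      ),
      tibble::tibble(
        population = w, term = "p",
        index = seq_along(pw$p), value = pw$p
      ),
      tibble::tibble(population = w, term = "n0", index = NA_integer_, value = pw$n0)
    )
  })
}
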