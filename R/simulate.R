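# Per-replicate seeds derived from one master seed, so replicate r is
# reproducible in isolation. Kept below 2^31 - 1.
replicate_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Built-in simulation scenarios
#'
#' Packages the data-generating truths used throughout the simulation
#' studies: a closed population of `N` individuals moving between an on-site
#' (observable) and an off-site (unobservable) state by a first-order Markov
#' chain between primary periods, removed on capture, sampled over `K`
#' occasions laid out as `K/2` primary periods with two secondary occasions
#' each, with constant capture probability `p = 0.3`.
#'
#' * `"constant"`: constant transitions, `N = 500`. Scenario 1 (individuals
#'   tend to stay off-site): \eqn{\phi^{12} = 0.8, \phi^{21} = 0.2};
#'   scenario 2 (tend to stay on-site): \eqn{\phi^{12} = 0.4,
#'   \phi^{21} = 0.6}. \eqn{\pi} is the first element of the stationary
#'   distribution of the transition matrix.
#' * `"time_varying"`: random-emigration time-varying transitions
#'   (\eqn{\phi^{21}_i = 1 - \phi^{12}_i}), `N = 500`. For `K = 20`,
#'   \eqn{\phi^{12}} is (0.8, 0.7, 0.8, 0.3, 0.6, 0.7, 0.8, 0.6, 0.6) in
#'   scenario 1 and (0.4, 0.4, 0.8, 0.4, 0.4, 0.8, 0.4, 0.4, 0.4) in
#'   scenario 2; for `K = 10`, (0.7, 0.2, 0.7, 0.7) and (0.3, 0.8, 0.3,
#'   0.3). \eqn{\pi} is the mean across time of the first element of the
#'   stationary distributions.
#' * `"integrated"`: two populations of sizes `N = 300` and `M = 200`.
#'   Population 1 follows the `"time_varying"` truth of the same scenario;
#'   population 2's transitions are shifted on the logit scale by the
#'   additive offset `gamma2 = -0.5`.
#'
#' @param setting `"constant"`, `"time_varying"` or `"integrated"`.
#' @param scenario 1 (low capture, individuals tend to stay off-site) or
#'   2 (low capture, tend to stay on-site).
#' @param K Total number of occasions, 10 or 20 (always two secondaries per
#'   primary period).
#' @param gamma2 Additive logit offset for population 2 (integrated setting).
#' @return An object of class `removal_scenario`: a list with the
#'   [removal_design()], a list `populations` (each with `N`, `pi`, `phi12`,
#'   `phi21`, `p`), and the name of the matching generating model.
#' @export
removal_scenario <- function(setting = c("constant", "time_varying", "integrated"),
                             scenario = 1, K = 20, gamma2 = -0.5) {
  setting <- match.arg(setting)
  stopifnot(scenario %in% c(1, 2), K %% 2 == 0, K >= 4)
  Tn <- K / 2
  design <- removal_design(Tn, 2)
  nt <- Tn - 1
  p <- 0.3
  tv_truth <- function(K, scenario) {
    if (K == 20) {
      if (scenario == 1) c(0.8, 0.7, 0.8, 0.3, 0.6, 0.7, 0.8, 0.6, 0.6)
      else c(0.4, 0.4, 0.8, 0.4, 0.4, 0.8, 0.4, 0.4, 0.4)
    } else if (K == 10) {
      if (scenario == 1) c(0.7, 0.2, 0.7, 0.7) else c(0.3, 0.8, 0.3, 0.3)
    } else {
      abort("Time-varying truths are defined for K = 10 or K = 20.")
    }
  }
  make_pop <- function(N, phi12, phi21) {
    list(N = N, pi = mean(phi21 / (phi12 + phi21)),
         phi12 = phi12, phi21 = phi21, p = rep(p, K))
  }
  if (setting == "constant") {
    phi12 <- rep(if (scenario == 1) 0.8 else 0.4, nt)
    phi21 <- rep(if (scenario == 1) 0.2 else 0.6, nt)
    pops <- list(make_pop(500, phi12, phi21))
    fit_code <- "R-SRC"
  } else if (setting == "time_varying") {
    phi12 <- tv_truth(K, scenario)
    pops <- list(make_pop(500, phi12, 1 - phi12))
    fit_code <- "R-SRtC"
  } else {
    phi12_1 <- tv_truth(K, scenario)
    phi12_2 <- plogis(qlogis(phi12_1) + gamma2)
    pops <- list(make_pop(300, phi12_1, 1 - phi12_1),
                 make_pop(200, phi12_2, 1 - phi12_2))
    fit_code <- "IR-S1,2RatC"
  }
  structure(
    list(design = design, populations = pops, setting = setting,
         scenario = scenario, K = K, gamma2 = if (setting == "integrated") gamma2 else NULL,
         fit_code = fit_code),
    class = "removal_scenario"
  )
}

#' @export
print.removal_scenario <- function(x, ...) {
  cat(sprintf(
    "<removal_scenario> %s transitions, scenario %d, K = %d, %d population(s)\n",
    x$setting, x$scenario, x$K, length(x$populations)
  ))
  invisible(x)
}

#' Simulate removal data
#'
#' Generates removal counts under the temporary-emigration data-generating
#' process, either by simulating each individual's hidden state trajectory
#' and captures (`method = "individual"`) or by a single multinomial draw of
#' `(n0, n_{i,j})` from the model cell probabilities
#' (`method = "multinomial"`). The two are distributionally identical; the
#' individual-based route exists as a mechanistic cross-check of the cell
#' probabilities.
#'
#' @param scenario A [removal_scenario()], or any list with elements
#'   `design` and `populations` (each population a list `N`, `pi`, `phi12`,
#'   `phi21`, `p` with `p` of length `K`).
#' @param seed Seed for the draw (set when non-`NULL`).
#' @param method `"multinomial"` or `"individual"`.
#' @return A [removal_data()] tibble.
#' @export
simulate_removal <- function(scenario, seed = NULL,
                             method = c("multinomial", "individual")) {
  method <- match.arg(method)
  design <- scenario$design
  occ <- design_occasions(design)
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map_dfr(seq_along(scenario$populations), function(w) {
    pop <- scenario$populations[[w]]
    n <- if (method == "multinomial") {
      sim_multinomial_one(pop, design)
    } else {
      sim_individual_one(pop, design)
    }
    dplyr::mutate(occ, population = w, count = n, .before = 1)
  })
  removal_data(rows[c("population", "primary", "secondary", "count")],
               design = design)
}

sim_multinomial_one <- function(pop, design) {
  p_vec <- pop$p
  p_vec[design_occasions(design)$missing] <- 0
  cp <- cell_probs_one(pop$pi, pop$phi12, pop$phi21, p_vec, design)
  draw <- rmultinom(1, pop$N, c(cp$L, cp$L0))[, 1]
  as.integer(head(draw, -1))
}

sim_individual_one <- function(pop, design) {
  N <- pop$N
  Tn <- design$n_primary
  k <- design$k
  occ <- design_occasions(design)
  p_vec <- pop$p
  p_vec[occ$missing] <- 0
  onsite <- runif(N) < pop$pi
  removed <- rep(FALSE, N)
  counts <- integer(design$K)
  m <- 0L
  for (i in seq_len(Tn)) {
    for (j in seq_len(k[i])) {
      m <- m + 1L
      at_risk <- onsite & !removed
      caught <- at_risk & (runif(N) < p_vec[m])
      counts[m] <- sum(caught)
      removed <- removed | caught
    }
    if (i < Tn) {
      free <- !removed
      u <- runif(N)
      leave <- free & onsite & (u < pop$phi12[i])
      arrive <- free & !onsite & (u < pop$phi21[i])
      onsite[leave] <- FALSE
      onsite[arrive] <- TRUE
    }
  }
  counts
}

#' Run a parameter-recovery simulation study
#'
#' Simulates `n_reps` replicate data sets from a scenario truth, fits a
#' model to each, and collects the replicate maximum-likelihood estimates.
#' Each replicate gets its own seed derived from the master seed, so any
#' replicate can be re-run in isolation. Non-convergent replicates are
#' flagged, not fatal.
#'
#' @param scenario A [removal_scenario()].
#' @param spec Model to fit; defaults to the scenario's matching generating
#'   structure.
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param method Simulator to use, see [simulate_removal()].
#' @param n_restarts Optimiser restarts per replicate fit.
#' @return A tibble of class `removal_study`, one row per replicate, with
#'   the replicate `seed`, `converged`, `D`, the natural-scale estimates of
#'   every free parameter and `N_hat_<w>` per population. The truth is
#'   attached as attribute `truth`; summarise with [summarise_study()].
#' @export
run_removal_study <- function(scenario, spec = NULL, n_reps = 100, seed = 1,
                              method = c("multinomial", "individual"),
                              n_restarts = 3) {
  method <- match.arg(method)
  if (is.null(spec)) {
    spec <- parse_model_code(scenario$fit_code, scenario$design,
                             n_populations = length(scenario$populations))
  }
  seeds <- replicate_seeds(seed, n_reps)
  rows <- purrr::map_dfr(seq_len(n_reps), function(r) {
    data <- simulate_removal(scenario, seed = seeds[r], method = method)
    fit <- tryCatch(
      fit_removal(data, spec, n_restarts = n_restarts, seed = seeds[r]),
      error = function(e) NULL
    )
    base <- tibble::tibble(replicate = r, seed = seeds[r],
                           D = total_removed(data))
    if (is.null(fit)) {
      return(dplyr::mutate(base, converged = FALSE, boundary = NA))
    }
    est <- as.list(fit$natural)
    names(est) <- names(fit$natural)
    Nh <- as.list(fit$N_hat)
    names(Nh) <- paste0("N_hat_", seq_along(fit$N_hat))
    dplyr::bind_cols(
      base,
      tibble::tibble(converged = fit$converged,
                     boundary = length(fit$boundary) > 0),
      tibble::as_tibble(est), tibble::as_tibble(Nh)
    )
  })
  structure(rows, truth = scenario,
            class = c("removal_study", class(tibble::tibble())))
}

#' Summarise a simulation study
#'
#' Replicates whose maximum-likelihood estimates sit on a boundary of the
#' parameter space are excluded from the moments by default: a boundary
#' replicate has no finite interior MLE for the affected parameters (a
#' diverging group offset, a transition probability at 0/1), so including
#' it turns the mean into an artefact of the link-scale stopping point.
#' The number excluded is visible in the `boundary` column of the study.
#'
#' @param study The tibble returned by [run_removal_study()].
#' @param converged_only Drop non-convergent replicates first?
#' @param exclude_boundary Drop replicates with boundary estimates?
#' @return A tibble with one row per estimated quantity: mean, empirical SD,
#'   and (where the scenario truth defines it) the truth and bias.
#' @export
summarise_study <- function(study, converged_only = TRUE,
                            exclude_boundary = TRUE) {
  scn <- attr(study, "truth")
  if (converged_only) study <- dplyr::filter(study, .data$converged)
  if (exclude_boundary && "boundary" %in% names(study)) {
    study <- dplyr::filter(study, !.data$boundary)
  }
  est_cols <- setdiff(names(study),
                      c("replicate", "seed", "D", "converged", "boundary"))
  long <- tidyr::pivot_longer(study[c(est_cols)], dplyr::everything(),
                              names_to = "term", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$term),
    mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
  )
  out$truth <- vapply(out$term, scenario_truth_value, numeric(1), scn = scn)
  out$bias <- out$mean - out$truth
  out[order(match(out$term, est_cols)), ]
}

# truth lookup for a named estimate column, NA when the scenario does not
# pin down that quantity
scenario_truth_value <- function(term, scn) {
  pops <- scn$populations
  if (grepl("^N_hat_", term)) {
    w <- as.integer(sub("^N_hat_", "", term))
    return(pops[[w]]$N)
  }
  if (term == "p") return(pops[[1]]$p[1])
  if (term == "pi") return(pops[[1]]$pi)
  if (grepl("^pi_", term)) return(pops[[as.integer(sub("^pi_", "", term))]]$pi)
  if (grepl("^gamma_", term) && !is.null(scn$gamma2)) return(scn$gamma2)
  if (term == "phi12") return(pops[[1]]$phi12[1])
  if (term == "phi21") return(pops[[1]]$phi21[1])
  if (grepl("^phi12_", term)) {
    i <- as.integer(sub("^phi12_", "", term))
    return(pops[[1]]$phi12[i])
  }
  if (grepl("^phi21_", term)) {
    i <- as.integer(sub("^phi21_", "", term))
    return(pops[[1]]$phi21[i])
  }
  if (grepl("^n0", term)) return(NA_real_) # replicate-specific truth N - D
  NA_real_
}
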