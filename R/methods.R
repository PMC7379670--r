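#' @export
print.rmer_fit <- function(x, ...) {
  code <- model_code(x$spec)
  if (is.null(x$theta_hat)) {
    cat(sprintf("<rmer_fit> %s: NOT CONVERGED (%s)\n", code, x$se_reason))
    return(invisible(x))
  }
  cat(sprintf("<rmer_fit> %s: logLik = %.3f, h = %d, AIC = %.2f%s\n",
              code, x$loglik, x$h, x$AIC,
              if (!x$converged) "  [not converged]" else ""))
  cat(sprintf("  D = %d removed; N_hat = %s\n", x$D,
              paste(sprintf("%.2f", x$N_hat), collapse = ", ")))
  if (length(x$boundary)) {
    cat("  boundary estimates:", paste(x$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
logLik.rmer_fit <- function(object, ...) {
  structure(object$loglik, df = object$h, class = "logLik")
}

#' Tidy a fitted removal model
#'
#' @param x An `rmer_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter (natural scale) plus a
#'   derived `N_<w>` abundance row per population; `std.error` is filled
#'   when Hessian standard errors are available (see [add_hessian_se()]).
#' @export
tidy.rmer_fit <- function(x, ...) {
  if (is.null(x$theta_hat)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric()))
  }
  if (!is.null(x$se)) return(x$se)
  out <- tibble::tibble(term = names(x$natural),
                        estimate = unname(x$natural),
                        std.error = NA_real_)
  dplyr::bind_rows(out, tibble::tibble(
    term = paste0("N_", seq_along(x$N_hat)),
    estimate = x$N_hat, std.error = NA_real_
  ))
}

#' Glance at a fitted removal model
#'
#' @param x An `rmer_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `h`, `logLik`, `AIC`, `D`,
#'   `n_populations`, `converged`, `boundary`.
#' @export
glance.rmer_fit <- function(x, ...) {
  tibble::tibble(
    model = model_code(x$spec),
    h = x$h %||% NA_integer_,
    logLik = x$loglik,
    AIC = x$AIC %||% NA_real_,
    D = x$D %||% NA_integer_,
    n_populations = x$spec$n_populations,
    converged = x$converged,
    boundary = length(x$boundary %||% character()) > 0
  )
}

#' Observed and expected removal counts of a fit
#'
#' @param fit A converged `rmer_fit`.
#' @return A tibble with per-occasion observed counts and fitted expected
#'   counts `N_hat * L_{i,j}`.
#' @export
expected_counts <- function(fit) {
  stopifnot(inherits(fit, "rmer_fit"))
  design <- attr(fit$data, "design")
  if (inherits(fit$spec, "grm_spec")) {
    template <- fit$template
    occ <- design_occasions(design)
    z <- covariate_vector(fit$data, fit$covariate)
    out <- purrr::map_dfr(seq_len(fit$spec$n_populations), function(w) {
      p <- if (fit$spec$p == "covariate") {
        plogis(fit$natural[["alpha"]] + fit$natural[["beta"]] * z)
      } else if (fit$spec$shared_p || fit$spec$n_populations == 1L) {
        rep(fit$natural[["p"]], design$K)
      } else rep(fit$natural[[paste0("p_", w)]], design$K)
      p[occ$missing] <- 0
      cp <- grm_cells(p)
      dplyr::mutate(occ, population = w, expected = fit$N_hat[w] * cp$L, .before = 1)
    })
  } else {
    cp <- cell_probabilities(fit$params, design)
    out <- dplyr::mutate(cp, expected = fit$N_hat[.data$population] * .data$prob)
  }
  obs <- fit$data[c("population", "primary", "secondary", "count")]
  dplyr::left_join(out, obs, by = c("population", "primary", "secondary"))
}

#' Plot observed against expected removal counts
#'
#' @param object A converged `rmer_fit`.
#' @param ... Unused.
#' @return A ggplot: observed counts (points) and fitted expected counts
#'   (line) over the running occasion index, one panel per population.
#' @export
autoplot.rmer_fit <- function(object, ...) {
  df <- expected_counts(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occasion)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "firebrick", size = 1) +
    ggplot2::facet_wrap(~population, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "occasion", y = "removals",
                  title = sprintf("%s: observed (bars) vs fitted (line)",
                                  model_code(object$spec)))
}

#' Plot the estimate distributions of a simulation study
#'
#' @param object A `removal_study` tibble from [run_removal_study()].
#' @param terms Optional subset of estimate columns to show.
#' @param ... Unused.
#' @return A ggplot of replicate-estimate boxplots with the generating
#'   truths as horizontal lines, one panel per parameter.
#' @export
autoplot.removal_study <- function(object, terms = NULL, ...) {
  scn <- attr(object, "truth")
  est_cols <- setdiff(names(object),
                      c("replicate", "seed", "D", "converged", "boundary"))
  if (!is.null(terms)) est_cols <- intersect(est_cols, terms)
  long <- tidyr::pivot_longer(
    dplyr::filter(object, .data$converged)[est_cols],
    dplyr::everything(), names_to = "term", values_to = "estimate"
  )
  truths <- tibble::tibble(
    term = est_cols,
    truth = vapply(est_cols, scenario_truth_value, numeric(1), scn = scn)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(data = truths[!is.na(truths$truth), ],
                        ggplot2::aes(yintercept = .data$truth),
                        colour = "firebrick", linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "replicate estimate")
}
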