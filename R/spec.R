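#' Specify a removal model with temporary emigration
#'
#' Declares an RMER/MER/IRMER model: the sampling layout plus the constraints
#' binding the initial-state probability \eqn{\pi}, the between-primary
#' transition probabilities \eqn{\phi^{12}_i} (on-site to off-site) and
#' \eqn{\phi^{21}_i} (off-site to on-site), and the capture probability
#' \eqn{p_{i,j}}. The constraint letters follow the field's model-naming
#' convention, see [model_code()].
#'
#' @param design A [removal_design()], shared by all populations.
#' @param pi Initial-state constraint, per population (recycled):
#'   `"stationary"` ("S") sets \eqn{\pi} to the mean across time of the first
#'   element of the stationary distributions of the transition matrices,
#'   \eqn{\pi = \frac{1}{T-1}\sum_i \phi^{21}_i/(\phi^{12}_i+\phi^{21}_i)};
#'   `"free"` ("N") estimates it.
#' @param phi Transition constraint: `"none"` ("N", both directions free),
#'   `"random"` ("R", random emigration \eqn{\phi^{21}_i = 1-\phi^{12}_i}),
#'   `"even"` ("E", even flow \eqn{\phi^{21}_i = \phi^{12}_i}), or
#'   `"general"` ("V", \eqn{\phi^{12}_i + \phi^{21}_i = v} with
#'   \eqn{v \in (0,2)} an extra free parameter).
#' @param phi_time `"constant"` or `"time_varying"` transitions.
#' @param p Capture-probability model: `"constant"` ("C"), `"covariate"`
#'   ("Z", \eqn{\mathrm{logit}(p_{i,j}) = \alpha + \beta z_{i,j}}), or
#'   `"time_varying"` ("T", one free \eqn{p_{i,j}} per sampled occasion; the
#'   fully time-dependent model, which is parameter redundant on its own).
#' @param last_two_equal Constraint "2": the penultimate and final transition
#'   probabilities are equal (requires `phi_time = "time_varying"`).
#' @param additive For integrated models: population `w > 1` gets an additive
#'   logit offset on the baseline transition probabilities,
#'   \eqn{\mathrm{logit}(\phi^{12}_{i,w}) = \eta_{1,i} + \gamma_w}
#'   (constraint "Ra"/"Ea"). Without it, transitions are shared across
#'   populations.
#' @param n_populations Number of independently removed populations sharing
#'   the design (and the capture model); `> 1` gives an integrated (IRMER)
#'   model whose likelihood is the product over populations.
#'
#' @return An object of class `rmer_spec`.
#' @examples
#' d <- removal_design(10, 2)
#' rmer_spec(d, pi = "stationary", phi = "random")          # R-SRC
#' rmer_spec(d, pi = "free", phi = "none", p = "covariate") # R-NNZ
#' @export
rmer_spec <- function(design,
                      pi = "stationary",
                      phi = c("random", "even", "none", "general"),
                      phi_time = c("constant", "time_varying"),
                      p = c("constant", "covariate", "time_varying"),
                      last_two_equal = FALSE,
                      additive = FALSE,
                      n_populations = 1L) {
  stopifnot(inherits(design, "removal_design"))
  n_populations <- as.integer(n_populations)
  stopifnot(n_populations >= 1L)
  pi <- match.arg(pi, c("stationary", "free"), several.ok = TRUE)
  if (length(pi) == 1L) pi <- rep(pi, n_populations)
  if (length(pi) != n_populations) abort("`pi` must have length 1 or `n_populations`.")
  phi <- match.arg(phi)
  phi_time <- match.arg(phi_time)
  p <- match.arg(p)
  if (last_two_equal && phi_time != "time_varying") {
    abort('Constraint "2" (`last_two_equal`) requires time-varying transitions.')
  }
  if (additive && n_populations < 2L) {
    abort("`additive` group offsets require `n_populations` > 1.")
  }
  if (design$n_primary < 2L && any(pi == "stationary")) {
    abort("The stationary initial-state constraint needs at least 2 primary periods.")
  }
  if (last_two_equal && design$n_primary < 3L) {
    abort('Constraint "2" needs at least 3 primary periods.')
  }
  out <- structure(
    list(
      design = design, pi = pi, phi = phi, phi_time = phi_time, p = p,
      last_two_equal = isTRUE(last_two_equal), additive = isTRUE(additive),
      n_populations = n_populations
    ),
    class = "rmer_spec"
  )
  out$code <- model_code(out)
  out
}

#' @export
print.rmer_spec <- function(x, ...) {
  cat(sprintf(
    "<rmer_spec> %s  (%d population%s, T = %d, K = %d, h = %d incl. abundance)\n",
    x$code, x$n_populations, if (x$n_populations > 1) "s" else "",
    x$design$n_primary, x$design$K, n_free_parameters(x, include_abundance = TRUE)
  ))
  invisible(x)
}

#' Model code label
#'
#' Builds the conventional "MODEL-XYZ" label of a specification: the prefix
#' is "R-" for a robust design, "IR-" for an integrated robust design, and
#' empty for a single-secondary (MER) design; "X" encodes the initial-state
#' constraint ("S"/"N", with population subscripts such as "S1,2" for
#' integrated models), "Y" the transition constraint ("N"/"R"/"E"/"V" with
#' suffixes "a" for an additive group offset, "2" for equal last two
#' transitions, "t" for time variation), and "Z" whether capture probability
#' is constant ("C") or covariate-driven ("Z").
#'
#' @param spec An [rmer_spec()] or [grm_spec()].
#' @return A character scalar, e.g. `"R-SRtC"`, `"NNC"`, `"IR-S1,2RatZ"`.
#' @export
model_code <- function(spec) {
  if (inherits(spec, "grm_spec")) {
    return(paste0("G-", if (spec$p == "constant") "C" else "Z"))
  }
  stopifnot(inherits(spec, "rmer_spec"))
  robust <- any(spec$design$k > 1L)
  W <- spec$n_populations
  prefix <- if (W > 1L) "IR-" else if (robust) "R-" else ""
  stat <- which(spec$pi == "stationary")
  X <- if (length(stat) == 0L) {
    "N"
  } else if (W == 1L) {
    "S"
  } else {
    paste0("S", paste(stat, collapse = ","))
  }
  base <- c(none = "N", random = "R", even = "E", general = "V")[[spec$phi]]
  # the unconstrained-transition label is dropped when the last-two-equal
  # constraint is present ("N2t" would be redundant: the code is "2t")
  if (spec$phi == "none" && spec$last_two_equal) base <- ""
  Y <- paste0(
    base,
    if (spec$additive) "a" else "",
    if (spec$last_two_equal) "2" else "",
    if (spec$phi_time == "time_varying") "t" else ""
  )
  Z <- switch(spec$p, constant = "C", covariate = "Z", time_varying = "T")
  paste0(prefix, X, Y, Z)
}

#' Parse a model code into a specification
#'
#' Inverse of [model_code()]: builds the [rmer_spec()] (or [grm_spec()], for
#' codes "G-C"/"G-Z") named by a label such as `"R-SRtC"` or `"IR-S1,2RatZ"`.
#'
#' @param code Character scalar model code.
#' @param design The [removal_design()] to attach.
#' @param n_populations Number of populations; defaults to 2 for "IR-" codes
#'   and 1 otherwise.
#' @return An [rmer_spec()] or [grm_spec()].
#' @export
parse_model_code <- function(code, design, n_populations = NULL) {
  stopifnot(is.character(code), length(code) == 1L)
  if (grepl("^G-[CZ]$", code)) {
    return(grm_spec(p = if (code == "G-C") "constant" else "covariate"))
  }
  # population subscripts on "S" (e.g. "S1,2") only occur in integrated codes,
  # so they are only admitted there -- otherwise "S2tC" would be ambiguous
  x_pat <- if (startsWith(code, "IR-")) "S[0-9,]*|N" else "S|N"
  m <- regmatches(code, regexec(
    paste0("^(IR-|R-)?(", x_pat, ")([NREV]?)(a?)(2?)(t?)([CZT])$"), code
  ))[[1]]
  if (length(m) == 0L) abort(sprintf("Cannot parse model code '%s'.", code))
  if (m[4] == "" && m[6] != "2") {
    abort(sprintf("Cannot parse model code '%s'.", code))
  }
  prefix <- m[2]
  if (is.null(n_populations)) n_populations <- if (prefix == "IR-") 2L else 1L
  if (prefix == "" && any(design$k > 1L)) {
    abort(sprintf("Code '%s' names a single-secondary model but the design has k > 1.", code))
  }
  pi <- rep("free", n_populations)
  if (startsWith(m[3], "S")) {
    idx <- m[3]
    if (idx == "S") {
      pi[] <- "stationary"
    } else {
      pops <- as.integer(strsplit(sub("^S", "", idx), ",")[[1]])
      pi[pops] <- "stationary"
    }
  }
  rmer_spec(
    design,
    pi = pi,
    phi = c(N = "none", R = "random", E = "even", V = "general",
            "none")[[if (m[4] == "") 5L else m[4]]],
    phi_time = if (m[7] == "t") "time_varying" else "constant",
    p = switch(m[8], C = "constant", Z = "covariate", T = "time_varying"),
    last_two_equal = m[6] == "2",
    additive = m[5] == "a",
    n_populations = n_populations
  )
}

# Free-parameter template: one row per free parameter, in canonical order.
# Columns: name (unique), par (base symbol), index (time index or NA),
# population (NA when shared), link ("logit", "log", "identity", "logit2").
theta_template <- function(spec, include_abundance = TRUE) {
  UseMethod("theta_template")
}

#' @export
theta_template.rmer_spec <- function(spec, include_abundance = TRUE) {
  W <- spec$n_populations
  Tn <- spec$design$n_primary
  nt <- max(Tn - 1L, 0L)
  rows <- list()
  add <- function(name, par, index = NA_integer_, population = NA_integer_,
                  link = "logit") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, par = par, index = as.integer(index),
      population = as.integer(population), link = link
    )
  }
  for (w in seq_len(W)) {
    if (spec$pi[w] == "free") {
      add(if (W == 1L) "pi" else paste0("pi_", w), "pi", population = w)
    }
  }
  if (nt > 0L) {
    n_phi <- if (spec$phi_time == "time_varying") nt - spec$last_two_equal else 1L
    if (spec$phi_time == "constant") {
      add("phi12", "phi12", index = 1L)
      if (spec$phi == "none") add("phi21", "phi21", index = 1L)
    } else {
      for (i in seq_len(n_phi)) add(paste0("phi12_", i), "phi12", index = i)
      if (spec$phi == "none") {
        for (i in seq_len(n_phi)) add(paste0("phi21_", i), "phi21", index = i)
      }
    }
    if (spec$phi == "general") add("v", "v", link = "logit2")
    if (spec$additive) {
      for (w in 2:W) add(paste0("gamma_", w), "gamma", population = w, link = "identity")
    }
  }
  if (spec$p == "constant") {
    add("p", "p")
  } else if (spec$p == "covariate") {
    add("alpha", "alpha", link = "identity")
    add("beta", "beta", link = "identity")
  } else {
    occ <- design_occasions(spec$design)
    for (m in occ$occasion[!occ$missing]) add(paste0("p_", m), "p", index = m)
  }
  if (include_abundance) {
    for (w in seq_len(W)) {
      add(if (W == 1L) "n0" else paste0("n0_", w), "n0", population = w, link = "log")
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
theta_template.grm_spec <- function(spec, include_abundance = TRUE) {
  W <- spec$n_populations
  rows <- list()
  add <- function(name, par, population = NA_integer_, link = "logit") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, par = par, index = NA_integer_,
      population = as.integer(population), link = link
    )
  }
  if (spec$p == "constant") {
    if (spec$shared_p || W == 1L) {
      add("p", "p")
    } else {
      for (w in seq_len(W)) add(paste0("p_", w), "p", population = w)
    }
  } else {
    add("alpha", "alpha", link = "identity")
    add("beta", "beta", link = "identity")
  }
  if (include_abundance) {
    for (w in seq_len(W)) {
      add(if (W == 1L) "n0" else paste0("n0_", w), "n0", population = w, link = "log")
    }
  }
  dplyr::bind_rows(rows)
}

#' Count the free parameters of a model
#'
#' Returns `h`, the number of free parameters. Two conventions are in use:
#' model-selection tables (and AIC) count one abundance parameter `n0` per
#' population (`include_abundance = TRUE`), while redundancy tables count
#' only the probability-scale parameters (`include_abundance = FALSE`).
#'
#' @param spec An [rmer_spec()] or [grm_spec()].
#' @param include_abundance Count the per-population `n0`?
#' @return Integer `h`.
#' @examples
#' d <- removal_design(10, 2)
#' # fully time-dependent single-population model: K + 2T parameters
#' n_free_parameters(rmer_spec(d, pi = "free", phi = "none",
#'   phi_time = "time_varying", p = "covariate"))
#' @export
n_free_parameters <- function(spec, include_abundance = TRUE) {
  nrow(theta_template(spec, include_abundance = include_abundance))
}
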