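#' Robust-design sampling layout
#'
#' A removal study is laid out as `n_primary` primary periods, the
#' population being open to movement between the study site and an
#' unobservable off-site state only between primary periods, with
#' `n_secondary[i]` secondary capture occasions inside primary period `i`
#' during which the population is closed. When every primary period holds a
#' single secondary occasion the layout reduces to a plain occasion-per-period
#' (non-robust) removal design.
#'
#' @param n_primary Number of primary periods (`>= 1`).
#' @param n_secondary Number of secondary occasions per primary period;
#'   either a scalar (recycled) or a vector of length `n_primary`.
#' @param missing Optional data frame with columns `primary` and `secondary`
#'   marking occasions with no sampling effort. Capture probability is forced
#'   to zero there, so no removals can be recorded.
#'
#' @return An object of class `removal_design`: a list with elements
#'   `n_primary`, `k` (per-primary secondary counts), `K` (total occasions)
#'   and `missing` (tibble of zero-effort occasions).
#' @examples
#' removal_design(10, 2)   # 10 primaries, 2 secondaries each, K = 20
#' removal_design(10, 1)   # single-secondary (non-robust) layout, K = 10
#' @export
removal_design <- function(n_primary, n_secondary, missing = NULL) {
  n_primary <- as.integer(n_primary)
  if (length(n_primary) != 1L || is.na(n_primary) || n_primary < 1L) {
    abort("`n_primary` must be a single integer >= 1.")
  }
  k <- as.integer(n_secondary)
  if (length(k) == 1L) k <- rep(k, n_primary)
  if (length(k) != n_primary || anyNA(k) || any(k < 1L)) {
    abort("`n_secondary` must be a positive scalar or vector of length `n_primary`.")
  }
  if (is.null(missing)) {
    missing <- tibble::tibble(primary = integer(), secondary = integer())
  } else {
    missing <- tibble::as_tibble(missing)[c("primary", "secondary")]
    missing$primary <- as.integer(missing$primary)
    missing$secondary <- as.integer(missing$secondary)
    bad <- missing$primary < 1L | missing$primary > n_primary |
      missing$secondary < 1L | missing$secondary > k[missing$primary]
    if (anyNA(bad) || any(bad)) abort("`missing` contains occasions outside the design.")
    missing <- dplyr::distinct(missing)
  }
  out <- structure(
    list(n_primary = n_primary, k = k, K = sum(k), missing = missing),
    class = "removal_design"
  )
  out$occasions <- build_occasions(out)
  out
}

build_occasions <- function(design) {
  out <- tibble::tibble(
    primary = rep(seq_len(design$n_primary), design$k),
    secondary = unlist(lapply(design$k, seq_len), use.names = FALSE)
  )
  out$occasion <- seq_len(nrow(out))
  out$missing <- FALSE
  if (nrow(design$missing)) {
    key <- paste(out$primary, out$secondary)
    out$missing <- key %in% paste(design$missing$primary, design$missing$secondary)
  }
  out
}

#' Occasion table for a design
#'
#' Enumerates the occasions of a design in canonical order (primary, then
#' secondary), with the running occasion index `occasion = 1..K` and a flag
#' for zero-effort occasions.
#'
#' @param design A [removal_design()].
#' @return A tibble with columns `primary`, `secondary`, `occasion`, `missing`.
#' @export
design_occasions <- function(design) {
  stopifnot(inherits(design, "removal_design"))
  design$occasions %||% build_occasions(design)
}

#' @export
print.removal_design <- function(x, ...) {
  kind <- if (all(x$k == 1L)) "single-secondary (non-robust)" else "robust"
  cat(sprintf(
    "<removal_design> %s layout: %d primary periods, K = %d occasions\n",
    kind, x$n_primary, x$K
  ))
  if (nrow(x$missing)) {
    cat(sprintf("  %d occasion(s) with no sampling effort\n", nrow(x$missing)))
  }
  invisible(x)
}

same_design <- function(a, b) {
  a$n_primary == b$n_primary && identical(a$k, b$k) &&
    identical(dplyr::arrange(a$missing, .data$primary, .data$secondary),
              dplyr::arrange(b$missing, .data$primary, .data$secondary))
}
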