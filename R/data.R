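#' Construct a removal-data table
#'
#' Validates a data frame of removal counts against a robust-design layout
#' and returns a `removal_data` tibble: one row per sampled occasion (and
#' population), in canonical order, with the design attached as an
#' attribute. Counts at occasions flagged as having no sampling effort are
#' forced to zero.
#'
#' @param df Data frame with columns `primary`, `secondary`, `count`, an
#'   optional `population` column (defaults to 1), an optional `effort`
#'   column (0 marks occasions with no sampling effort) and any further
#'   covariate columns, which are carried along.
#' @param design Optional [removal_design()]; inferred from the rows when
#'   absent (each primary's secondary count is its largest secondary index;
#'   effort-0 rows become missing occasions).
#' @return A tibble of class `removal_data` with attribute `design`.
#' @examples
#' removal_data(data.frame(
#'   primary = c(1, 1, 2, 2), secondary = c(1, 2, 1, 2), count = c(5, 3, 2, 1)
#' ))
#' @export
removal_data <- function(df, design = NULL) {
  df <- tibble::as_tibble(df)
  need <- c("primary", "secondary", "count")
  if (!all(need %in% names(df))) {
    abort("`df` needs columns primary, secondary, count.")
  }
  if (!"population" %in% names(df)) df$population <- 1L
  df$primary <- as.integer(df$primary)
  df$secondary <- as.integer(df$secondary)
  df$population <- as.integer(df$population)
  if (any(df$count < 0, na.rm = TRUE) || anyNA(df$count)) {
    abort("Counts must be non-negative and non-missing.")
  }
  if (anyDuplicated(df[c("population", "primary", "secondary")])) {
    abort("Duplicate (population, primary, secondary) rows.")
  }
  pops <- sort(unique(df$population))
  if (!identical(pops, seq_along(pops))) {
    abort("Populations must be numbered 1, 2, ...")
  }

  if (is.null(design)) {
    one <- df[df$population == pops[[1]], ]
    Tn <- max(one$primary)
    k <- vapply(seq_len(Tn), function(i) {
      s <- one$secondary[one$primary == i]
      if (!length(s)) abort(sprintf("Primary period %d has no rows.", i))
      max(s)
    }, integer(1))
    miss <- NULL
    if ("effort" %in% names(df)) {
      m <- one[one$effort == 0, c("primary", "secondary")]
      if (nrow(m)) miss <- m
    }
    design <- removal_design(Tn, k, missing = miss)
  }

  occ <- design_occasions(design)
  full <- tidyr::expand_grid(population = pops, occ)
  out <- dplyr::left_join(full, df, by = c("population", "primary", "secondary"))
  # every design occasion must be present for every population
  gap <- is.na(out$count) & !out$missing
  if (any(gap)) {
    abort(sprintf(
      "Missing rows for %d sampled occasion(s); secondary numbering must have no gaps.",
      sum(gap)
    ))
  }
  if (any(out$count[out$missing] > 0, na.rm = TRUE)) {
    warn("Positive counts at zero-effort occasions were forced to 0.")
  }
  out$count[out$missing] <- 0L
  out$count <- as.integer(out$count)
  out$effort <- as.integer(!out$missing)
  keep <- c("population", "primary", "secondary", "occasion", "count", "effort")
  extra <- setdiff(names(df), c(keep, "missing"))
  out <- out[c(keep, extra)]
  out <- dplyr::arrange(out, .data$population, .data$occasion)
  structure(out, design = design,
            class = c("removal_data", class(tibble::tibble())))
}

#' Total number of removed individuals
#'
#' @param data A [removal_data()] object.
#' @param by_population Return one total per population?
#' @return Integer total `D`, or a named vector per population.
#' @export
total_removed <- function(data, by_population = FALSE) {
  stopifnot(inherits(data, "removal_data"))
  if (!by_population) return(sum(data$count))
  d <- dplyr::summarise(dplyr::group_by(data, .data$population),
                        D = sum(.data$count), .groups = "drop")
  setNames(as.integer(d$D), d$population)
}

# counts for one population, length K in occasion order
counts_matrix <- function(data) {
  design <- attr(data, "design")
  pops <- sort(unique(data$population))
  lapply(pops, function(w) {
    sub <- data[data$population == w, ]
    sub$count[order(sub$occasion)]
  })
}

#' Read removal counts from CSV
#'
#' Reads a removal-data CSV with columns `primary`, `secondary`, `count`,
#' optional `population` and `effort` (0 = no sampling at that occasion;
#' the occasion is registered as missing and its count forced to zero) and
#' any covariate columns, and validates it into a [removal_data()] object.
#'
#' @param path File path.
#' @return A `removal_data` tibble.
#' @export
read_removal_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  removal_data(df)
}

#' Write removal counts to CSV
#'
#' Round-trips through [read_removal_csv()]: `read_removal_csv(write_removal_csv(x, f))`
#' reproduces `x`.
#'
#' @param data A [removal_data()] object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_removal_csv <- function(data, path) {
  stopifnot(inherits(data, "removal_data"))
  out <- as.data.frame(data)[setdiff(names(data), "occasion")]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a model configuration file
#'
#' Parses a YAML (or JSON) configuration describing a removal model run:
#'
#' ```yaml
#' design: {n_primary: 10, n_secondary: 2}
#' model: R-SRtC
#' n_populations: 1
#' covariate: precipitation   # optional column name
#' ```
#'
#' @param path File path to a YAML/JSON configuration.
#' @return A list with elements `spec` (an [rmer_spec()] or [grm_spec()]),
#'   `covariate` (column name or `NULL`) and any further fields verbatim.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design) || is.null(cfg$model)) {
    abort("Config needs `design` and `model` fields.")
  }
  miss <- NULL
  if (!is.null(cfg$design$missing)) {
    miss <- dplyr::bind_rows(lapply(cfg$design$missing, tibble::as_tibble))
  }
  design <- removal_design(cfg$design$n_primary, cfg$design$n_secondary,
                           missing = miss)
  spec <- parse_model_code(cfg$model, design,
                           n_populations = cfg$n_populations)
  c(list(spec = spec, covariate = cfg$covariate), cfg["seed"])
}
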