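#' Write the built-in scenario fixtures to disk
#'
#' Simulates one data set from each of the six built-in scenario presets
#' (constant/time-varying/integrated transitions, scenarios 1 and 2, at
#' `K = 20`) and writes each as a removal-data CSV next to a JSON file
#' holding the generating truth. Deterministic given `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param K Number of occasions for all presets.
#' @return Invisibly, a character vector of the files written.
#' @export
generate_scenario_fixtures <- function(dir, seed = 1, K = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  presets <- tidyr::expand_grid(
    setting = c("constant", "time_varying", "integrated"),
    scenario = c(1, 2)
  )
  seeds <- replicate_seeds(seed, nrow(presets))
  files <- character()
  for (i in seq_len(nrow(presets))) {
    scn <- removal_scenario(presets$setting[i], presets$scenario[i], K = K)
    stem <- file.path(dir, sprintf("%s-s%d", presets$setting[i], presets$scenario[i]))
    data <- simulate_removal(scn, seed = seeds[i])
    write_removal_csv(data, paste0(stem, ".csv"))
    truth <- list(
      schema_version = 1L,
      setting = scn$setting, scenario = scn$scenario, K = scn$K,
      seed = seeds[i], fit_code = scn$fit_code, gamma2 = scn$gamma2,
      populations = lapply(scn$populations, function(p) {
        list(N = p$N, pi = p$pi, phi12 = p$phi12, phi21 = p$phi21, p = p$p[1])
      })
    )
    jsonlite::write_json(truth, paste0(stem, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, paste0(stem, ".csv"), paste0(stem, ".json"))
  }
  invisible(files)
}
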